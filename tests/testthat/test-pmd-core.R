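test_that("RT grouping is single linkage with order-independent group ids", {
  tab <- toy_table(mz = c(500, 400, 300, 200), rt = c(100, 101, 102, 200))
  g <- assign_rt_groups(tab, rt_cutoff = 10)
  expect_equal(g$group, c(1L, 1L, 1L, 2L))

  # shuffled input yields the same partition
  perm <- c(3, 1, 4, 2)
  tab2 <- toy_table(mz = c(500, 400, 300, 200)[perm],
                    rt = c(100, 101, 102, 200)[perm])
  g2 <- assign_rt_groups(tab2, rt_cutoff = 10)
  expect_equal(g2$group, g$group[perm])

  # a chain within the cutoff collapses to one group
  chain <- toy_table(mz = rep(100, 5), rt = c(0, 9, 18, 27, 36))
  expect_equal(assign_rt_groups(chain, 10)$group, rep(1L, 5))

  one <- toy_table(mz = 100, rt = 5)
  expect_equal(assign_rt_groups(one, 10)$group, 1L)
})

test_that("PMD frequencies round to 2 decimals and count once per RT group", {
  # glucose [M+H]+ vs its sodium adduct: 203.0526 - 181.0707 = 21.9819
  tab <- toy_table(mz = c(181.0707, 203.0526), rt = c(300, 300.5))
  rec <- compute_pmd_frequency(tab, assign_rt_groups(tab, 10))
  expect_equal(rec$pmd, 21.98)
  expect_equal(rec$frequency, 1L)

  # same pair pattern in 3 disjoint RT groups -> frequency 3
  tab3 <- toy_table(mz = rep(c(181.0707, 203.0526), 3),
                    rt = c(100, 100, 300, 300, 500, 500))
  rec3 <- compute_pmd_frequency(tab3, assign_rt_groups(tab3, 10))
  expect_equal(rec3$frequency[rec3$pmd == 21.98], 3L)

  # three pairs at one distance inside one group still count once
  tabrep <- toy_table(mz = c(100, 110, 200, 210, 300, 310),
                      rt = rep(50, 6))
  recrep <- compute_pmd_frequency(tabrep, assign_rt_groups(tabrep, 10))
  expect_equal(recrep$frequency[recrep$pmd == 10], 1L)
})

test_that("high-frequency PMD selection honors explicit and elbow cutoffs", {
  rec <- data.frame(pmd = c(21.98, 18.01, 3.37),
                    frequency = c(50L, 40L, 1L))
  expect_equal(select_high_frequency_pmds(rec, freq_cutoff = 10),
               c(18.01, 21.98))
  expect_length(select_high_frequency_pmds(rec, freq_cutoff = 100), 0)

  # elbow: {50, 40, 39, 2, 1} has its largest drop 39 -> 2
  rec2 <- data.frame(pmd = c(21.98, 18.01, 1.00, 5.11, 3.37),
                     frequency = c(50L, 40L, 39L, 2L, 1L))
  expect_setequal(select_high_frequency_pmds(rec2), c(21.98, 18.01, 1.00))

  # the elbow never admits frequency-1 distances
  rec3 <- data.frame(pmd = c(1.23, 4.56), frequency = c(1L, 1L))
  expect_length(select_high_frequency_pmds(rec3), 0)

  expect_length(select_high_frequency_pmds(
    data.frame(pmd = numeric(0), frequency = integer(0))), 0)
})

test_that("redundant-peak reduction finds components and elects the intense peak", {
  # A (most intense, glucose-like), B = A + Na-H, C = A - water
  inten <- matrix(c(1e6, 4e5, 2e5), 3, 1,
                  dimnames = list(NULL, "s1"))
  tab <- toy_table(mz = c(181.07, 203.05, 163.06), rt = c(300, 300.4, 300.8),
                   intensities = inten, ids = c("A", "B", "C"))
  g <- assign_rt_groups(tab, 10)
  red <- reduce_redundant_peaks(tab, g, c(21.98, 18.01))
  expect_equal(red$independent, "A")
  expect_setequal(red$components[[1]], c("A", "B", "C"))
  expect_equal(brute_components(tab$features$mz, c(21.98, 18.01)),
               rep(1L, 3))

  # no qualifying pairs: everyone independent
  red0 <- reduce_redundant_peaks(tab, g, numeric(0))
  expect_setequal(red0$independent, c("A", "B", "C"))

  # two disjoint pairs in one RT group give two components
  inten4 <- matrix(c(10, 5, 8, 2), 4, 1, dimnames = list(NULL, "s1"))
  tab4 <- toy_table(mz = c(100, 121.98, 300, 318.01),
                    rt = rep(50, 4), intensities = inten4)
  red4 <- reduce_redundant_peaks(tab4, assign_rt_groups(tab4, 10),
                                 c(21.98, 18.01))
  expect_length(red4$components, 2)
  expect_setequal(red4$independent, c("F001", "F003"))
})

test_that("component finding agrees with brute-force transitive closure", {
  withr::local_seed(42)
  offsets <- c(21.9819, -18.0106, 1.0034, 17.0265)
  for (rep_i in 1:200) {
    n <- sample(2:12, 1)
    mz <- runif(n, 100, 900)
    # seed some true offset relations so components are non-trivial
    for (k in seq_len(min(n - 1, 3))) {
      mz[k + 1] <- mz[1] + sample(offsets, 1)
    }
    tab <- toy_table(mz = mz, rt = rep(100, n),
                     intensities = matrix(runif(n, 1, 100), n, 1,
                                          dimnames = list(NULL, "s1")))
    high <- c(21.98, 18.01, 1.00, 17.03)
    red <- reduce_redundant_peaks(tab, assign_rt_groups(tab, 10), high)
    oracle <- brute_components(mz, high)
    # identical partitions: same member sets, order-free comparison
    got <- sort(vapply(red$components,
                       function(x) paste(sort(x), collapse = "|"),
                       character(1)))
    want <- sort(vapply(split(tab$features$id, oracle),
                        function(x) paste(sort(x), collapse = "|"),
                        character(1)))
    expect_equal(got, unname(want))
  }
})

test_that("overlapping clusters merge with the most intense base retained", {
  inten <- matrix(c(10, 50, 20), 3, 1, dimnames = list(NULL, "s1"))
  tab <- toy_table(mz = c(100, 110, 120), rt = c(10, 11, 12),
                   intensities = inten, ids = c("A", "B", "C"))
  merged <- build_and_merge_clusters(
    independent = c("A", "C"),
    components = list(c("A", "B"), c("B", "C")), tab)
  expect_length(merged, 1)
  expect_setequal(merged[[1]]$members, c("A", "B", "C"))
  expect_equal(merged[[1]]$base_peak, "C")  # intensity 20 > 10

  disjoint <- build_and_merge_clusters(
    independent = c("A", "C"),
    components = list(c("A", "B"), "C"), tab)
  expect_length(disjoint, 2)
  expect_equal(vapply(disjoint, `[[`, character(1), "base_peak"),
               c("A", "C"))
})

test_that("correlation pruning keeps r >= 0.9 and drops anticorrelated members", {
  base <- c(10, 20, 30, 40, 50)
  m <- rbind(base,
             2 * base,                      # r = 1, kept
             rev(base),                     # r = -1, removed
             c(5, 5, 5, 5, 5))              # zero variance, removed
  colnames(m) <- sprintf("s%d", 1:5)
  tab <- toy_table(mz = c(100, 110, 120, 130), rt = rep(10, 4),
                   intensities = m, roles = rep("study", 5),
                   ids = c("A", "B", "C", "D"))
  cl <- list(members = c("A", "B", "C", "D"), base_peak = "A",
             precursor = NA_character_)
  expect_warning(pruned <- prune_by_correlation(cl, tab), "zero-variance")
  expect_setequal(pruned$members, c("A", "B"))

  # r exactly 0.9 is retained: mix x with an orthogonal zero-mean residual
  x <- c(-2, -1, 0, 1, 2)
  resid <- c(1, -2, 0, 2, -1)
  y <- 0.9 * x / sd(x) + sqrt(1 - 0.9^2) * resid / sd(resid)
  expect_equal(cor(x, y), 0.9, tolerance = 1e-12)
  m2 <- rbind(100 + 10 * x, 100 + 10 * y)
  colnames(m2) <- sprintf("s%d", 1:5)
  tab2 <- toy_table(mz = c(100, 110), rt = c(10, 10), intensities = m2,
                    roles = rep("study", 5), ids = c("A", "B"))
  cl2 <- list(members = c("A", "B"), base_peak = "A",
              precursor = NA_character_)
  expect_setequal(prune_by_correlation(cl2, tab2)$members, c("A", "B"))

  # fewer than 3 study samples: pruning skipped with a warning
  tab3 <- toy_table(mz = c(100, 110), rt = c(10, 10),
                    intensities = matrix(1:4, 2, 2,
                                         dimnames = list(NULL, c("s1", "s2"))),
                    roles = rep("study", 2), ids = c("A", "B"))
  expect_warning(out3 <- prune_by_correlation(cl2, tab3), "skipped")
  expect_setequal(out3$members, c("A", "B"))
})

test_that("precursor election takes the intensity maximum with low-m/z tie-break", {
  inten <- matrix(c(1e6, 5e5, 300, 300), 4, 1,
                  dimnames = list(NULL, "s1"))
  tab <- toy_table(mz = c(181.07, 203.05, 500.2, 400.1),
                   rt = c(10, 10, 600, 601),
                   intensities = inten, ids = c("A", "B", "C", "D"))
  clusters <- list(
    list(members = c("A", "B"), base_peak = "A", precursor = NA_character_),
    list(members = c("C", "D"), base_peak = "C", precursor = NA_character_))
  prec <- select_precursors(clusters, tab)
  expect_equal(nrow(prec), 2)
  expect_equal(prec$id[1], "A")         # clear intensity winner
  expect_equal(prec$id[2], "D")         # tie broken toward lower m/z
  expect_equal(prec$rt, sort(prec$rt))  # sorted by RT

  expect_error(select_precursors(list(list(members = character(0),
                                           base_peak = "A",
                                           precursor = NA_character_)), tab),
               "empty cluster")
})

test_that("pipeline counts never grow along the reduction chain", {
  withr::local_seed(11)
  sim <- simulate_dataset(synth_config(n_compounds = 40,
                                       background_features = 30, seed = 5))
  tab <- qc_filter(sim$pos)
  res <- pmd_workflow(tab)
  expect_lte(length(res$clusters), length(res$independent))
  expect_lte(length(res$independent), nrow(tab$features))
  expect_equal(nrow(res$precursors), length(res$clusters))
  # every precursor is a member of its own cluster and its intensity maximum
  inten <- study_means(tab)
  for (cl in res$clusters) {
    expect_true(cl$precursor %in% cl$members)
    expect_equal(unname(inten[cl$precursor]),
                 max(inten[cl$members]))
  }
})

test_that("sodium adduct pairs push PMD 21.98 into the top frequencies", {
  withr::local_seed(3)
  base <- runif(40, 150, 800)
  rt <- 15 * (1:40)
  tab <- toy_table(mz = c(base, base + 21.9819),
                   rt = c(rt, rt + runif(40, -1, 1)))
  rec <- compute_pmd_frequency(tab, assign_rt_groups(tab, 10))
  expect_equal(rec$pmd[1], 21.98)
  expect_gte(rec$frequency[1], 39)
})
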