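simple_scan <- function(prec, rt, mz, int = NULL) {
  if (is.null(int)) int <- rep(1000, length(mz))
  ms2_scan(prec, rt, cbind(mz, int))
}

test_that("scans go to the nearest in-tolerance target with low-m/z tie-break", {
  targets <- data.frame(id = c("T1", "T2"), mz = c(181.07, 181.17),
                        rt = c(300, 300), stringsAsFactors = FALSE)
  scans <- list(
    simple_scan(181.075, 300, 100),   # 0.005 from T1 -> assigned
    simple_scan(181.12, 300, 100),    # 0.05 from both -> unassigned
    simple_scan(181.1200001, 300, 100))
  got <- group_scans_by_precursor(scans, targets, mz_tol = 0.02)
  expect_equal(got$groups$T1, 1L)
  expect_equal(got$unassigned, c(2L, 3L))

  # equidistant scan goes to the lower-m/z target (0.25 is exact in binary)
  targets2 <- data.frame(id = c("A", "B"), mz = c(100.0, 100.5),
                         rt = c(50, 50), stringsAsFactors = FALSE)
  got2 <- group_scans_by_precursor(list(simple_scan(100.25, 50, 60)),
                                   targets2, mz_tol = 0.3)
  expect_equal(got2$groups$A, 1L)
  expect_length(got2$groups$B, 0)

  # no targets: everything unassigned
  got0 <- group_scans_by_precursor(scans,
                                   targets[0, , drop = FALSE])
  expect_equal(got0$unassigned, 1:3)

  # optional RT constraint excludes off-time scans
  got_rt <- group_scans_by_precursor(list(simple_scan(181.07, 400, 60)),
                                     targets, rt_tol = 5)
  expect_equal(got_rt$unassigned, 1L)
})

test_that("fragment occurrence follows the strict 60% rule", {
  # fragment at 200.0 in 4 of 5 scans (80% > 60%: kept);
  # fragment at 300.0 in 3 of 5 scans (60%, not > 60%: dropped)
  scans <- list(
    simple_scan(500, 100, c(150.0, 200.0, 300.0)),
    simple_scan(500, 100, c(150.0, 200.0, 300.0)),
    simple_scan(500, 100, c(150.0, 200.0, 300.0)),
    simple_scan(500, 100, c(150.0, 200.0)),
    simple_scan(500, 100, 150.0))
  cs <- build_consensus_spectrum(scans)
  expect_equal(round(cs$fragments[, "mz"], 1), c(150.0, 200.0))
  expect_equal(cs$n_scans, 5)
})

test_that("fragments within 5 ppm merge; a single scan passes through unchanged", {
  # 400.0000 vs 400.0015 differ by 3.75 ppm -> one cluster
  scans <- list(simple_scan(500, 100, 400.0000, 1000),
                simple_scan(500, 100, 400.0015, 3000))
  cs <- build_consensus_spectrum(scans)
  expect_equal(nrow(cs$fragments), 1)
  expect_equal(unname(cs$fragments[1, "mz"]),
               weighted.mean(c(400, 400.0015), c(1000, 3000)),
               tolerance = 1e-9)

  # 400.0000 vs 400.0025 differ by 6.25 ppm -> two clusters, each in one
  # of two scans (50%), so both drop
  scans2 <- list(simple_scan(500, 100, 400.0000),
                 simple_scan(500, 100, 400.0025))
  expect_equal(nrow(build_consensus_spectrum(scans2)$fragments), 0)

  one <- simple_scan(500, 120, c(90.5, 150.2, 310.9), c(5, 10, 2))
  cs1 <- build_consensus_spectrum(list(one))
  expect_equal(cs1$fragments[, "mz"], c(90.5, 150.2, 310.9))
  expect_equal(cs1$fragments[, "intensity"], c(5, 10, 2))

  expect_error(build_consensus_spectrum(list()), "no scans")
})

test_that("consensus matches the brute-force all-pairs oracle on random scans", {
  withr::local_seed(31)
  for (i in 1:50) {
    n_scans <- sample(1:10, 1)
    base_frags <- sort(runif(sample(3:20, 1), 50, 500))
    scans <- lapply(seq_len(n_scans), function(s) {
      present <- runif(length(base_frags)) < 0.8
      mz <- base_frags[present] * (1 + runif(sum(present), -3e-6, 3e-6))
      if (length(mz) == 0) mz <- runif(1, 50, 500)
      simple_scan(600, 50, mz, runif(length(mz), 100, 1e4))
    })
    got <- build_consensus_spectrum(scans)$fragments
    want <- brute_consensus(scans)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(unname(got[, "mz"]), unname(want[, "mz"]),
                   tolerance = 1e-9)
      expect_equal(unname(got[, "intensity"]), unname(want[, "intensity"]),
                   tolerance = 1e-9)
    }
  }
})

test_that("true fragments survive and single-scan spurious peaks are dropped", {
  sim <- simulate_dataset(synth_config(n_compounds = 15,
                                       background_features = 0, seed = 4))
  res <- pmd_workflow(qc_filter(sim$pos))
  prec <- res$precursors[1:5, ]
  scans <- simulate_ms2_runs(prec, sim$truth, n_scans_per_target = 5,
                             spurious_rate = 0.1, seed = 6)
  grp <- group_scans_by_precursor(scans, prec)
  fm <- sim$truth$feature_map
  for (id in prec$id) {
    idx <- grp$groups[[id]]
    expect_length(idx, 5)
    cs <- build_consensus_spectrum(scans[idx],
                                   target = prec[prec$id == id, ])
    cmp <- fm$compound[match(id, fm$feature_id)]
    truth_frags <- sim$truth$fragments[[cmp]]
    # every true fragment recovered within 5 ppm, nothing spurious kept
    expect_equal(nrow(cs$fragments), nrow(truth_frags))
    expect_equal(unname(cs$fragments[, "mz"]), truth_frags$mz,
                 tolerance = 1e-5)
  }
})

test_that("MS1 linking applies strict 5 ppm / 5 s bounds", {
  tab <- toy_table(mz = c(181.0707, 500.0), rt = c(303, 700),
                   ids = c("F1", "F2"))
  entries <- data.frame(id = c("C1", "C2", "C3"),
                        mz = c(181.0710, 181.0707 * (1 + 6e-6), 500.0),
                        rt = c(300, 303, 706))
  got <- link_back_to_ms1(entries, tab, ppm = 5, rt_tol = 5)
  c1 <- got[got$entry_id == "C1", ]
  expect_true(c1$matched)
  expect_equal(c1$feature_id, "F1")
  expect_equal(c1$ppm, 1e6 * 0.0003 / 181.0707, tolerance = 1e-3)
  expect_false(got$matched[got$entry_id == "C2"])  # 6 ppm away
  expect_false(got$matched[got$entry_id == "C3"])  # 6 s away
})

test_that("known compounds match at two decimals via the element-mass oracle", {
  creatinine <- formula_mass("C4H7N3O")
  uric_acid <- formula_mass("C5H4N4O3")
  expect_equal(creatinine, 113.0590, tolerance = 2e-4)
  expect_equal(uric_acid, 168.0283, tolerance = 2e-4)
  compounds <- data.frame(name = c("creatinine", "uric acid"),
                          monoisotopic_mass = c(creatinine, uric_acid),
                          stringsAsFactors = FALSE)

  prec_pos <- data.frame(id = c("P1", "P2"), mz = c(114.0665, 114.08))
  mp <- match_known_compounds(prec_pos, compounds, "positive")
  expect_equal(mp$id, "P1")                  # both round to 114.07
  expect_equal(mp$name, "creatinine")
  expect_equal(round(mp$theoretical_mz, 2), 114.07)

  prec_neg <- data.frame(id = "N1", mz = 167.0210)
  mn <- match_known_compounds(prec_neg, compounds, "negative")
  expect_equal(mn$name, "uric acid")         # both round to 167.02
  expect_equal(round(mn$theoretical_mz, 2), 167.02)
})
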