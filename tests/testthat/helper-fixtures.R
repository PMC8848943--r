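# Fixture builders and independent oracles shared across the test files.
# Everything here is deliberately naive: enumeration, closed forms and
# brute force, kept independent of the package internals they check.

# Small feature table from parallel vectors; default one study sample.
toy_table <- function(mz, rt, intensities = NULL, roles = NULL,
                      ids = NULL) {
  n <- length(mz)
  if (is.null(intensities)) {
    intensities <- matrix(1000, n, 1, dimnames = list(NULL, "study_1"))
  }
  if (is.null(colnames(intensities))) {
    colnames(intensities) <- sprintf("s%d", seq_len(ncol(intensities)))
  }
  if (is.null(roles)) roles <- rep("study", ncol(intensities))
  if (is.null(ids)) ids <- sprintf("F%03d", seq_len(n))
  feature_table(data.frame(id = ids, mz = mz, rt = rt,
                           stringsAsFactors = FALSE),
                intensities, roles)
}

# The constructed 10-feature toy table: 2 RT-range violators (F001, F002),
# 2 fold-change violators (F005, F006), 2 RSD violators (F009, F010), no
# overlaps; by hand enumeration exactly F003, F004, F007, F008 survive.
qc_toy_table <- function() {
  study <- rbind(
    c(500, 500, 500),     # F001 rt 10 (below range)
    c(500, 500, 500),     # F002 rt 950 (above range)
    c(600, 600, 600),     # F003 ok
    c(900, 900, 900),     # F004 ok
    c(250, 250, 250),     # F005 blank mean 100 -> FC 2.5 < 3, removed
    c(100, 100, 100),     # F006 blank mean 100 -> FC 1, removed
    c(600, 570, 630),     # F007 RSD 5%, kept
    c(800, 840, 760),     # F008 RSD 5%, kept
    c(100, 500, 900),     # F009 RSD 80%, removed
    c(50, 500, 950)       # F010 RSD 90%, removed
  )
  blank <- matrix(0, 10, 2)
  blank[5, ] <- 100
  blank[6, ] <- 100
  inten <- cbind(study, blank)
  colnames(inten) <- c("s1", "s2", "s3", "b1", "b2")
  toy_table(mz = seq(100, 109), rt = c(10, 950, rep(500, 8)),
            intensities = inten,
            roles = c("study", "study", "study", "blank", "blank"))
}

# Connected components by exhaustive pair enumeration plus transitive
# closure (Floyd-Warshall style), the oracle for redundant-peak reduction.
brute_components <- function(mz, high_pmds) {
  n <- length(mz)
  adj <- diag(TRUE, n)
  keys <- as.integer(round(round(high_pmds, 2) * 100))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d <- round(abs(mz[i] - mz[j]), 2)
      if (i != j && as.integer(round(d * 100)) %in% keys) {
        adj[i, j] <- TRUE
      }
    }
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (adj[i, k] && adj[k, j]) adj[i, j] <- TRUE
      }
    }
  }
  comp <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      next_id <- next_id + 1L
      comp[adj[i, ]] <- next_id
    }
  }
  comp
}

# Brute-force consensus: all-pairs ppm relation (< ppm relative to the
# smaller m/z), transitive closure, occurrence counting, weighted-mean m/z
# and median per-scan summed intensity.
brute_consensus <- function(scans, frag_ppm = 5, occurrence_min = 0.6) {
  pool <- do.call(rbind, lapply(seq_along(scans), function(s) {
    fr <- scans[[s]]$fragments
    if (nrow(fr) == 0) return(NULL)
    data.frame(scan = s, mz = fr[, "mz"], intensity = fr[, "intensity"])
  }))
  if (is.null(pool)) return(matrix(numeric(0), ncol = 2))
  n <- nrow(pool)
  adj <- diag(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (1e6 * abs(pool$mz[i] - pool$mz[j]) /
            min(pool$mz[i], pool$mz[j]) < frag_ppm) {
        adj[i, j] <- TRUE
      }
    }
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (adj[i, k] && adj[k, j]) adj[i, j] <- TRUE
      }
    }
  }
  comp <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      next_id <- next_id + 1L
      comp[adj[i, ]] <- next_id
    }
  }
  out <- list()
  for (cl in split(seq_len(n), comp)) {
    sub <- pool[cl, ]
    if (length(unique(sub$scan)) <= occurrence_min * length(scans)) next
    per_scan <- tapply(sub$intensity, sub$scan, sum)
    out[[length(out) + 1L]] <- c(
      mz = sum(sub$mz * sub$intensity) / sum(sub$intensity),
      intensity = unname(median(per_scan)))
  }
  if (length(out) == 0) return(matrix(numeric(0), ncol = 2))
  m <- do.call(rbind, out)
  m[order(m[, "mz"]), , drop = FALSE]
}

# Independent MGF parser (never uses package code).
parse_mgf <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  for (ln in lines) {
    if (ln == "BEGIN IONS") {
      cur <- list(meta = character(0), frags = list())
    } else if (ln == "END IONS") {
      frag <- if (length(cur$frags)) do.call(rbind, cur$frags) else
        matrix(numeric(0), ncol = 2)
      blocks[[length(blocks) + 1L]] <- list(
        title = sub("^TITLE=", "", grep("^TITLE=", cur$meta, value = TRUE)),
        pepmass = as.numeric(sub("^PEPMASS=", "",
                                 grep("^PEPMASS=", cur$meta, value = TRUE))),
        rt = as.numeric(sub("^RTINSECONDS=", "",
                            grep("^RTINSECONDS=", cur$meta, value = TRUE))),
        fragments = frag)
      cur <- NULL
    } else if (!is.null(cur) && nzchar(ln)) {
      if (grepl("=", ln, fixed = TRUE)) {
        cur$meta <- c(cur$meta, ln)
      } else {
        cur$frags[[length(cur$frags) + 1L]] <-
          as.numeric(strsplit(ln, " ")[[1]])
      }
    }
  }
  blocks
}

# Monoisotopic mass from a molecular formula, using CODATA/AME isotope
# masses: the element-mass oracle for adduct arithmetic.
ELEMENT_MASS <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                  O = 15.9949146221, S = 31.97207069, P = 30.97376151,
                  Na = 22.98976928)
formula_mass <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  total <- 0
  for (p in parts) {
    el <- gsub("[0-9]", "", p)
    n <- gsub("[^0-9]", "", p)
    n <- if (nzchar(n)) as.integer(n) else 1L
    total <- total + ELEMENT_MASS[[el]] * n
  }
  total
}
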