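#' Assign MS2 scans to precursor targets
#'
#' A scan is assigned to a target when its recorded precursor m/z lies
#' within \code{mz_tol} of the target m/z and, if \code{rt_tol} is given,
#' its RT within \code{rt_tol} of the target RT. A scan matching several
#' targets goes to the nearest-m/z target (ties to the lower-m/z target);
#' scans matching none are reported as unassigned.
#'
#' @param scans list of \code{\link{ms2_scan}} objects.
#' @param targets data.frame with columns \code{id}, \code{mz} and (when
#'   \code{rt_tol} is used) \code{rt}, e.g. from
#'   \code{\link{select_precursors}}.
#' @param mz_tol precursor m/z tolerance, Da (inclusive).
#' @param rt_tol optional RT tolerance, seconds (inclusive); \code{NULL}
#'   disables the RT constraint.
#' @return List with \code{groups} (named list, target id -> integer
#'   indices into \code{scans}) and \code{unassigned} (integer vector).
#' @export
group_scans_by_precursor <- function(scans, targets, mz_tol = 0.02,
                                     rt_tol = NULL) {
  groups <- stats::setNames(
    replicate(nrow(targets), integer(0), simplify = FALSE), targets$id)
  unassigned <- integer(0)
  ord_t <- order(targets$mz)   # lower-m/z target wins ties
  for (s in seq_along(scans)) {
    dmz <- abs(scans[[s]]$precursor_mz - targets$mz)
    ok <- dmz <= mz_tol
    if (!is.null(rt_tol)) {
      ok <- ok & abs(scans[[s]]$rt - targets$rt) <= rt_tol
    }
    if (!any(ok)) {
      unassigned <- c(unassigned, s)
      next
    }
    cand <- ord_t[ok[ord_t]]
    best <- cand[which.min(dmz[cand])]
    groups[[best]] <- c(groups[[best]], s)
  }
  list(groups = groups, unassigned = unassigned)
}

#' Consensus spectrum container
#'
#' @param target_feature MS1 feature id of the precursor target.
#' @param precursor_mz target m/z, Da.
#' @param rt target RT, seconds.
#' @param fragments two-column matrix (\code{mz}, \code{intensity}).
#' @param n_scans number of scans merged.
#' @return An object of class \code{consensus_spectrum}.
#' @export
consensus_spectrum <- function(target_feature, precursor_mz, rt, fragments,
                               n_scans) {
  fragments <- matrix(as.numeric(fragments), ncol = 2,
                      dimnames = list(NULL, c("mz", "intensity")))
  if (nrow(fragments) > 0) {
    fragments <- fragments[order(fragments[, "mz"]), , drop = FALSE]
  }
  structure(list(target_feature = target_feature,
                 precursor_mz = precursor_mz, rt = rt,
                 fragments = fragments, n_scans = n_scans),
            class = "consensus_spectrum")
}

#' Merge repeated MS2 scans of one target into a consensus spectrum
#'
#' Fragment peaks from all scans are pooled and clustered by single linkage
#' on m/z, joining peaks whose relative shift is below \code{frag_ppm}
#' (ppm taken relative to the smaller of the two m/z values). A cluster is
#' retained only when it is observed in strictly more than
#' \code{occurrence_min} of the contributing scans -- a peak seen in a
#' single scan of many is noise. Each retained cluster reports the
#' intensity-weighted mean m/z and the median across contributing scans of
#' the per-scan summed intensity.
#'
#' @param scans non-empty list of \code{\link{ms2_scan}} objects already
#'   grouped to one target.
#' @param target optional one-row data.frame (\code{id}, \code{mz},
#'   \code{rt}) identifying the target; defaults to the first scan's
#'   precursor.
#' @param frag_ppm fragment clustering tolerance, ppm (strict).
#' @param occurrence_min minimum occurrence fraction (strictly exceeded).
#' @return A \code{\link{consensus_spectrum}}.
#' @export
build_consensus_spectrum <- function(scans, target = NULL, frag_ppm = 5,
                                     occurrence_min = 0.6) {
  if (length(scans) == 0) stop("no scans for target")
  n_scans <- length(scans)
  pool <- do.call(rbind, lapply(seq_along(scans), function(s) {
    fr <- scans[[s]]$fragments
    if (nrow(fr) == 0) return(NULL)
    cbind(scan = s, fr)
  }))
  if (is.null(pool) || nrow(pool) == 0) {
    frag <- matrix(numeric(0), ncol = 2)
  } else {
    ord <- order(pool[, "mz"])
    pool <- pool[ord, , drop = FALSE]
    mz <- pool[, "mz"]
    # single linkage in one dimension: a new cluster starts at every gap
    # of at least frag_ppm between adjacent sorted m/z values
    brk <- if (length(mz) > 1) {
      ppm_diff(mz[-length(mz)], mz[-1]) >= frag_ppm
    } else {
      logical(0)
    }
    cl <- cumsum(c(1L, as.integer(brk)))
    rows <- lapply(split(seq_along(cl), cl), function(idx) {
      sub <- pool[idx, , drop = FALSE]
      n_obs <- length(unique(sub[, "scan"]))
      if (n_obs <= occurrence_min * n_scans) return(NULL)
      per_scan <- tapply(sub[, "intensity"], sub[, "scan"], sum)
      c(mz = weighted.mean(sub[, "mz"], sub[, "intensity"]),
        intensity = unname(median(per_scan)))
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    frag <- if (length(rows)) do.call(rbind, rows) else
      matrix(numeric(0), ncol = 2)
  }
  if (is.null(target)) {
    target <- data.frame(id = paste0("prec_", scans[[1]]$precursor_mz),
                         mz = scans[[1]]$precursor_mz,
                         rt = scans[[1]]$rt)
  }
  consensus_spectrum(target$id, target$mz, target$rt, frag, n_scans)
}

#' Link consensus spectra (or annotations) back to MS1 features
#'
#' Attaches each entry with an (m/z, RT) coordinate to every MS1 feature
#' lying within both a strict ppm tolerance on m/z and a strict RT
#' tolerance; entries matching no feature are flagged unmatched.
#'
#' @param entries data.frame with columns \code{mz}, \code{rt} and
#'   optionally \code{id} (generated from row order when absent); a list of
#'   \code{\link{consensus_spectrum}} objects is also accepted.
#' @param table a quality-filtered \code{feature_table}.
#' @param ppm m/z tolerance, ppm (strict, relative to the smaller m/z).
#' @param rt_tol RT tolerance, seconds (strict).
#' @return data.frame with one row per (entry, feature) match plus one row
#'   (\code{feature_id = NA}, \code{matched = FALSE}) per unmatched entry.
#' @export
link_back_to_ms1 <- function(entries, table, ppm = 5, rt_tol = 5) {
  if (is.list(entries) && !is.data.frame(entries) &&
      all(vapply(entries, inherits, logical(1), "consensus_spectrum"))) {
    entries <- data.frame(
      id = vapply(entries, `[[`, character(1), "target_feature"),
      mz = vapply(entries, `[[`, numeric(1), "precursor_mz"),
      rt = vapply(entries, `[[`, numeric(1), "rt"),
      stringsAsFactors = FALSE)
  }
  if (is.null(entries$id)) entries$id <- sprintf("E%04d", seq_len(nrow(entries)))
  feat <- table$features
  out <- list()
  for (i in seq_len(nrow(entries))) {
    dppm <- ppm_diff(entries$mz[i], feat$mz)
    drt <- abs(entries$rt[i] - feat$rt)
    hit <- which(dppm < ppm & drt < rt_tol)
    if (length(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        entry_id = entries$id[i], feature_id = feat$id[hit],
        mz = entries$mz[i], feature_mz = feat$mz[hit],
        ppm = dppm[hit], delta_rt = drt[hit], matched = TRUE,
        stringsAsFactors = FALSE)
    } else {
      out[[length(out) + 1L]] <- data.frame(
        entry_id = entries$id[i], feature_id = NA_character_,
        mz = entries$mz[i], feature_mz = NA_real_,
        ppm = NA_real_, delta_rt = NA_real_, matched = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Match precursor ions to known compounds at two decimal places
#'
#' Theoretical ion m/z values are formed as monoisotopic mass plus (positive
#' mode) or minus (negative mode) one electron-corrected proton mass
#' (1.00728 Da). A precursor matches a compound when both m/z values agree
#' after rounding to two decimals (half away from zero).
#'
#' @param precursors data.frame with columns \code{id}, \code{mz}.
#' @param compounds data.frame with columns \code{name},
#'   \code{monoisotopic_mass} (Da).
#' @param mode ionization mode, \code{"positive"} or \code{"negative"}.
#' @return data.frame of all matches: \code{id}, \code{mz}, \code{name},
#'   \code{theoretical_mz}.
#' @export
match_known_compounds <- function(precursors, compounds,
                                  mode = c("positive", "negative")) {
  mode <- match.arg(mode)
  stopifnot(all(compounds$monoisotopic_mass > 0))
  theo <- compounds$monoisotopic_mass +
    if (mode == "positive") PROTON_MASS else -PROTON_MASS
  theo2 <- round_away(theo, 2L)
  prec2 <- round_away(precursors$mz, 2L)
  out <- list()
  for (i in seq_len(nrow(precursors))) {
    hit <- which(abs(theo2 - prec2[i]) < 1e-9)
    if (length(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        id = precursors$id[i], mz = precursors$mz[i],
        name = compounds$name[hit], theoretical_mz = theo[hit],
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(id = character(0), mz = numeric(0), name = character(0),
               theoretical_mz = numeric(0))
  rownames(res) <- NULL
  res
}
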