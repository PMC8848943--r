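#' Quality-control filter settings
#'
#' Bundles the three MS1 feature filters applied before precursor selection:
#' a retention-time window that removes the void volume and the column-wash
#' phase, a blank fold-change filter that removes background ions, and a
#' replicate-RSD filter that removes irreproducible features.
#'
#' @param rt_min,rt_max retained retention-time range, seconds (inclusive).
#' @param fold minimum study/blank mean-intensity ratio for a feature to be
#'   kept.
#' @param rsd_max maximum relative standard deviation (sd/mean, as a
#'   fraction) across study samples.
#' @return An object of class \code{filter_config}.
#' @export
filter_config <- function(rt_min = 30, rt_max = 930, fold = 3,
                          rsd_max = 0.30) {
  stopifnot(rt_min < rt_max, fold > 0, rsd_max > 0, rsd_max < 1)
  structure(list(rt_min = rt_min, rt_max = rt_max, fold = fold,
                 rsd_max = rsd_max),
            class = "filter_config")
}

#' Trim features to the chromatographic retention-time range
#'
#' Keeps features with \code{rt_min <= rt <= rt_max} (boundaries inclusive).
#'
#' @param table a \code{feature_table}.
#' @param cfg a \code{\link{filter_config}}.
#' @return Filtered \code{feature_table}; the sample set is unchanged.
#' @export
trim_rt_range <- function(table, cfg = filter_config()) {
  keep <- table$features$rt >= cfg$rt_min & table$features$rt <= cfg$rt_max
  subset_features(table, keep)
}

#' Remove background features by blank fold change
#'
#' Keeps features whose mean study intensity is at least \code{fold} times
#' the mean intensity across all pooled blank samples. Features absent from
#' the blanks (blank mean exactly zero) are always kept, so the rule needs
#' no division.
#'
#' @inheritParams trim_rt_range
#' @return Filtered \code{feature_table}.
#' @export
blank_fold_change_filter <- function(table, cfg = filter_config()) {
  bl <- blank_cols(table)
  if (length(bl) == 0) {
    stop("no blank samples: skip the fold-change filter explicitly ",
         "rather than applying it without blanks")
  }
  if (length(study_cols(table)) == 0) stop("no study samples")
  study_mean <- study_means(table)
  blank_mean <- rowMeans(table$intensities[, bl, drop = FALSE])
  keep <- blank_mean == 0 | study_mean >= cfg$fold * blank_mean
  subset_features(table, keep)
}

#' Remove irreproducible features by replicate RSD
#'
#' Keeps features whose relative standard deviation (sample standard
#' deviation with n-1 denominator, divided by the mean) across study samples
#' is at most \code{rsd_max}. Features with zero mean study intensity are
#' removed.
#'
#' @inheritParams trim_rt_range
#' @return Filtered \code{feature_table}.
#' @export
rsd_filter <- function(table, cfg = filter_config()) {
  sc <- study_cols(table)
  if (length(sc) < 2) stop("RSD filter requires at least 2 study samples")
  m <- table$intensities[, sc, drop = FALSE]
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  keep <- mu > 0 & s / mu <= cfg$rsd_max
  keep[is.na(keep)] <- FALSE
  subset_features(table, keep)
}

#' Apply all three quality-control filters
#'
#' Runs \code{\link{trim_rt_range}}, \code{\link{blank_fold_change_filter}}
#' (skipped with a message when the table carries no blanks and
#' \code{require_blanks = FALSE}) and \code{\link{rsd_filter}}. The filters
#' are independent per-feature predicates, so the surviving set does not
#' depend on their order.
#'
#' @inheritParams trim_rt_range
#' @param require_blanks error (default) or skip the fold-change filter when
#'   no blank samples are present.
#' @return Filtered \code{feature_table}.
#' @export
qc_filter <- function(table, cfg = filter_config(), require_blanks = TRUE) {
  out <- trim_rt_range(table, cfg)
  if (length(blank_cols(table)) > 0) {
    out <- blank_fold_change_filter(out, cfg)
  } else if (require_blanks) {
    stop("no blank samples: pass require_blanks = FALSE to skip the ",
         "fold-change filter")
  }
  rsd_filter(out, cfg)
}
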