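#' Link features across ionization polarities
#'
#' A compound ionizing in both modes appears as [M+H]+ in positive and
#' [M-H]- in negative mode, so its two features differ by two proton masses
#' (about 2.015 Da, the nominal "2.02 Da" at two decimals) and co-elute.
#' Every positive/negative feature pair whose m/z difference falls inside
#' \code{pmd_nominal +/- pmd_window} and whose RT difference is at most
#' \code{rt_tol} (inclusive) is reported; one feature may take part in
#' several links. The linkage is only meaningful when both tables come from
#' the same chromatography column and gradient.
#'
#' @param pos_table,neg_table quality-filtered \code{feature_table}s from
#'   positive and negative mode.
#' @param pmd_nominal center of the accepted m/z difference window, Da. The
#'   default 2.0151 sits midway between the proton-pair difference with
#'   (2.01455) and without (2.01565) the electron-mass correction.
#' @param pmd_window half-width of the window, Da. The default 0.011 covers
#'   both conventions as well as values rounding to 2.02.
#' @param rt_tol maximum absolute RT difference, seconds (inclusive).
#' @return data.frame with columns \code{pos_id}, \code{neg_id},
#'   \code{mz_pos}, \code{mz_neg}, \code{delta_mz}, \code{rt_pos},
#'   \code{rt_neg}, \code{delta_rt}, sorted by positive-mode RT then m/z.
#' @export
link_polarities <- function(pos_table, neg_table, pmd_nominal = 2.0151,
                            pmd_window = 0.011, rt_tol = 10) {
  pos <- pos_table$features
  neg <- neg_table$features
  lo <- pmd_nominal - pmd_window
  hi <- pmd_nominal + pmd_window
  out <- list()
  for (i in seq_len(nrow(pos))) {
    dmz <- pos$mz[i] - neg$mz
    drt <- pos$rt[i] - neg$rt
    hit <- which(dmz >= lo & dmz <= hi & abs(drt) <= rt_tol)
    if (length(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        pos_id = pos$id[i], neg_id = neg$id[hit],
        mz_pos = pos$mz[i], mz_neg = neg$mz[hit],
        delta_mz = dmz[hit],
        rt_pos = pos$rt[i], rt_neg = neg$rt[hit],
        delta_rt = drt[hit], stringsAsFactors = FALSE)
    }
  }
  links <- if (length(out)) do.call(rbind, out) else
    data.frame(pos_id = character(0), neg_id = character(0),
               mz_pos = numeric(0), mz_neg = numeric(0),
               delta_mz = numeric(0), rt_pos = numeric(0),
               rt_neg = numeric(0), delta_rt = numeric(0))
  links <- links[order(links$rt_pos, links$mz_pos, links$mz_neg), ,
                 drop = FALSE]
  rownames(links) <- NULL
  links
}
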