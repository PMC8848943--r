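#' Configuration for the synthetic-dataset generator
#'
#' Describes a ground-truth LC-HRMS experiment emulating the statistical
#' structure the workflow assumes: compounds eluting in discrete
#' chromatographic bands, each emitting a protonated base ion plus redundant
#' ions at characteristic mass offsets (sodium adduct, water loss,
#' carbon-13 isotopologue) with tightly correlated intensity profiles
#' across study samples; blank background; and uninformative background
#' features designed to fail the quality filters.
#'
#' The intensity model is multiplicative-lognormal on three levels: a
#' per-compound abundance, a per-(compound, sample) factor shared by all
#' ions of the compound (between-sample abundance variation, CV
#' \code{bio_cv}, compounded with spray/matrix fluctuation, CV
#' \code{noise_cv} -- both act on the whole compound at once), and a small
#' independent per-ion measurement noise (CV \code{ion_cv}). The shared
#' factor dominating the independent one is what makes within-compound
#' Pearson correlations approach 1 while replicate RSD stays well inside
#' the 30 percent QC limit.
#'
#' @param n_compounds number of true compounds per polarity.
#' @param ions_per_compound ions per compound (base ion plus
#'   \code{ions_per_compound - 1} offsets drawn from \code{offset_table}).
#' @param n_study,n_blank numbers of study and blank samples.
#' @param rt_range retention-time range, seconds.
#' @param mz_range base-ion m/z range, Da.
#' @param offset_table data.frame (\code{offset} Da, \code{label}) of
#'   redundant-ion mass offsets relative to the base ion.
#' @param noise_cv per-sample multiplicative noise CV shared by a
#'   compound's ions.
#' @param bio_cv between-sample compound abundance CV (shared likewise).
#' @param ion_cv independent per-ion measurement noise CV.
#' @param background_features number of background features (half fail the
#'   blank fold-change filter, half the RSD filter).
#' @param band_spacing spacing of elution bands, seconds; must exceed the
#'   RT grouping cutoff so bands stay resolvable.
#' @param share_fraction fraction of compounds present in both polarities.
#' @param decoy_fraction fraction of compounds accompanied by a decoy ion:
#'   a feature at a high-frequency offset from the base ion but with an
#'   independent abundance profile, the case correlation pruning exists
#'   for.
#' @param seed integer seed; all randomness in the generator flows from it.
#' @return An object of class \code{synth_config}.
#' @export
synth_config <- function(n_compounds = 300, ions_per_compound = 3,
                         n_study = 5, n_blank = 5,
                         rt_range = c(30, 930), mz_range = c(100, 1000),
                         offset_table = data.frame(
                           offset = c(21.9819, -18.0106, 1.0034),
                           label = c("Na adduct", "water loss",
                                     "13C isotope"),
                           stringsAsFactors = FALSE),
                         noise_cv = 0.05, bio_cv = 0.10, ion_cv = 0.005,
                         background_features = 200, band_spacing = 15,
                         share_fraction = 0.3, decoy_fraction = 0,
                         seed = 1) {
  stopifnot(n_compounds >= 1, ions_per_compound >= 1,
            ions_per_compound <= nrow(offset_table) + 1,
            n_study >= 1, n_blank >= 0,
            rt_range[1] < rt_range[2], mz_range[1] < mz_range[2],
            noise_cv > 0, noise_cv < 0.30,
            share_fraction >= 0, share_fraction <= 1,
            decoy_fraction >= 0, decoy_fraction <= 1)
  margin <- max(abs(offset_table$offset)) + 5
  if (mz_range[2] - mz_range[1] <= 2 * margin) {
    stop("mz_range too narrow for the configured ion offsets")
  }
  structure(list(n_compounds = n_compounds,
                 ions_per_compound = ions_per_compound,
                 n_study = n_study, n_blank = n_blank,
                 rt_range = rt_range, mz_range = mz_range,
                 offset_table = offset_table,
                 noise_cv = noise_cv, bio_cv = bio_cv, ion_cv = ion_cv,
                 background_features = background_features,
                 band_spacing = band_spacing,
                 share_fraction = share_fraction,
                 decoy_fraction = decoy_fraction,
                 seed = seed),
            class = "synth_config")
}

# Lognormal deviates with unit mean and the given coefficient of variation.
rlnorm_cv <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Elution-band centers: evenly spaced across rt_range with a small jitter,
# spacing > RT grouping cutoff so single-linkage grouping resolves bands.
band_centers <- function(rt_range, spacing) {
  n <- floor((rt_range[2] - rt_range[1]) / spacing)
  rt_range[1] + spacing * (seq_len(n) - 0.5)
}

#' Simulate a paired positive/negative-mode MS1 dataset with ground truth
#'
#' Generates feature tables for both ionization polarities plus the truth
#' map needed for parameter-recovery testing. Compounds are laid out on
#' elution bands; each emits its base ion and randomly chosen redundant-ion
#' offsets sharing its retention time (jitter below 1 s) and its per-sample
#' intensity profile. A \code{share_fraction} of compounds appears in both
#' polarities at an m/z difference of 2.0157 Da (small jitter) and an RT
#' shift below 2 s. Background features either mirror their blank
#' intensities (failing the fold-change filter) or fluctuate with high CV
#' (failing the RSD filter). Base m/z values are resampled whenever an
#' accidental cross-polarity pair would mimic a true link, so the truth map
#' is the complete list of linkable pairs.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @return List with \code{pos}, \code{neg} (both \code{feature_table})
#'   and \code{truth}: \code{feature_map} (data.frame \code{feature_id},
#'   \code{polarity}, \code{compound}, \code{ion}, \code{is_background},
#'   \code{is_decoy}), \code{fragments} (named list compound -> data.frame
#'   \code{mz}, \code{intensity}), \code{shared} (data.frame
#'   \code{compound}, \code{pos_base_id}, \code{neg_base_id}) and
#'   \code{most_intense_ion} (named character, compound+polarity ->
#'   feature id).
#' @export
simulate_dataset <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, simulate_dataset_impl(cfg))
}

simulate_dataset_impl <- function(cfg) {
  centers <- band_centers(cfg$rt_range, cfg$band_spacing)
  n_shared <- round(cfg$share_fraction * cfg$n_compounds)
  sample_names <- c(sprintf("study_%d", seq_len(cfg$n_study)),
                    if (cfg$n_blank > 0) sprintf("blank_%d",
                                                 seq_len(cfg$n_blank)))
  roles <- c(rep("study", cfg$n_study), rep("blank", cfg$n_blank))

  make_polarity <- function(polarity, compounds, base_mz, base_rt) {
    n <- length(compounds)
    abund <- rlnorm(n, meanlog = log(1e6), sdlog = 1)
    shared_cv <- sqrt(cfg$bio_cv^2 + cfg$noise_cv^2)
    rows <- list()
    feature_map <- list()
    most_intense <- character(0)
    counter <- 0L
    for (k in seq_len(n)) {
      n_extra <- cfg$ions_per_compound - 1L
      offs <- if (n_extra > 0) {
        sample.int(nrow(cfg$offset_table), n_extra)
      } else {
        integer(0)
      }
      ion_mz <- c(base_mz[k], base_mz[k] + cfg$offset_table$offset[offs])
      ion_lab <- c("base", cfg$offset_table$label[offs])
      ratios <- c(1, runif(n_extra, 0.2, 0.7))
      ion_rt <- base_rt[k] + runif(length(ion_mz), -0.5, 0.5)
      comp_factor <- rlnorm_cv(cfg$n_study, shared_cv)
      for (j in seq_along(ion_mz)) {
        counter <- counter + 1L
        fid <- sprintf("%s_C%03d_%d", polarity, k, j)
        study <- abund[k] * ratios[j] * comp_factor *
          rlnorm_cv(cfg$n_study, cfg$ion_cv)
        blank <- rep(0, cfg$n_blank)
        rows[[length(rows) + 1L]] <- list(
          id = fid, mz = ion_mz[j], rt = ion_rt[j],
          intensity = c(study, blank))
        feature_map[[length(feature_map) + 1L]] <- data.frame(
          feature_id = fid, polarity = polarity,
          compound = compounds[k], ion = ion_lab[j],
          is_background = FALSE, is_decoy = FALSE,
          stringsAsFactors = FALSE)
        if (j == 1L) most_intense[compounds[k]] <- fid
      }
      if (runif(1) < cfg$decoy_fraction) {
        counter <- counter + 1L
        fid <- sprintf("%s_D%03d", polarity, k)
        decoy_abund <- rlnorm(1, meanlog = log(1e5), sdlog = 1)
        study <- decoy_abund * rlnorm_cv(cfg$n_study, shared_cv) *
          rlnorm_cv(cfg$n_study, cfg$ion_cv)
        rows[[length(rows) + 1L]] <- list(
          id = fid, mz = base_mz[k] + 21.9819,
          rt = base_rt[k] + runif(1, -0.5, 0.5),
          intensity = c(study, rep(0, cfg$n_blank)))
        feature_map[[length(feature_map) + 1L]] <- data.frame(
          feature_id = fid, polarity = polarity,
          compound = sprintf("decoy_%s_%03d", polarity, k), ion = "decoy",
          is_background = FALSE, is_decoy = TRUE,
          stringsAsFactors = FALSE)
      }
    }
    # background features: half blank-mirrored, half high-CV
    nb <- cfg$background_features
    if (nb > 0) {
      bg_band <- sample(centers, nb, replace = TRUE)
      bg_rt <- bg_band + runif(nb, -1.5, 1.5)
      bg_mz <- runif(nb, cfg$mz_range[1], cfg$mz_range[2])
      bg_level <- rlnorm(nb, meanlog = log(1e5), sdlog = 1)
      for (k in seq_len(nb)) {
        fid <- sprintf("%s_BG%03d", polarity, k)
        if (k <= nb / 2) {           # blank-like: fails fold change
          study <- bg_level[k] * rlnorm_cv(cfg$n_study, cfg$noise_cv)
          blank <- bg_level[k] * rlnorm_cv(cfg$n_blank, cfg$noise_cv)
        } else {                     # irreproducible: fails RSD
          study <- bg_level[k] * rlnorm_cv(cfg$n_study, 1.5)
          blank <- rep(0, cfg$n_blank)
        }
        rows[[length(rows) + 1L]] <- list(
          id = fid, mz = bg_mz[k], rt = bg_rt[k],
          intensity = c(study, blank))
        feature_map[[length(feature_map) + 1L]] <- data.frame(
          feature_id = fid, polarity = polarity,
          compound = NA_character_, ion = NA_character_,
          is_background = TRUE, is_decoy = FALSE,
          stringsAsFactors = FALSE)
      }
    }
    feats <- data.frame(
      id = vapply(rows, `[[`, character(1), "id"),
      mz = vapply(rows, `[[`, numeric(1), "mz"),
      rt = vapply(rows, `[[`, numeric(1), "rt"),
      stringsAsFactors = FALSE)
    inten <- do.call(rbind, lapply(rows, `[[`, "intensity"))
    colnames(inten) <- sample_names
    list(table = feature_table(feats, inten, roles),
         feature_map = do.call(rbind, feature_map),
         most_intense = most_intense)
  }

  # compound layout ---------------------------------------------------------
  pos_compounds <- sprintf("cmpd_%03d", seq_len(cfg$n_compounds))
  shared <- pos_compounds[seq_len(n_shared)]
  n_neg_only <- cfg$n_compounds - n_shared
  neg_only <- if (n_neg_only > 0) {
    sprintf("cmpd_n%03d", seq_len(n_neg_only))
  } else {
    character(0)
  }
  margin <- max(abs(cfg$offset_table$offset)) + 5
  draw_mz <- function(n) {
    runif(n, cfg$mz_range[1] + margin, cfg$mz_range[2] - margin)
  }
  pos_band <- sample(centers, cfg$n_compounds, replace = TRUE)
  pos_rt <- pos_band + runif(cfg$n_compounds, -1.5, 1.5)
  pos_mz <- draw_mz(cfg$n_compounds)
  neg_compounds <- c(shared, neg_only)
  neg_rt <- c(pos_rt[seq_len(n_shared)] + runif(n_shared, -2, 2),
              sample(centers, n_neg_only, replace = TRUE) +
                runif(n_neg_only, -1.5, 1.5))
  neg_mz <- c(pos_mz[seq_len(n_shared)] - 2.0157 +
                runif(n_shared, -0.003, 0.003),
              draw_mz(n_neg_only))
  # resample base m/z wherever an accidental co-eluting cross-polarity
  # pair would fall into the linkage window without sharing a compound,
  # so the truth map stays the complete list of linkable pairs
  for (pass in 1:25) {
    clash <- polarity_clashes(pos_mz, pos_rt, pos_compounds,
                              neg_mz, neg_rt, neg_compounds,
                              cfg$offset_table$offset)
    if (length(clash) == 0) break
    for (j in clash) {
      if (j <= n_shared) {
        # redraw the pair together so the true link survives
        pos_mz[j] <- draw_mz(1)
        neg_mz[j] <- pos_mz[j] - 2.0157 + runif(1, -0.003, 0.003)
      } else {
        neg_mz[j] <- draw_mz(1)
      }
    }
  }

  pos <- make_polarity("pos", pos_compounds, pos_mz, pos_rt)
  neg <- make_polarity("neg", neg_compounds, neg_mz, neg_rt)

  fragments <- lapply(
    stats::setNames(nm = unique(c(pos_compounds, neg_compounds))),
    function(cmp) {
      nf <- sample(5:10, 1)
      data.frame(mz = sort(runif(nf, 50, 400)),
                 intensity = rlnorm(nf, meanlog = log(1e4), sdlog = 0.8))
    })

  truth <- list(
    feature_map = rbind(pos$feature_map, neg$feature_map),
    fragments = fragments,
    shared = data.frame(
      compound = shared,
      pos_base_id = sprintf("pos_C%03d_1", seq_len(n_shared)),
      neg_base_id = sprintf("neg_C%03d_1", seq_len(n_shared)),
      stringsAsFactors = FALSE),
    most_intense_ion = c(
      stats::setNames(pos$most_intense,
                      paste0("pos.", names(pos$most_intense))),
      stats::setNames(neg$most_intense,
                      paste0("neg.", names(neg$most_intense)))))
  list(pos = pos$table, neg = neg$table, truth = truth)
}

# Indices into the negative-mode compound vector whose base or redundant
# ions could link (m/z difference near two proton masses, RT within
# tolerance plus slack) to a positive-mode ion of a different compound.
polarity_clashes <- function(pos_mz, pos_rt, pos_cmp,
                             neg_mz, neg_rt, neg_cmp, offsets,
                             window = c(1.995, 2.045), rt_slack = 16) {
  ion_offsets <- c(0, offsets)
  # every pairwise difference between a positive and a negative ion offset
  off_diff <- as.vector(outer(ion_offsets, ion_offsets, "-"))
  clash <- integer(0)
  for (j in seq_along(neg_mz)) {
    near <- which(abs(pos_rt - neg_rt[j]) <= rt_slack &
                    pos_cmp != neg_cmp[j])
    if (length(near) == 0) next
    dmz <- outer(pos_mz[near] - neg_mz[j], off_diff, "+")
    if (any(dmz >= window[1] & dmz <= window[2])) {
      clash <- c(clash, j)
    }
  }
  clash
}

#' Simulate repeated MS2 scans for precursor targets
#'
#' For each target, \code{n_scans_per_target} fragment scans are generated
#' at the target's retention time. A target whose feature id maps to a
#' ground-truth compound receives that compound's true fragment list with
#' m/z jitter below 2 ppm and lognormal intensity noise; per scan, spurious
#' single-scan fragments are added at rate \code{spurious_rate} (expected
#' spurious peaks per true peak). A target absent from the truth map
#' receives random fragments (a negative control).
#'
#' @param precursors data.frame with columns \code{id}, \code{mz},
#'   \code{rt}.
#' @param truth the truth object from \code{\link{simulate_dataset}}.
#' @param n_scans_per_target scans per target.
#' @param spurious_rate expected spurious fragments per true fragment per
#'   scan.
#' @param seed integer seed.
#' @return List of \code{\link{ms2_scan}} objects,
#'   \code{n_scans_per_target} per precursor, with \code{source_run} set to
#'   \code{"sim"}.
#' @export
simulate_ms2_runs <- function(precursors, truth, n_scans_per_target = 5,
                              spurious_rate = 0.1, seed = 1) {
  fm <- truth$feature_map
  with_seed(seed, {
    scans <- list()
    for (i in seq_len(nrow(precursors))) {
      cmp <- fm$compound[match(precursors$id[i], fm$feature_id)]
      frag <- if (!is.na(cmp) && cmp %in% names(truth$fragments)) {
        truth$fragments[[cmp]]
      } else {
        data.frame(mz = sort(runif(6, 50, 400)),
                   intensity = rlnorm(6, log(1e3), 1))
      }
      for (s in seq_len(n_scans_per_target)) {
        mz <- frag$mz * (1 + runif(nrow(frag), -2e-6, 2e-6))
        int <- frag$intensity * rlnorm_cv(nrow(frag), 0.2)
        n_spur <- stats::rpois(1, spurious_rate * nrow(frag))
        if (n_spur > 0) {
          mz <- c(mz, runif(n_spur, 50, 450))
          int <- c(int, rlnorm(n_spur, log(500), 1))
        }
        scans[[length(scans) + 1L]] <- ms2_scan(
          precursor_mz = precursors$mz[i] + runif(1, -0.003, 0.003),
          rt = precursors$rt[i] + runif(1, -1, 1),
          fragments = cbind(mz, int), source_run = "sim")
      }
    }
    scans
  })
}

#' Score pipeline outputs against the simulation ground truth
#'
#' Computes the parameter-recovery metrics used to validate the workflow on
#' simulated data. Cluster purity is the fraction of clusters whose member
#' features map to a single compound (background features count as their
#' own singleton compounds; decoys count as impurities). Compound recall is
#' the fraction of true compounds contributing at least one elected
#' precursor; precursor correctness the fraction of precursors that are
#' their compound's most intense true ion. Link recall and precision score
#' a polarity-link table against the shared-compound map: a link is true
#' when its two features map to the same compound.
#'
#' @param clusters list of pruned ion clusters (precursors set), e.g. from
#'   \code{\link{pmd_workflow}}.
#' @param precursors precursor data.frame from
#'   \code{\link{select_precursors}}.
#' @param truth the truth object from \code{\link{simulate_dataset}}.
#' @param polarity which polarity the clusters belong to.
#' @param links optional polarity-link data.frame from
#'   \code{\link{link_polarities}}.
#' @return List of metrics in [0, 1]: \code{cluster_purity},
#'   \code{compound_recall}, \code{precursor_correctness} and, when
#'   \code{links} is given, \code{link_recall} and \code{link_precision}.
#' @export
ground_truth_report <- function(clusters, precursors, truth,
                                polarity = "pos", links = NULL) {
  fm <- truth$feature_map[truth$feature_map$polarity == polarity, ]
  cmp_of <- stats::setNames(fm$compound, fm$feature_id)
  bg <- is.na(cmp_of)
  cmp_of[bg] <- names(cmp_of)[bg]   # background: one pseudo-compound each

  purity <- vapply(clusters, function(cl) {
    length(unique(cmp_of[cl$members])) == 1L
  }, logical(1))

  true_cmps <- unique(fm$compound[!fm$is_background & !fm$is_decoy])
  prec_cmp <- cmp_of[precursors$id]
  recall <- mean(true_cmps %in% prec_cmp)

  best <- truth$most_intense_ion[paste0(polarity, ".", prec_cmp)]
  correctness <- mean(precursors$id == best, na.rm = TRUE)

  out <- list(cluster_purity = mean(purity),
              compound_recall = recall,
              precursor_correctness = correctness)
  if (!is.null(links)) {
    all_cmp <- stats::setNames(truth$feature_map$compound,
                               truth$feature_map$feature_id)
    link_true <- !is.na(all_cmp[links$pos_id]) &
      !is.na(all_cmp[links$neg_id]) &
      all_cmp[links$pos_id] == all_cmp[links$neg_id]
    linked_cmps <- unique(all_cmp[links$pos_id[link_true]])
    out$link_precision <- if (nrow(links) == 0) NA_real_ else
      mean(link_true)
    out$link_recall <- mean(truth$shared$compound %in% linked_cmps)
  }
  out
}
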