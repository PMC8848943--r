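#' Group features by retention time
#'
#' Single-linkage clustering of features on retention time: two features
#' belong to the same group when they can be connected by a chain of
#' features with consecutive RT differences no larger than \code{rt_cutoff}.
#' In one dimension this is exactly the rule "start a new group at every
#' RT gap larger than the cutoff", so the assignment is independent of the
#' input row order. Co-eluting redundant ions (adducts, isotopologues,
#' neutral-loss fragments) of one compound fall into one group.
#'
#' @param table a \code{feature_table}.
#' @param rt_cutoff largest within-group RT gap, seconds.
#' @return An object of class \code{rt_groups}: list with \code{group}
#'   (integer group id per feature, in table order, numbered by ascending
#'   RT) and \code{rt_cutoff}.
#' @export
assign_rt_groups <- function(table, rt_cutoff = 10) {
  stopifnot(nrow(table$features) > 0, rt_cutoff > 0)
  rt <- table$features$rt
  ord <- order(rt)
  gaps <- diff(rt[ord]) > rt_cutoff
  grp_sorted <- cumsum(c(1L, as.integer(gaps)))
  group <- integer(length(rt))
  group[ord] <- grp_sorted
  structure(list(group = group, rt_cutoff = rt_cutoff), class = "rt_groups")
}

# Integer centi-Dalton key for a rounded PMD, so that set membership of
# rounded masses never depends on floating-point representation.
pmd_key <- function(pmd) as.integer(round_away(pmd, 2L) * 100 + 0.5)

#' Tally paired mass distances across retention-time groups
#'
#' For every unordered pair of co-eluting features (same RT group) the
#' paired mass distance (PMD) is the absolute m/z difference rounded to two
#' decimals. The frequency of a PMD is the number of RT groups containing at
#' least one pair at that distance -- each group counts once however many
#' pairs it contributes, so one abundant compound cannot inflate a PMD.
#' Recurrent PMDs betray systematic relations: 21.98 Da for sodium adducts,
#' 18.01 Da for water loss, 1.00 Da for carbon-13 isotopologues.
#'
#' @param table a \code{feature_table}.
#' @param groups result of \code{\link{assign_rt_groups}} on \code{table}.
#' @return data.frame with columns \code{pmd} (Da, 2 decimals) and
#'   \code{frequency}, sorted by descending frequency then ascending pmd.
#' @export
compute_pmd_frequency <- function(table, groups) {
  stopifnot(inherits(groups, "rt_groups"),
            length(groups$group) == nrow(table$features))
  mz <- table$features$mz
  per_group <- split(mz, groups$group)
  keys <- unlist(lapply(per_group, function(v) {
    if (length(v) < 2) return(integer(0))
    d <- abs(outer(v, v, "-"))
    unique(pmd_key(d[upper.tri(d)]))
  }), use.names = FALSE)
  if (length(keys) == 0) {
    return(data.frame(pmd = numeric(0), frequency = integer(0)))
  }
  tab <- table(keys)
  pmd <- as.integer(names(tab)) / 100
  freq <- as.integer(tab)
  ord <- order(-freq, pmd)
  data.frame(pmd = pmd[ord], frequency = freq[ord])
}

#' Select the high-frequency paired mass distances
#'
#' With an explicit cutoff, returns every PMD whose frequency reaches it.
#' Without one, the cutoff is chosen automatically at the largest drop in
#' the frequency sequence sorted descending (the elbow of the frequency
#' curve), never admitting PMDs observed in fewer than two RT groups: a
#' distance seen once carries no evidence of a systematic relation.
#'
#' @param records data.frame from \code{\link{compute_pmd_frequency}}.
#' @param freq_cutoff minimum frequency, or \code{NULL} for automatic elbow
#'   selection.
#' @return Numeric vector of selected PMD values (Da, 2 decimals).
#' @export
select_high_frequency_pmds <- function(records, freq_cutoff = NULL) {
  if (nrow(records) == 0) return(numeric(0))
  freq <- sort(records$frequency, decreasing = TRUE)
  if (is.null(freq_cutoff)) {
    drops <- freq - c(freq[-1], 0L)
    cut_at <- which.max(drops)
    freq_cutoff <- max(freq[cut_at], 2L)
  }
  sort(records$pmd[records$frequency >= freq_cutoff])
}

#' Collapse redundant peaks into independent peaks
#'
#' Within each retention-time group, features are connected when their PMD
#' is one of the selected high-frequency distances. Every connected
#' component of this relation is read as the ion set of one putative
#' compound; its independent peak is the member with the highest mean study
#' intensity (ties broken by lower m/z). Features pairing with nothing are
#' their own singleton component and independent peak.
#'
#' @param table a \code{feature_table}.
#' @param groups result of \code{\link{assign_rt_groups}}.
#' @param high_pmds numeric vector of high-frequency PMDs (Da, 2 decimals);
#'   empty means every feature is independent.
#' @return List with \code{independent} (character vector of feature ids)
#'   and \code{components} (list of character vectors, the ids of each
#'   component; parallel to \code{independent}).
#' @export
reduce_redundant_peaks <- function(table, groups, high_pmds) {
  ids <- table$features$id
  mz <- table$features$mz
  inten <- study_means(table)
  keyset <- pmd_key(high_pmds)
  independent <- character(0)
  components <- list()
  for (g in split(seq_along(ids), groups$group)) {
    membership <- seq_along(g)
    if (length(g) > 1 && length(keyset) > 0) {
      pairs <- combn(seq_along(g), 2)
      edge <- pmd_key(abs(mz[g[pairs[1, ]]] - mz[g[pairs[2, ]]])) %in% keyset
      if (any(edge)) {
        gr <- igraph::make_empty_graph(n = length(g), directed = FALSE)
        gr <- igraph::add_edges(gr, rbind(pairs[1, edge], pairs[2, edge]))
        membership <- igraph::components(gr)$membership
      }
    }
    for (members in split(g, membership)) {
      best <- members[order(-inten[members], mz[members])][1]
      independent <- c(independent, ids[best])
      components[[length(components) + 1L]] <- ids[members]
    }
  }
  ord <- order(match(independent, ids))
  list(independent = independent[ord], components = components[ord])
}

#' Build pseudo-spectra and merge overlapping clusters
#'
#' Turns each component into an ion cluster (pseudo-spectrum) whose base
#' peak is its independent peak, then merges clusters that share any member
#' feature -- when two independent peaks are linked to the same paired ions
#' they are read as one compound. The merged cluster keeps the most intense
#' of the merged base peaks (ties broken by lower m/z).
#'
#' @param independent,components result of
#'   \code{\link{reduce_redundant_peaks}} (or any parallel list of base
#'   peaks and member-id sets).
#' @param table the \code{feature_table} the components were derived from
#'   (supplies intensities for the merged-base election).
#' @return List of ion clusters, each a list with \code{members} (character
#'   vector), \code{base_peak} (id) and \code{precursor} (\code{NA} until
#'   \code{\link{select_precursors}}).
#' @export
build_and_merge_clusters <- function(independent, components, table) {
  stopifnot(length(independent) == length(components))
  n <- length(components)
  if (n == 0) return(list())
  membership <- data.frame(
    cluster = rep(seq_len(n), lengths(components)),
    id = unlist(components),
    stringsAsFactors = FALSE
  )
  # Clusters sharing a feature id are vertices joined through that id;
  # connected components of the overlap graph give the merged clusters.
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("c", membership$cluster),
               to = paste0("f", membership$id)),
    directed = FALSE
  )
  comp <- igraph::components(g)$membership
  cluster_comp <- comp[paste0("c", seq_len(n))]
  inten <- study_means(table)
  mz <- structure(table$features$mz, names = table$features$id)
  out <- lapply(split(seq_len(n), cluster_comp), function(cl) {
    members <- sort(unique(unlist(components[cl])))
    bases <- unique(independent[cl])
    base <- bases[order(-inten[bases], mz[bases])][1]
    list(members = members, base_peak = base, precursor = NA_character_)
  })
  names(out) <- NULL
  # deterministic order: by RT then m/z of the base peak
  rt <- structure(table$features$rt, names = table$features$id)
  base_ids <- vapply(out, `[[`, character(1), "base_peak")
  out[order(rt[base_ids], mz[base_ids])]
}

#' Prune weakly correlated members from an ion cluster
#'
#' Ions of one compound co-vary across study samples; a member whose
#' Pearson correlation with the base peak's study-intensity vector falls
#' below \code{r_min} is excluded as an unrelated co-eluting peak. The base
#' peak itself is always retained. Members with a zero-variance intensity
#' vector have no defined correlation and are removed with a warning. With
#' fewer than three study samples the correlation is meaningless and
#' pruning is skipped with a warning.
#'
#' @param cluster an ion cluster (see \code{\link{build_and_merge_clusters}}).
#' @param table a \code{feature_table}.
#' @param r_min minimum Pearson correlation (boundary retained).
#' @return The pruned cluster.
#' @export
prune_by_correlation <- function(cluster, table, r_min = 0.9) {
  sc <- study_cols(table)
  if (length(sc) < 3) {
    warning("fewer than 3 study samples: correlation pruning skipped")
    return(cluster)
  }
  m <- table$intensities[, sc, drop = FALSE]
  base_v <- m[cluster$base_peak, ]
  keep <- vapply(cluster$members, function(id) {
    if (id == cluster$base_peak) return(TRUE)
    v <- m[id, ]
    if (sd(v) == 0 || sd(base_v) == 0) {
      warning("zero-variance intensity vector for '", id,
              "': member removed")
      return(FALSE)
    }
    cor(v, base_v) >= r_min
  }, logical(1))
  cluster$members <- cluster$members[keep]
  cluster
}

#' Elect one precursor ion per cluster
#'
#' The precursor targeted for MS/MS is the cluster member with the highest
#' mean study intensity (ties broken by lower m/z).
#'
#' @param clusters list of (pruned) ion clusters.
#' @param table a \code{feature_table}.
#' @return data.frame with one row per cluster: \code{id}, \code{mz},
#'   \code{rt}, \code{intensity} (mean study intensity), sorted by RT then
#'   m/z. The input clusters are returned with their \code{precursor} field
#'   set in the attribute \code{"clusters"}.
#' @export
select_precursors <- function(clusters, table) {
  if (any(lengths(lapply(clusters, `[[`, "members")) == 0)) {
    stop("empty cluster: upstream invariant violated")
  }
  inten <- study_means(table)
  feat <- table$features
  rows <- lapply(clusters, function(cl) {
    best <- cl$members[order(-inten[cl$members],
                             feat$mz[match(cl$members, feat$id)])][1]
    i <- match(best, feat$id)
    data.frame(id = best, mz = feat$mz[i], rt = feat$rt[i],
               intensity = unname(inten[best]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  clusters <- Map(function(cl, p) { cl$precursor <- p; cl },
                  clusters, out$id)
  ord <- order(out$rt, out$mz)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "clusters") <- clusters[ord]
  out
}

#' Run the full redundant-peak reduction and precursor election
#'
#' Convenience wrapper chaining \code{\link{assign_rt_groups}},
#' \code{\link{compute_pmd_frequency}},
#' \code{\link{select_high_frequency_pmds}},
#' \code{\link{reduce_redundant_peaks}},
#' \code{\link{build_and_merge_clusters}},
#' \code{\link{prune_by_correlation}} and \code{\link{select_precursors}}
#' on a quality-filtered feature table.
#'
#' @param table a quality-filtered \code{feature_table}.
#' @param rt_cutoff RT grouping cutoff, seconds.
#' @param freq_cutoff PMD frequency cutoff, or \code{NULL} for the elbow.
#' @param r_min correlation-pruning threshold; \code{NA} disables pruning.
#' @return List with \code{groups}, \code{pmd_records}, \code{high_pmds},
#'   \code{independent}, \code{clusters} (pruned, with precursors set) and
#'   \code{precursors} (the data.frame from
#'   \code{\link{select_precursors}}).
#' @export
pmd_workflow <- function(table, rt_cutoff = 10, freq_cutoff = NULL,
                         r_min = 0.9) {
  groups <- assign_rt_groups(table, rt_cutoff)
  records <- compute_pmd_frequency(table, groups)
  high <- select_high_frequency_pmds(records, freq_cutoff)
  red <- reduce_redundant_peaks(table, groups, high)
  clusters <- build_and_merge_clusters(red$independent, red$components, table)
  if (!is.na(r_min) && length(study_cols(table)) >= 3) {
    clusters <- lapply(clusters, prune_by_correlation, table = table,
                       r_min = r_min)
  }
  precursors <- select_precursors(clusters, table)
  list(groups = groups, pmd_records = records, high_pmds = high,
       independent = red$independent,
       clusters = attr(precursors, "clusters"),
       precursors = precursors)
}

#' Write ion clusters to JSON
#'
#' One record per cluster: \code{cluster_id}, \code{base_peak},
#' \code{precursor} and the member list with each member's m/z, RT and PMD
#' to the base peak.
#'
#' @param clusters list of ion clusters (with precursors set).
#' @param table a \code{feature_table}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_clusters_json <- function(clusters, table, path) {
  feat <- table$features
  recs <- lapply(seq_along(clusters), function(k) {
    cl <- clusters[[k]]
    base_mz <- feat$mz[match(cl$base_peak, feat$id)]
    i <- match(cl$members, feat$id)
    list(cluster_id = k,
         base_peak = cl$base_peak,
         precursor = cl$precursor,
         members = data.frame(
           id = cl$members, mz = feat$mz[i], rt = feat$rt[i],
           pmd_to_base = round_away(abs(feat$mz[i] - base_mz), 2L),
           stringsAsFactors = FALSE))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
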