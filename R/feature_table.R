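#' Construct an MS1 feature table
#'
#' The feature table is the substrate of every MS1 stage of the workflow: a
#' set of aligned LC-MS features (m/z, retention time) with one intensity per
#' sample, and a role (\code{"study"} or \code{"blank"}) for each sample.
#'
#' @param features data.frame with columns \code{id} (unique character),
#'   \code{mz} (Da, > 0) and \code{rt} (seconds, >= 0).
#' @param intensities numeric matrix, features x samples, non-negative.
#' @param roles character vector of sample roles, one per column of
#'   \code{intensities}, each \code{"study"} or \code{"blank"}. Column names
#'   of \code{intensities} give the sample names.
#'
#' @return An object of class \code{feature_table}: a list with elements
#'   \code{features} (data.frame), \code{samples} (data.frame with
#'   \code{name}, \code{role}) and \code{intensities} (matrix).
#' @export
feature_table <- function(features, intensities, roles) {
  stopifnot(is.data.frame(features),
            all(c("id", "mz", "rt") %in% names(features)))
  features$id <- as.character(features$id)
  if (anyDuplicated(features$id)) {
    stop("feature ids must be unique")
  }
  if (any(features$mz <= 0) || any(features$rt < 0)) {
    stop("features require mz > 0 and rt >= 0")
  }
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (nrow(intensities) != nrow(features)) {
    stop("intensity matrix must have one row per feature")
  }
  if (is.null(colnames(intensities))) {
    stop("intensity matrix must carry sample names as column names")
  }
  if (anyDuplicated(colnames(intensities))) {
    stop("sample names must be unique")
  }
  if (length(roles) != ncol(intensities)) {
    stop("one role per sample required")
  }
  roles <- match.arg(as.character(roles), c("study", "blank"),
                     several.ok = TRUE)
  if (any(is.na(intensities)) || any(intensities < 0)) {
    stop("intensities must be non-negative and non-missing")
  }
  rownames(intensities) <- features$id
  structure(
    list(
      features = features[, c("id", "mz", "rt")],
      samples = data.frame(name = colnames(intensities), role = roles,
                           stringsAsFactors = FALSE),
      intensities = intensities
    ),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  ns <- table(factor(x$samples$role, levels = c("study", "blank")))
  cat(sprintf("MS1 feature table: %d features, %d study + %d blank samples\n",
              nrow(x$features), ns[["study"]], ns[["blank"]]))
  cat(sprintf("  m/z %.4f-%.4f Da, RT %.1f-%.1f s\n",
              min(x$features$mz), max(x$features$mz),
              min(x$features$rt), max(x$features$rt)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

# Column indices of study / blank samples.
study_cols <- function(table) which(table$samples$role == "study")
blank_cols <- function(table) which(table$samples$role == "blank")

#' Mean study-sample intensity per feature
#'
#' The intensity summary used throughout precursor election: the arithmetic
#' mean over study samples only (blanks never contribute after filtering).
#'
#' @param table a \code{feature_table}.
#' @return Named numeric vector, one mean per feature id.
#' @export
study_means <- function(table) {
  rowMeans(table$intensities[, study_cols(table), drop = FALSE])
}

# Subset a feature table by a logical or integer feature index.
subset_features <- function(table, keep) {
  feature_table(table$features[keep, , drop = FALSE],
                table$intensities[keep, , drop = FALSE],
                table$samples$role)
}

#' Read an MS1 feature table from CSV
#'
#' Expects a comma-delimited file with a header row containing \code{mz} and
#' \code{rt} columns (an \code{id} column is optional; ids are generated from
#' row order when absent) and one numeric column per sample. Missing
#' intensities are read as 0.
#'
#' @param path path to the CSV file.
#' @param role_map named character vector mapping sample column names to
#'   roles (\code{"study"} or \code{"blank"}). Samples absent from the map
#'   default to \code{"study"}.
#' @return A \code{feature_table}.
#' @export
read_feature_table <- function(path, role_map = NULL) {
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  lower <- tolower(names(raw))
  mz_col <- match("mz", lower)
  rt_col <- match("rt", lower)
  if (is.na(mz_col) || is.na(rt_col)) {
    stop("feature table must contain 'mz' and 'rt' columns")
  }
  if (nrow(raw) == 0) {
    stop("no features in ", path)
  }
  id_col <- match("id", lower)
  ids <- if (is.na(id_col)) sprintf("F%04d", seq_len(nrow(raw))) else
    as.character(raw[[id_col]])
  sample_cols <- setdiff(seq_along(raw), c(mz_col, rt_col, id_col))
  if (length(sample_cols) == 0) {
    stop("feature table has no sample columns")
  }
  inten <- raw[, sample_cols, drop = FALSE]
  for (j in seq_along(inten)) {
    v <- inten[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (any(is.na(vn) & !is.na(v) & nzchar(trimws(v)))) {
        stop("non-numeric intensity in sample column '",
             names(inten)[j], "'")
      }
      v <- vn
    }
    v[is.na(v)] <- 0
    inten[[j]] <- v
  }
  mz <- as.numeric(raw[[mz_col]])
  rt <- as.numeric(raw[[rt_col]])
  if (any(is.na(mz)) || any(is.na(rt))) {
    stop("non-numeric mz/rt values")
  }
  sample_names <- names(inten)
  roles <- rep("study", length(sample_names))
  if (!is.null(role_map)) {
    hit <- match(sample_names, names(role_map))
    roles[!is.na(hit)] <- unname(role_map[hit[!is.na(hit)]])
  }
  feature_table(data.frame(id = ids, mz = mz, rt = rt,
                           stringsAsFactors = FALSE),
                as.matrix(inten), roles)
}

#' Write an MS1 feature table to CSV
#'
#' Columns are written in a deterministic order: \code{id}, \code{mz},
#' \code{rt}, then samples in table order. Roles are not stored in the file;
#' they are re-applied through \code{role_map} on reading.
#'
#' @param table a \code{feature_table}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  out <- cbind(table$features,
               as.data.frame(table$intensities, check.names = FALSE))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Role map of a feature table
#'
#' Convenience accessor returning the named role vector accepted by
#' \code{\link{read_feature_table}}, so a table's roles survive a round trip
#' through CSV.
#'
#' @param table a \code{feature_table}.
#' @return Named character vector sample name -> role.
#' @export
role_map <- function(table) {
  structure(table$samples$role, names = table$samples$name)
}
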