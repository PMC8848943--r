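#' Schedule precursors into targeted-MS/MS injections
#'
#' Precursor targets are randomly assigned to injections such that within
#' every injection no retention-time interval of length \code{window}
#' (sliding, not binned) contains more than \code{max_per_window} targets --
#' the instrument cannot give adequate scan time to more co-eluting targets
#' than that. The algorithm shuffles the targets with the given seed, then
#' first-fit places each target into the lowest-index injection where the
#' density constraint still holds, opening a new injection when none fits.
#' This honors random assignment while guaranteeing a valid plan and an
#' injection count no larger than the trivial upper bound
#' \code{ceiling(n / max_per_window)}.
#'
#' @param precursors data.frame with columns \code{id}, \code{mz}, \code{rt}
#'   (seconds), as produced by \code{\link{select_precursors}}.
#' @param window RT window length, seconds (default 12 s = 0.2 min).
#' @param max_per_window maximum targets per window per injection.
#' @param seed integer seed for the random assignment order.
#' @return An object of class \code{injection_plan}: list with
#'   \code{injections} (list of data.frames \code{id}, \code{mz},
#'   \code{rt}, each sorted by RT), \code{window}, \code{max_per_window},
#'   \code{seed}.
#' @export
schedule_injections <- function(precursors, window = 12, max_per_window = 6,
                                seed = 1) {
  stopifnot(nrow(precursors) > 0, window > 0, max_per_window >= 1)
  ord <- with_seed(seed, sample.int(nrow(precursors)))
  rts <- list()   # sorted RT vectors, one per injection
  assign_to <- integer(nrow(precursors))
  for (i in ord) {
    rt <- precursors$rt[i]
    placed <- FALSE
    for (k in seq_along(rts)) {
      cand <- sort(c(rts[[k]], rt))
      if (!window_violated(cand, window, max_per_window)) {
        rts[[k]] <- cand
        assign_to[i] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rts[[length(rts) + 1L]] <- rt
      assign_to[i] <- length(rts)
    }
  }
  injections <- lapply(seq_along(rts), function(k) {
    inj <- precursors[assign_to == k, c("id", "mz", "rt"), drop = FALSE]
    inj <- inj[order(inj$rt, inj$mz), , drop = FALSE]
    rownames(inj) <- NULL
    inj
  })
  structure(list(injections = injections, window = window,
                 max_per_window = max_per_window, seed = seed),
            class = "injection_plan")
}

# TRUE when some sliding RT interval of length `window` holds more than
# `max_per_window` of the sorted retention times. Any violating interval
# can be slid until its left edge sits on a target, so checking intervals
# anchored at each target is exhaustive.
window_violated <- function(sorted_rt, window, max_per_window) {
  n <- length(sorted_rt)
  if (n <= max_per_window) return(FALSE)
  any(sorted_rt[(max_per_window + 1L):n] -
        sorted_rt[seq_len(n - max_per_window)] <= window)
}

#' @export
print.injection_plan <- function(x, ...) {
  cat(sprintf(
    "Injection plan: %d targets in %d injection(s) (max %d per %.1f s window)\n",
    sum(vapply(x$injections, nrow, integer(1))), length(x$injections),
    x$max_per_window, x$window))
  invisible(x)
}

#' Validate an injection plan by brute force
#'
#' Checks (1) that the plan's targets form a partition of the precursor
#' list (no duplicates, nothing missing) and (2) the sliding-window density
#' constraint, by examining every window anchored at every target of every
#' injection.
#'
#' @param plan an \code{injection_plan}.
#' @param precursors the precursor data.frame the plan was built from.
#' @return List with \code{pass} (logical), \code{partition_ok},
#'   \code{violations} (data.frame of offending windows: injection, window
#'   start, count) and \code{messages}.
#' @export
validate_plan <- function(plan, precursors) {
  planned <- unlist(lapply(plan$injections, `[[`, "id"))
  msgs <- character(0)
  partition_ok <- TRUE
  if (anyDuplicated(planned)) {
    partition_ok <- FALSE
    msgs <- c(msgs, "duplicate targets across injections")
  }
  if (!setequal(planned, precursors$id) ||
      length(planned) != nrow(precursors)) {
    partition_ok <- FALSE
    msgs <- c(msgs, "not a partition of the precursor list")
  }
  viol <- list()
  for (k in seq_along(plan$injections)) {
    rt <- sort(plan$injections[[k]]$rt)
    for (i in seq_along(rt)) {
      cnt <- sum(rt >= rt[i] & rt <= rt[i] + plan$window)
      if (cnt > plan$max_per_window) {
        viol[[length(viol) + 1L]] <- data.frame(
          injection = k, window_start = rt[i], count = cnt)
      }
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(injection = integer(0), window_start = numeric(0),
               count = integer(0))
  if (nrow(violations) > 0) {
    msgs <- c(msgs, sprintf("%d over-dense window(s)", nrow(violations)))
  }
  list(pass = partition_ok && nrow(violations) == 0,
       partition_ok = partition_ok, violations = violations,
       messages = msgs)
}

#' Export injection target lists as CSV files
#'
#' One file per injection (\code{injection_01.csv}, ...) with columns
#' \code{mz}, \code{rt_start}, \code{rt_end}, \code{id}, where the RT
#' bounds are the target RT plus/minus half the scheduling window, floored
#' at zero.
#'
#' @param plan an \code{injection_plan}.
#' @param out_dir output directory (created if absent).
#' @return Character vector of the files written.
#' @export
export_injection_lists <- function(plan, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory ", out_dir)
  }
  paths <- character(length(plan$injections))
  for (k in seq_along(plan$injections)) {
    inj <- plan$injections[[k]]
    out <- data.frame(
      mz = inj$mz,
      rt_start = pmax(0, inj$rt - plan$window / 2),
      rt_end = inj$rt + plan$window / 2,
      id = inj$id, stringsAsFactors = FALSE)
    paths[k] <- file.path(out_dir, sprintf("injection_%02d.csv", k))
    write.csv(out, paths[k], row.names = FALSE, quote = FALSE)
  }
  paths
}
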