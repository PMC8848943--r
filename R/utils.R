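#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor median rlnorm runif sd weighted.mean
#' @importFrom utils combn write.csv read.csv
NULL

# Round half away from zero at a fixed number of decimals. Used wherever a
# rounded mass value takes part in an equality comparison (PMD binning,
# two-decimal known-compound matching), where base R's round-half-to-even
# would make results depend on the binary representation of the input.
round_away <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Parts-per-million difference between two m/z values, relative to the
# smaller of the two (the stricter convention; stated once, used by both
# fragment clustering and MS1 linking).
ppm_diff <- function(mz1, mz2) {
  1e6 * abs(mz1 - mz2) / pmin(mz1, mz2)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All stochastic operations in the package
# funnel their seed through this helper so no global state leaks.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Electron-corrected proton mass, Da: the m/z shift between a neutral
# monoisotopic mass and its [M+H]+ / [M-H]- ions.
PROTON_MASS <- 1.00728

# [M+H]+ minus [M-H]- for one compound: two proton masses.
POS_NEG_DELTA <- 2 * PROTON_MASS
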