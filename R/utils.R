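#' Round half away from zero
#'
#' Decimal rounding in which exact halves move away from zero (so 0.895
#' becomes 0.90 at two decimals), the convention used when reporting kappa
#' statistics in text. A tiny guard absorbs binary representation error of
#' decimal inputs.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return rounded numeric vector.
#' @examples
#' round_half_up(0.895)  # 0.90, where round() would give 0.89
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Truncated normal draw via inverse-CDF; used for physiologically bounded
# covariates.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
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
    set.seed(seed)
  }
  force(code)
}
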