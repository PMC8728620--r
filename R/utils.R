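# Shared internal helpers: seeded RNG scopes, rounding/rendering conventions.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded simulators do not disturb the
#' caller's RNG stream. `seed = NULL` leaves the current stream untouched.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  expr
}

#' Derive independent sub-seeds from a master seed
#'
#' Every stochastic pipeline stage gets its own stream so that adding or
#' reordering stages does not silently change others. Sub-seeds stay below
#' 2^31 - 1.
#' @keywords internal
#' @noRd
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; screening reports conventionally round
#' half away from zero (92/16579 -> 0.55%, 2/3 -> 66.7%).
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Render a fraction as a percent string
#'
#' Half-away-from-zero rounding; 1 decimal by default, 2 decimals for rates
#' below 1% when `digits = NULL` (the convention used for sub-percent referral
#' rates).
#' @param x fraction in \[0, 1\]
#' @param digits decimal places, or `NULL` to pick 1 (>= 1%) or 2 (< 1%)
#' @return character vector like "0.55" (no percent sign)
#' @export
render_percent <- function(x, digits = NULL) {
  vapply(x, function(xi) {
    d <- if (is.null(digits)) (if (abs(xi) < 0.01) 2L else 1L) else digits
    formatC(round_half_up(100 * xi, d), format = "f", digits = d)
  }, character(1))
}

#' Render a prevalence as "1 in N"
#'
#' Counts of five or more digits are grouped with a thin space ("1 in 16 579");
#' four-digit counts are printed plain ("1 in 8290").
#' @param one_in_n positive integer (samples per case)
#' @return character scalar
#' @export
render_one_in <- function(one_in_n) {
  vapply(one_in_n, function(n) {
    if (is.na(n)) return("none observed")
    s <- if (n >= 1e4) formatC(n, format = "d", big.mark = " ") else formatC(n, format = "d")
    paste("1 in", s)
  }, character(1))
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Trapezoidal integral on a fixed grid
#' @keywords internal
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
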