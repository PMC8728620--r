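# First-tier population calling: normal range from the cohort's methylation
# distribution (mean +/- k SD) or fixed conservative bands, and referral flags.

#' Build a first-tier threshold set
#'
#' Two modes:
#' * `sd_rule`: normal range is `mean -/+ k * sd` of the screening population's
#'   methylation distribution, clipped to \[0, 1\]; values *strictly* outside
#'   are flagged.
#' * `conservative`: fixed disease bands, *inclusive*: low band at
#'   `ratio <= as_band_max`, high band at `ratio >= pws_band_min`.
#'
#' @param ratios methylation ratios of the screened population (sd_rule mode)
#' @param k number of SDs defining the normal range
#' @param mean,sd supply the distribution moments directly instead of `ratios`
#' @param min_n smallest population size accepted for sd_rule estimation
#' @param robust use median/MAD instead of mean/SD
#' @param mode `"sd_rule"` or `"conservative"`
#' @param as_band_max,pws_band_min conservative fixed bands
#' @return object of class `"threshold_set"`
#' @export
#' @examples
#' compute_thresholds(mean = 0.51, sd = 0.085, k = 3)  # lower 0.255, upper 0.765
compute_thresholds <- function(ratios = NULL, k = 3, mean = NULL, sd = NULL,
                               min_n = 100, robust = FALSE,
                               mode = c("sd_rule", "conservative"),
                               as_band_max = 0.12, pws_band_min = 0.88) {
  mode <- match.arg(mode)
  if (mode == "conservative") {
    stopifnot(as_band_max < pws_band_min)
    return(structure(
      list(mode = "conservative", mean = NA_real_, sd = NA_real_, k = NA_real_,
           lower = NA_real_, upper = NA_real_,
           as_band_max = as_band_max, pws_band_min = pws_band_min),
      class = "threshold_set"
    ))
  }
  stopifnot(k > 0)
  if (is.null(mean) || is.null(sd)) {
    if (is.null(ratios)) stop("supply ratios, or mean and sd")
    if (length(ratios) < min_n) {
      stop("fewer than ", min_n, " ratios: the population SD cannot be estimated ",
           "reliably; use fixed thresholds (mode = \"conservative\") instead")
    }
    if (robust) {
      mean <- stats::median(ratios)
      sd <- stats::mad(ratios)
    } else {
      mean <- base::mean(ratios)
      sd <- stats::sd(ratios)
    }
  }
  lower <- max(0, mean - k * sd)
  upper <- min(1, mean + k * sd)
  structure(
    list(mode = "sd_rule", mean = mean, sd = sd, k = k,
         lower = lower, upper = upper,
         as_band_max = as_band_max, pws_band_min = pws_band_min),
    class = "threshold_set"
  )
}

#' Conservative fixed thresholds (disease-band mode)
#' @param as_band_max low (AS) band upper edge, inclusive
#' @param pws_band_min high (PWS) band lower edge, inclusive
#' @return a `threshold_set` in conservative mode
#' @export
conservative_thresholds <- function(as_band_max = 0.12, pws_band_min = 0.88) {
  compute_thresholds(mode = "conservative",
                     as_band_max = as_band_max, pws_band_min = pws_band_min)
}

#' @export
print.threshold_set <- function(x, ...) {
  if (x$mode == "sd_rule") {
    cat(sprintf("First-tier thresholds (sd_rule, k = %g): normal range (%.4g, %.4g)\n",
                x$k, x$lower, x$upper))
    cat(sprintf("  population mean %.4g, SD %.4g; flags are strictly outside\n",
                x$mean, x$sd))
  } else {
    cat(sprintf("First-tier thresholds (conservative): low band <= %.3g, high band >= %.3g (inclusive)\n",
                x$as_band_max, x$pws_band_min))
  }
  invisible(x)
}

#' Call first-tier band membership for methylation ratios
#'
#' sd_rule flags strictly outside the normal range (a ratio exactly at a bound
#' is negative); conservative flags inclusively at the fixed band edges.
#'
#' @param ratio methylation ratio(s) in \[0, 1\]
#' @param thresholds a `threshold_set`
#' @param sample_id optional ids
#' @return data.frame: `sample_id`, `ratio`, `band` (`negative`/`low_band`/
#'   `high_band`), `referred`
#' @export
call_tier1 <- function(ratio, thresholds, sample_id = NULL) {
  stopifnot(inherits(thresholds, "threshold_set"), all(ratio >= 0 & ratio <= 1))
  band <- if (thresholds$mode == "sd_rule") {
    ifelse(ratio < thresholds$lower, "low_band",
           ifelse(ratio > thresholds$upper, "high_band", "negative"))
  } else {
    ifelse(ratio <= thresholds$as_band_max, "low_band",
           ifelse(ratio >= thresholds$pws_band_min, "high_band", "negative"))
  }
  data.frame(
    sample_id = if (is.null(sample_id)) sprintf("S%06d", seq_along(ratio)) else sample_id,
    ratio = ratio,
    band = band,
    referred = band != "negative",
    stringsAsFactors = FALSE
  )
}

#' Screen a cohort of methylation calls against thresholds
#'
#' @param calls a `methylation_calls` data.frame (needs `sample_id`, `ratio`)
#' @param thresholds a `threshold_set`
#' @return list of class `"tier1_screen"`: `$calls` (per-sample tier-1 calls)
#'   and `$summary` (`n_screened`, `n_low`, `n_high`, `n_referred`,
#'   `percent_referred` rendered to 2 decimals)
#' @export
screen_cohort <- function(calls, thresholds) {
  stopifnot(nrow(calls) > 0)
  t1 <- call_tier1(calls$ratio, thresholds, sample_id = calls$sample_id)
  n <- nrow(t1)
  n_low <- sum(t1$band == "low_band")
  n_high <- sum(t1$band == "high_band")
  summary <- list(
    n_screened = n, n_low = n_low, n_high = n_high,
    n_referred = n_low + n_high,
    percent_referred = as.numeric(render_percent((n_low + n_high) / n, digits = 2))
  )
  structure(list(calls = t1, summary = summary), class = "tier1_screen")
}

#' @export
print.tier1_screen <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Tier 1: %d screened, %d referred (%.2f%%): %d low band, %d high band\n",
              s$n_screened, s$n_referred, s$percent_referred, s$n_low, s$n_high))
  invisible(x)
}
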