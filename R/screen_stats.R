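# Screening performance statistics: PPV/NPV, sensitivity/specificity,
# prevalence as "1 in N" with exact binomial confidence intervals, and
# tier-flow accounting.

#' Positive predictive value
#'
#' Confirmed positives over screen positives. Percent rendering is half away
#' from zero to one decimal (e.g. 2/3 renders "66.7").
#' @param confirmed confirmed-positive count
#' @param flagged screen-positive count (> 0)
#' @return list: `ppv` (fraction), `percent` (rendered string)
#' @export
ppv <- function(confirmed, flagged) {
  stopifnot(flagged > 0, confirmed >= 0, confirmed <= flagged)
  p <- confirmed / flagged
  list(ppv = p, percent = render_percent(p, digits = 1))
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile inversion of the binomial tails; identical to inverting the
#' tail probabilities directly.
#' @param k successes (0 <= k <= n)
#' @param n trials
#' @param level confidence level in (0, 1)
#' @return numeric `c(low, high)`
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  stopifnot(k >= 0, k <= n, level > 0, level < 1)
  a <- (1 - level) / 2
  low <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  high <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(low, high)
}

#' Prevalence with "1 in N" rendering and exact CI
#'
#' @param confirmed confirmed-case count
#' @param screened total screened (> 0)
#' @param level confidence level
#' @return list: `fraction`, `one_in_n` (half-away-from-zero rounded; `NA` when
#'   no case was observed), `ci_low`, `ci_high`, `label` (e.g. "1 in 8290")
#' @export
#' @examples
#' prevalence(2, 16579)$label  # "1 in 8290"
prevalence <- function(confirmed, screened, level = 0.95) {
  stopifnot(screened > 0, confirmed >= 0, confirmed <= screened)
  ci <- clopper_pearson(confirmed, screened, level)
  one_in_n <- if (confirmed == 0) NA_integer_ else
    as.integer(round_half_up(screened / confirmed))
  list(fraction = confirmed / screened, one_in_n = one_in_n,
       ci_low = ci[1], ci_high = ci[2], label = render_one_in(one_in_n))
}

#' Sensitivity and specificity from a confusion table
#'
#' @param tp,fp,tn,fn nonnegative counts; sensitivity needs `tp + fn > 0`,
#'   specificity needs `tn + fp > 0`
#' @return list: `sensitivity`, `specificity` (fractions, `NA` when the margin
#'   is empty and that quantity was not requested), rendered percents
#' @export
sensitivity_specificity <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  if (tp + fn == 0 && tn + fp == 0) stop("empty confusion table")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(sensitivity = sens, specificity = spec,
       sensitivity_percent = if (is.na(sens)) NA_character_ else render_percent(sens, 1),
       specificity_percent = if (is.na(spec)) NA_character_ else render_percent(spec, 1))
}

#' Tier-flow accounting and per-condition performance
#'
#' Reconciles the tier-1 referral list with tier-2 confirmations and builds the
#' screening report counts, enforcing the conservation identities
#' `n_screened = n_negative + n_flagged` and
#' `n_flagged = n_confirmed + n_unconfirmed + n_qc_failed`.
#'
#' @param tier1 tier-1 call data.frame (`sample_id`, `band`, `referred`)
#' @param tier2 `cinq_call` rows for the referred samples (`sample_id`,
#'   `confirmed`, `qc_flags`); may be empty, in which case every flagged sample
#'   counts as unconfirmed
#' @param conditions optional named character vector mapping confirmed
#'   sample_ids to a condition label (`"AS"`, `"PWS"`, `"Dup15q"`)
#' @param level CI level for prevalence
#' @return list of class `"tier_flow"` with counts, per-condition prevalence
#'   and PPV
#' @export
tier_flow <- function(tier1, tier2 = NULL, conditions = NULL, level = 0.95) {
  n <- nrow(tier1)
  flagged_ids <- tier1$sample_id[tier1$referred]
  n_flagged <- length(flagged_ids)
  if (is.null(tier2) || nrow(tier2) == 0) {
    tier2 <- data.frame(sample_id = character(0), confirmed = logical(0),
                        qc_flags = character(0), stringsAsFactors = FALSE)
  }
  if (!all(tier2$sample_id %in% flagged_ids)) {
    stop("tier-2 calls include sample ids that were not referred by tier 1")
  }
  qc_failed <- tier2$sample_id[nzchar(tier2$qc_flags)]
  confirmed_ids <- tier2$sample_id[tier2$confirmed & !nzchar(tier2$qc_flags)]
  n_confirmed <- length(confirmed_ids)
  n_qc <- length(qc_failed)
  n_unconfirmed <- n_flagged - n_confirmed - n_qc

  counts <- list(
    n_screened = n, n_negative = n - n_flagged, n_flagged = n_flagged,
    n_confirmed = n_confirmed, n_unconfirmed = n_unconfirmed, n_qc_failed = n_qc
  )
  overall <- list(
    prevalence = prevalence(n_confirmed, n, level),
    ppv = if (n_flagged > 0) ppv(n_confirmed, n_flagged) else NULL
  )
  per_condition <- NULL
  if (!is.null(conditions) && n_confirmed > 0) {
    cond <- conditions[confirmed_ids]
    per_condition <- lapply(split(names(cond), unname(cond)), function(ids) {
      list(n_confirmed = length(ids), prevalence = prevalence(length(ids), n, level))
    })
  }
  structure(list(counts = counts, overall = overall, per_condition = per_condition),
            class = "tier_flow")
}

#' @export
print.tier_flow <- function(x, ...) {
  cts <- x$counts
  cat(sprintf("Tier flow: %d screened -> %d flagged -> %d confirmed (%d unconfirmed, %d qc-failed)\n",
              cts$n_screened, cts$n_flagged, cts$n_confirmed,
              cts$n_unconfirmed, cts$n_qc_failed))
  if (!is.null(x$overall$ppv)) {
    cat(sprintf("  PPV %s%%; prevalence %s (95%% CI %.3g-%.3g per screen)\n",
                x$overall$ppv$percent, x$overall$prevalence$label,
                x$overall$prevalence$ci_low, x$overall$prevalence$ci_high))
  }
  for (nm in names(x$per_condition)) {
    pc <- x$per_condition[[nm]]
    cat(sprintf("  %s: %d confirmed, prevalence %s\n",
                nm, pc$n_confirmed, pc$prevalence$label))
  }
  invisible(x)
}
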