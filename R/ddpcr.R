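# Second-tier methylation confirmation by two-channel droplet digital PCR.
#
# Template molecules partition into droplets; a channel's concentration (mean
# copies per droplet, lambda) is recovered from its negative-droplet fraction
# by Poisson occupancy correction, lambda = -ln(neg/total). The methylation
# ratio lambda_meth / (lambda_meth + lambda_unmeth) is compared with a
# reference range from storage-matched control wells.

#' Poisson occupancy correction
#'
#' Mean template copies per droplet from the negative-droplet count:
#' `lambda = -ln(neg / total)`. All droplets negative gives 0; all droplets
#' positive (neg = 0) is a saturation error, the concentration being
#' unquantifiable.
#'
#' @param neg negative-droplet count(s)
#' @param total total droplet count(s)
#' @return mean copies per droplet
#' @export
#' @examples
#' poisson_lambda(368, 1000)  # ~0.9997
poisson_lambda <- function(neg, total) {
  stopifnot(all(total > 0), all(neg >= 0), all(neg <= total))
  if (any(neg == 0)) {
    stop("saturation: all droplets positive; concentration unquantifiable")
  }
  -log(neg / total)
}

#' Simulate a two-channel droplet well
#'
#' Methylated and unmethylated template loads are `m * lambda` and
#' `(1 - m) * lambda` copies per droplet; each channel's negative count is
#' Binomial(total, exp(-load)), or its rounded expectation in deterministic
#' (noise-free) mode.
#'
#' @param methylation methylated template fraction in \[0, 1\]
#' @param copies_per_droplet total template load lambda (> 0)
#' @param total_droplets droplets in the well
#' @param seed integer seed
#' @param sample_id id carried on the well
#' @param input_ng nominal DNA input (bookkeeping only)
#' @param deterministic use expected counts instead of binomial draws
#' @return data.frame of class `"droplet_well"`: `sample_id`, `total_droplets`,
#'   `neg_meth`, `neg_unmeth`, `input_ng`
#' @export
simulate_droplets <- function(methylation, copies_per_droplet = 1,
                              total_droplets = 20000, seed = NULL,
                              sample_id = NA_character_, input_ng = 5,
                              deterministic = FALSE) {
  stopifnot(methylation >= 0, methylation <= 1, copies_per_droplet > 0,
            total_droplets >= 1)
  p_neg <- exp(-c(meth = methylation, unmeth = 1 - methylation) * copies_per_droplet)
  neg <- if (deterministic) {
    round(total_droplets * p_neg)
  } else {
    with_seed(seed, stats::rbinom(2L, total_droplets, p_neg))
  }
  out <- data.frame(
    sample_id = sample_id, total_droplets = as.integer(total_droplets),
    neg_meth = as.integer(neg[1]), neg_unmeth = as.integer(neg[2]),
    input_ng = input_ng, stringsAsFactors = FALSE
  )
  class(out) <- c("droplet_well", "data.frame")
  out
}

#' Methylation ratio of a droplet well
#'
#' @param well a `droplet_well` (one row)
#' @return list: `lambda_meth`, `lambda_unmeth`, `ratio`, `qc` (empty string or
#'   a flag; saturation/zero-template wells return `ratio = NA` with a flag)
#' @export
cinq_ratio <- function(well) {
  lam <- tryCatch(
    list(
      m = poisson_lambda(well$neg_meth, well$total_droplets),
      u = poisson_lambda(well$neg_unmeth, well$total_droplets),
      qc = ""
    ),
    error = function(e) list(m = NA_real_, u = NA_real_, qc = "saturation")
  )
  ratio <- if (!is.na(lam$m) && (lam$m + lam$u) > 0) lam$m / (lam$m + lam$u) else NA_real_
  qc <- lam$qc
  if (!nzchar(qc) && is.na(ratio)) qc <- "no_template"
  list(lambda_meth = lam$m, lambda_unmeth = lam$u, ratio = ratio, qc = qc)
}

#' Reference range from storage-matched control wells
#'
#' Default is the min/max of the control-well ratios, optionally expanded by a
#' guard band: a min/max range of n exchangeable controls excludes a fresh null
#' sample with probability about 2/(n+1), so the guard band sets the separation
#' margin a confirmed call must clear. `"meansd"` uses mean +/- k SD instead.
#'
#' @param control_wells a `droplet_well` data.frame (>= `min_wells` rows)
#' @param method `"minmax"` or `"meansd"`
#' @param k SD multiplier for `"meansd"`
#' @param expand additive guard band applied to both ends
#' @param min_wells fewest control wells accepted
#' @return numeric `c(low, high)`
#' @export
cinq_reference_range <- function(control_wells, method = c("minmax", "meansd"),
                                 k = 5, expand = 0, min_wells = 20) {
  method <- match.arg(method)
  ratios <- vapply(seq_len(nrow(control_wells)),
                   function(i) cinq_ratio(control_wells[i, ])$ratio, numeric(1))
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) < min_wells) {
    stop("need >= ", min_wells, " quantifiable storage-matched control wells")
  }
  rng <- if (method == "minmax") range(ratios) else {
    mean(ratios) + c(-k, k) * stats::sd(ratios)
  }
  c(max(0, rng[1] - expand), min(1, rng[2] + expand))
}

#' Call second-tier confirmation for a droplet well
#'
#' Confirmed when the Poisson-corrected methylation ratio falls strictly
#' outside the control reference range. Saturated or template-free wells
#' propagate as qc failures, never as confirmed calls.
#'
#' @param well a `droplet_well` (one row)
#' @param reference_range numeric `c(low, high)`
#' @return data.frame of class `"cinq_call"`: `sample_id`, `lambda_meth`,
#'   `lambda_unmeth`, `ratio`, `confirmed`, `ref_low`, `ref_high`, `qc_flags`
#' @export
call_cinq <- function(well, reference_range) {
  stopifnot(length(reference_range) == 2, reference_range[1] <= reference_range[2])
  r <- cinq_ratio(well)
  confirmed <- !is.na(r$ratio) &&
    (r$ratio < reference_range[1] || r$ratio > reference_range[2])
  out <- data.frame(
    sample_id = well$sample_id,
    lambda_meth = r$lambda_meth, lambda_unmeth = r$lambda_unmeth,
    ratio = r$ratio, confirmed = confirmed,
    ref_low = reference_range[1], ref_high = reference_range[2],
    qc_flags = r$qc, stringsAsFactors = FALSE
  )
  class(out) <- c("cinq_call", "data.frame")
  out
}

#' Absolute concentration of a droplet well (copies/uL)
#'
#' Convenience output; assumes a 0.85 nL droplet volume (instrument dependent).
#' @param well a `droplet_well`
#' @param droplet_nl droplet volume in nanolitres
#' @return list with `meth` and `unmeth` copies per microlitre
#' @export
cinq_copies_per_ul <- function(well, droplet_nl = 0.85) {
  r <- cinq_ratio(well)
  list(meth = r$lambda_meth / (droplet_nl * 1e-3),
       unmeth = r$lambda_unmeth / (droplet_nl * 1e-3))
}
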