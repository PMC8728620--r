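# Second-tier copy-number confirmation: relative standard-curve qPCR of the
# SNRPN locus normalised to beta-globin (a 2-copy reference), classified
# against empirically derived CNV-ratio reference ranges.

# Independent (well-to-well) dispersion of the CNV ratio on the log10 scale.
# Chosen so that +/-3 SD reproduces the relative width of the empirical 1- and
# 2-copy reference ranges (half-widths ~0.045-0.057 log10 units).
.CNV_LOG10_SD <- 0.015

# Per-copy assay distortion: empirical ratio centres are not proportional to
# copy number (the 1-copy range centres at 1.115, not half the 2-copy centre
# of 1.82). Encoded as a multiplier per copy class on top of the uniform bias.
.CNV_DISTORTION <- c(`1` = 1.115 / 0.91, `2` = 1, `3` = 1, `4` = 1, `5` = 1, `7` = 1)

#' Fit a qPCR standard curve
#'
#' Least-squares line of Ct on log10 input quantity over a dilution series.
#' Amplification efficiency is `10^(-1/slope) - 1` (1.0 = perfect doubling,
#' slope -3.3219).
#'
#' @param log10_quantity log10 input quantities (>= 3 dilution points)
#' @param ct observed Ct values
#' @param r2_floor minimum r-squared for a passing curve
#' @param efficiency_range acceptable efficiency interval
#' @return object of class `"standard_curve"`: `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `pass`
#' @export
#' @examples
#' fit_standard_curve(0:3, 34 - 3.3219 * (0:3))
fit_standard_curve <- function(log10_quantity, ct, r2_floor = 0.98,
                               efficiency_range = c(0.8, 1.1)) {
  if (length(log10_quantity) < 3L) stop("need >= 3 dilution points")
  stopifnot(length(ct) == length(log10_quantity))
  fit <- stats::lm(ct ~ log10_quantity)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) stop("standard curve slope must be negative")
  r2 <- suppressWarnings(summary(fit)$r.squared)  # perfect fits warn in summary.lm
  eff <- 10^(-1 / slope) - 1
  structure(
    list(slope = slope, intercept = unname(stats::coef(fit)[1]),
         r_squared = r2, efficiency = eff,
         pass = r2 >= r2_floor && eff >= efficiency_range[1] && eff <= efficiency_range[2]),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve: slope %.4f, intercept %.2f, r2 %.4f, efficiency %.1f%% [%s]\n",
              x$slope, x$intercept, x$r_squared, 100 * x$efficiency,
              if (x$pass) "pass" else "FAIL"))
  invisible(x)
}

.ct_to_quantity <- function(ct, curve) 10^((ct - curve$intercept) / curve$slope)

#' CNV ratio from target and reference Cts
#'
#' Quantities are read off each standard curve; the ratio is `2 * bias *
#' q_target / q_reference`, the factor 2 reflecting the 2-copy reference gene
#' and `bias` a per-assay scale calibrated so 2-copy controls land in the
#' empirical 2-copy reference range (default 0.91, the range midpoint over 2).
#'
#' @param ct_target,ct_reference Ct values (vectorised)
#' @param curve_target,curve_reference `standard_curve` objects
#' @param bias per-assay multiplicative scale
#' @return positive CNV ratio(s)
#' @export
cnv_ratio <- function(ct_target, ct_reference, curve_target, curve_reference,
                      bias = 0.91) {
  stopifnot(bias > 0)
  2 * bias * .ct_to_quantity(ct_target, curve_target) /
    .ct_to_quantity(ct_reference, curve_reference)
}

#' Default CNV-ratio reference ranges
#'
#' The 1-copy (0.97-1.26) and 2-copy (1.62-2.02) ranges are empirical
#' min/max values over diagnostic deletion and nondeletion panels. The 4-, 5-
#' and 7-copy ranges are NOT empirically anchored: they are synthetic defaults,
#' `centre * 10^(+/- 3 * sigma)` on the log10 scale with the assay's ratio
#' dispersion `sigma = 0.015` (the band width consistent with the empirical
#' ranges) and centres `copies * bias`.
#'
#' @param bias per-assay scale (see [cnv_ratio()])
#' @param log10_sd per-sample ratio dispersion on the log10 scale
#' @return data.frame: `copies`, `low`, `high`, `source`
#' @export
default_cnv_ranges <- function(bias = 0.91, log10_sd = .CNV_LOG10_SD) {
  synth <- function(copies) {
    ctr <- copies * bias
    c(ctr * 10^(-3 * log10_sd), ctr * 10^(3 * log10_sd))
  }
  r4 <- synth(4); r5 <- synth(5); r7 <- synth(7)
  data.frame(
    copies = c(1L, 2L, 4L, 5L, 7L),
    low  = c(0.97, 1.62, r4[1], r5[1], r7[1]),
    high = c(1.26, 2.02, r4[2], r5[2], r7[2]),
    source = c("empirical", "empirical", "synthetic", "synthetic", "synthetic"),
    stringsAsFactors = FALSE
  )
}

#' Classify a CNV ratio against reference ranges
#'
#' Membership is inclusive at both endpoints; a ratio inside no range is
#' indeterminate (`copy_class = NA`). Ratios below every range or above the
#' 5-copy range are flagged for third-tier reflex. Overlapping ranges are a
#' configuration error.
#'
#' @param ratio CNV ratio(s)
#' @param ranges reference ranges as from [default_cnv_ranges()]
#' @param sample_id optional ids
#' @return data.frame of class `"cnv_call"`: `sample_id`, `cnv_ratio`,
#'   `copy_class` (integer, `NA` = indeterminate), `reflex`
#' @export
#' @examples
#' classify_cnv(c(1.10, 1.80, 1.45))$copy_class  # 1, 2, NA
classify_cnv <- function(ratio, ranges = default_cnv_ranges(), sample_id = NULL) {
  ranges <- ranges[order(ranges$low), ]
  if (any(ranges$low > ranges$high)) stop("malformed reference range")
  if (nrow(ranges) > 1 && any(ranges$low[-1] <= ranges$high[-nrow(ranges)])) {
    stop("configuration error: CNV reference ranges overlap")
  }
  cls <- vapply(ratio, function(r) {
    hit <- which(r >= ranges$low & r <= ranges$high)
    if (length(hit) == 1L) ranges$copies[hit] else NA_integer_
  }, integer(1))
  top <- if (5L %in% ranges$copies) ranges$high[ranges$copies == 5L] else max(ranges$high)
  reflex <- ratio < min(ranges$low) | ratio > top
  out <- data.frame(
    sample_id = if (is.null(sample_id)) sprintf("S%06d", seq_along(ratio)) else sample_id,
    cnv_ratio = ratio, copy_class = cls, reflex = reflex,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cnv_call", "data.frame")
  attr(out, "ranges") <- ranges
  out
}

#' Default matched standard curves for simulation (target and reference)
#' @param slope Ct change per log10 quantity (100% efficiency = -3.3219)
#' @return list with `target` and `reference` `standard_curve` objects
#' @export
default_cnv_curves <- function(slope = -1 / log10(2)) {
  mk <- function(intercept) {
    structure(list(slope = slope, intercept = intercept, r_squared = 1,
                   efficiency = 10^(-1 / slope) - 1, pass = TRUE),
              class = "standard_curve")
  }
  list(target = mk(34), reference = mk(31))
}

#' Simulate a qPCR CNV measurement for a known copy number
#'
#' Target quantity is `distortion[copies] * copies / 2` relative to the 2-copy
#' reference. Ct noise decomposes into a shared per-sample component (input
#' mass, lysate quality, run effects; identical for target and reference wells
#' and therefore cancelled by normalisation) and an independent well component.
#' Replicate wells, when requested, are averaged on the Ct scale.
#'
#' @param copies true copy number (1, 2, 3, 4, 5 or 7)
#' @param curves list as from [default_cnv_curves()]
#' @param bias per-assay scale (see [cnv_ratio()])
#' @param ct_sd total per-well Ct SD
#' @param ct_sd_well independent well-to-well Ct SD (must not exceed `ct_sd`)
#' @param replicates wells per sample, averaged
#' @param input_quantity nominal template input (reference-curve units)
#' @param seed integer seed
#' @return list: `ct_target`, `ct_reference` (replicate means), `cnv_ratio`
#' @export
simulate_cnv_measurement <- function(copies, curves = default_cnv_curves(),
                                     bias = 0.91, ct_sd = 0.15,
                                     ct_sd_well = 0.035, replicates = 1,
                                     input_quantity = 10, seed = NULL) {
  stopifnot(copies >= 0, ct_sd_well <= ct_sd)
  key <- as.character(copies)
  distortion <- if (key %in% names(.CNV_DISTORTION)) .CNV_DISTORTION[[key]] else 1
  q_t <- distortion * (copies / 2) * input_quantity
  q_r <- input_quantity
  sd_shared <- sqrt(max(ct_sd^2 - ct_sd_well^2, 0))
  with_seed(seed, {
    shared <- stats::rnorm(1, sd = sd_shared)
    ct_t <- curves$target$intercept + curves$target$slope * log10(q_t) + shared +
      mean(stats::rnorm(replicates, sd = ct_sd_well))
    ct_r <- curves$reference$intercept + curves$reference$slope * log10(q_r) + shared +
      mean(stats::rnorm(replicates, sd = ct_sd_well))
    list(ct_target = ct_t, ct_reference = ct_r,
         cnv_ratio = cnv_ratio(ct_t, ct_r, curves$target, curves$reference, bias))
  })
}
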