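# First-tier methylation quantification from bisulfite-PCR high-resolution
# melt curves.
#
# After bisulfite conversion, unmethylated template is AT-richer and melts at a
# lower temperature than methylated template. A mixture melts in two
# transitions; the fraction of the negative-derivative (-dF/dT) peak area under
# the high-Tm transition estimates the methylated fraction. Spiked standards of
# known mix calibrate residual nonlinearity; per-plate controls correct run
# shifts.

.MELT_DEFAULTS <- list(
  tm_unmeth = 78, tm_meth = 82, width = 0.6,
  grid = seq(65, 95, by = 0.1),
  sg_window = 11L, sg_poly = 3L,
  single_peak_frac = 0.005
)

.melt_sigmoid <- function(temps, tm, width) 1 / (1 + exp((temps - tm) / width))

#' Simulate a bisulfite-PCR melt curve
#'
#' Two-transition forward model: `F(T) = m * S(T; Tm_meth) + (1 - m) *
#' S(T; Tm_unmeth)` with `S` a decreasing sigmoid of the given width, plus
#' optional iid fluorescence noise (clamped at zero).
#'
#' @param methylation methylated template fraction in \[0, 1\]
#' @param noise_sd fluorescence noise SD (0 = noise-free)
#' @param grid strictly increasing temperature grid (degrees C, >= 50 points)
#' @param seed integer seed for the noise draw
#' @param tm_unmeth,tm_meth melting temperatures of the unmethylated and
#'   methylated transitions (`tm_unmeth < tm_meth`)
#' @param width sigmoid width (degrees C)
#' @param well_id,plate_id,sample_id identifiers carried on the curve
#' @param role well role: `"sample"`, `"pws_control"`, `"as_control"` or
#'   `"spike_standard"`
#' @param known_mix known methylation fraction for spike standards
#' @return object of class `"melt_curve"`
#' @export
#' @examples
#' mc <- simulate_melt(0.5)
#' raw_area_fraction(mc)
simulate_melt <- function(methylation, noise_sd = 0, grid = .MELT_DEFAULTS$grid,
                          seed = NULL,
                          tm_unmeth = .MELT_DEFAULTS$tm_unmeth,
                          tm_meth = .MELT_DEFAULTS$tm_meth,
                          width = .MELT_DEFAULTS$width,
                          well_id = "A01", plate_id = "P0001",
                          sample_id = NA_character_,
                          role = "sample", known_mix = NA_real_) {
  stopifnot(methylation >= 0, methylation <= 1, tm_unmeth < tm_meth)
  if (length(grid) < 50L || any(diff(grid) <= 0)) {
    stop("temperature grid must be strictly increasing with >= 50 points")
  }
  f <- methylation * .melt_sigmoid(grid, tm_meth, width) +
    (1 - methylation) * .melt_sigmoid(grid, tm_unmeth, width)
  if (noise_sd > 0) {
    f <- with_seed(seed, f + stats::rnorm(length(grid), sd = noise_sd))
    f <- pmax(f, 0)
  }
  structure(
    list(temperatures = grid, fluorescence = f,
         well_id = well_id, plate_id = plate_id, sample_id = sample_id,
         role = role, known_mix = known_mix,
         tm_unmeth = tm_unmeth, tm_meth = tm_meth),
    class = "melt_curve"
  )
}

# Savitzky-Golay smoothing coefficients (central FIR row).
.sg_coefs <- function(window, poly) {
  m <- signal::sgolay(p = poly, n = window)
  m[(window + 1L) %/% 2L + (window %% 2L == 0L), ]
}

#' Quantify a matrix of melt curves (columns) on a shared grid.
#' Returns list(raw = numeric, qc = character).
#' @keywords internal
#' @noRd
quantify_raw_matrix <- function(fluor, temps,
                                tm_unmeth = .MELT_DEFAULTS$tm_unmeth,
                                tm_meth = .MELT_DEFAULTS$tm_meth,
                                sg_window = .MELT_DEFAULTS$sg_window,
                                sg_poly = .MELT_DEFAULTS$sg_poly,
                                single_peak_frac = .MELT_DEFAULTS$single_peak_frac) {
  fluor <- as.matrix(fluor)
  m <- nrow(fluor)
  dt <- diff(temps)
  d <- -(fluor[-1L, , drop = FALSE] - fluor[-m, , drop = FALSE]) / dt
  tmid <- (temps[-1L] + temps[-m]) / 2
  sm <- stats::filter(d, .sg_coefs(sg_window, sg_poly), sides = 2)
  sm <- matrix(as.numeric(sm), nrow = nrow(d))
  na <- is.na(sm)
  sm[na] <- d[na]              # unsmoothed values at the window edges
  sm <- pmax(sm, 0)

  win_lo <- which(tmid >= tm_unmeth - 2 & tmid <= tm_unmeth + 2)
  win_hi <- which(tmid >= tm_meth - 2 & tmid <= tm_meth + 2)
  n <- ncol(sm)
  raw <- numeric(n)
  qc <- character(n)

  # highest interior local maximum within a window (NA when the window holds
  # only a monotone shoulder of a neighbouring peak)
  window_peak <- function(col, win) {
    win <- win[win > 1L & win < length(col)]
    cand <- win[col[win] >= col[win - 1L] & col[win] >= col[win + 1L] & col[win] > 0]
    if (length(cand) == 0L) NA_integer_ else cand[which.max(col[cand])]
  }

  for (j in seq_len(n)) {
    col <- sm[, j]
    i_lo <- window_peak(col, win_lo)
    i_hi <- window_peak(col, win_hi)
    if (is.na(i_lo) && is.na(i_hi)) { raw[j] <- NA_real_; qc[j] <- "flat_curve"; next }
    if (is.na(i_lo)) { raw[j] <- 1; qc[j] <- "single_peak"; next }
    if (is.na(i_hi)) { raw[j] <- 0; qc[j] <- "single_peak"; next }
    h_lo <- col[i_lo]; h_hi <- col[i_hi]
    tot_h <- h_lo + h_hi
    if (h_lo / tot_h < single_peak_frac) { raw[j] <- 1; qc[j] <- "single_peak"; next }
    if (h_hi / tot_h < single_peak_frac) { raw[j] <- 0; qc[j] <- "single_peak"; next }
    if (i_hi - i_lo < 2L) {
      v <- which.min(abs(tmid - (tm_unmeth + tm_meth) / 2))  # degenerate: nominal midpoint
    } else {
      span <- i_lo:i_hi
      v <- span[which.min(col[span])]
    }
    a_lo <- trapz(tmid[1:v], col[1:v])
    a_hi <- trapz(tmid[v:length(col)], col[v:length(col)])
    raw[j] <- a_hi / (a_lo + a_hi)
  }
  list(raw = clamp01(raw), qc = qc)
}

#' Raw high-Tm peak-area fraction of a melt curve
#'
#' Computes -dF/dT on the grid, smooths it (Savitzky-Golay local polynomial),
#' locates the valley between the two transition peaks and returns the
#' trapezoidal area of the high-Tm peak as a fraction of total peak area.
#' Single-transition curves return 0 or 1 with a `"single_peak"` qc flag
#' (attribute `qc`), not an error.
#'
#' @param curve a `melt_curve`
#' @return fraction in \[0, 1\]; attribute `qc` holds any flag
#' @export
raw_area_fraction <- function(curve) {
  stopifnot(inherits(curve, "melt_curve"))
  q <- quantify_raw_matrix(matrix(curve$fluorescence, ncol = 1),
                           curve$temperatures,
                           tm_unmeth = curve$tm_unmeth, tm_meth = curve$tm_meth)
  structure(q$raw, qc = q$qc)
}

#' Fit a spiked-standard calibration for the melt quantifier
#'
#' Maps raw peak-area fractions onto known methylation mixes by isotonic
#' regression with linear interpolation between standards, yielding a monotone
#' nondecreasing map on \[0, 1\] and its inverse.
#'
#' @param standards either a list of `melt_curve` objects with `known_mix` set,
#'   or a data.frame with columns `known_mix` and `raw`
#' @param monotone_tol largest tolerated inversion (raw decreasing while known
#'   mix increases) before the calibration is rejected
#' @return object of class `"melt_calibration"` with `$map(raw)` and
#'   `$inverse(ratio)` functions and the `$pairs` table
#' @export
fit_calibration <- function(standards, monotone_tol = 0.05) {
  if (is.data.frame(standards)) {
    pairs <- standards[, c("known_mix", "raw")]
  } else {
    known <- vapply(standards, function(cv) cv$known_mix, numeric(1))
    raw <- vapply(standards, function(cv) as.numeric(raw_area_fraction(cv)), numeric(1))
    pairs <- data.frame(known_mix = known, raw = raw)
  }
  pairs <- pairs[order(pairs$known_mix, pairs$raw), ]
  lv <- unique(pairs$known_mix)
  if (length(lv) < 3L || min(lv) != 0 || max(lv) != 1) {
    stop("calibration needs >= 3 distinct known_mix levels including 0 and 1")
  }
  inv <- diff(pairs$raw)
  if (any(inv < -monotone_tol)) {
    k <- which(inv < -monotone_tol)[1]
    stop(sprintf(
      "calibration failure: raw fraction drops %.3f between known mixes %.2f and %.2f",
      -inv[k], pairs$known_mix[k], pairs$known_mix[k + 1]
    ))
  }
  iso <- stats::isoreg(pairs$raw, pairs$known_mix)
  x <- if (is.null(iso$ord)) iso$x else iso$x[iso$ord]
  y <- iso$yf
  keep <- !duplicated(x)
  x <- x[keep]; y <- y[keep]
  map_fn <- stats::approxfun(x, y, rule = 2)
  inv_fn <- stats::approxfun(y, x, rule = 2, ties = "ordered")
  structure(
    list(pairs = pairs,
         map = function(raw) clamp01(map_fn(raw)),
         inverse = function(ratio) clamp01(inv_fn(ratio))),
    class = "melt_calibration"
  )
}

#' @export
print.melt_calibration <- function(x, ...) {
  cat("Melt-quantifier calibration:", nrow(x$pairs), "standards at",
      length(unique(x$pairs$known_mix)), "mix levels\n")
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

.control_expected <- function(role, known_mix) {
  ifelse(role == "pws_control", 1,
         ifelse(role == "as_control", 0,
                ifelse(role == "spike_standard", known_mix, NA_real_)))
}

#' Quantify one assay plate of melt curves
#'
#' Applies the calibration to every well, estimates the plate shift from the
#' control wells (observed minus expected calibrated ratio; mid-range controls
#' are preferred since boundary controls truncate), subtracts it from sample
#' wells, and flags the plate when the control deviation exceeds tolerance.
#'
#' @param curves list of `melt_curve` objects from one plate, including its
#'   control wells (a PWS control and spiked standards)
#' @param calibration a `melt_calibration`
#' @param shift_tol control deviation above which calls are qc-flagged
#' @return data.frame of class `"methylation_calls"` (sample wells only):
#'   `sample_id`, `well_id`, `plate_id`, `ratio`, `method`, `qc_flags`
#' @export
quantify_plate <- function(curves, calibration, shift_tol = 0.05) {
  stopifnot(length(curves) > 0, inherits(calibration, "melt_calibration"))
  roles <- vapply(curves, function(cv) cv$role, character(1))
  if (!any(roles == "pws_control") || !any(roles == "spike_standard")) {
    stop("plate rejected: control wells missing (needs a PWS control and spiked standards)")
  }
  temps <- curves[[1]]$temperatures
  fl <- vapply(curves, function(cv) {
    if (!identical(length(cv$fluorescence), length(temps))) {
      stop("all curves on a plate must share one temperature grid")
    }
    cv$fluorescence
  }, numeric(length(temps)))
  q <- quantify_raw_matrix(fl, temps,
                           tm_unmeth = curves[[1]]$tm_unmeth,
                           tm_meth = curves[[1]]$tm_meth)
  cal <- calibration$map(q$raw)

  known <- vapply(curves, function(cv) cv$known_mix, numeric(1))
  expected <- .control_expected(roles, known)
  is_ctrl <- roles != "sample" & !is.na(expected)
  mid <- is_ctrl & expected >= 0.2 & expected <= 0.8
  use <- if (any(mid)) mid else is_ctrl
  shift <- mean(cal[use] - expected[use])

  smp <- which(roles == "sample")
  flags <- q$qc[smp]
  if (abs(shift) > shift_tol) {
    flags <- ifelse(nzchar(flags), paste(flags, "plate_shift", sep = ";"), "plate_shift")
  }
  out <- data.frame(
    sample_id = vapply(curves[smp], function(cv) cv$sample_id, character(1)),
    well_id = vapply(curves[smp], function(cv) cv$well_id, character(1)),
    plate_id = vapply(curves[smp], function(cv) cv$plate_id, character(1)),
    ratio = clamp01(cal[smp] - shift),
    method = "MSQMA",
    qc_flags = flags,
    stringsAsFactors = FALSE
  )
  class(out) <- c("methylation_calls", "data.frame")
  attr(out, "plate_shift") <- shift
  out
}
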