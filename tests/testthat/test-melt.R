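test_that("the forward melt model is symmetric and pure templates give single transitions", {
  # symmetry at m = 0.5: equal derivative peak areas on either side of the
  # mid-temperature (closed-form areas from the fluorescence differences)
  mc <- simulate_melt(0.5)
  f <- stats::approxfun(mc$temperatures, mc$fluorescence)
  mid <- (mc$tm_unmeth + mc$tm_meth) / 2
  area_low <- f(65) - f(mid)
  area_high <- f(mid) - f(95)
  expect_lt(abs(area_low - area_high), 1e-6)
  # pure templates quantify to the extremes with a single-peak flag
  r1 <- raw_area_fraction(simulate_melt(1))
  r0 <- raw_area_fraction(simulate_melt(0))
  expect_equal(as.numeric(r1), 1)
  expect_equal(as.numeric(r0), 0)
  expect_identical(attr(r1, "qc"), "single_peak")
  # mid-mix round trip without calibration
  expect_lt(abs(as.numeric(raw_area_fraction(simulate_melt(0.3))) - 0.3), 0.02)
  # invalid grids are rejected
  expect_error(simulate_melt(0.5, grid = seq(95, 65, by = -0.1)), "increasing")
  expect_error(simulate_melt(0.5, grid = c(65, 70, 75)), "50 points")
  # fluorescence is nonincreasing after smoothing (noise-free: exactly)
  expect_true(all(diff(mc$fluorescence) <= 1e-12))
})

test_that("calibration is identity on perfect standards and rejects bad input", {
  std <- data.frame(known_mix = c(0, 0.25, 0.5, 0.75, 1),
                    raw = c(0, 0.25, 0.5, 0.75, 1))
  cal <- fit_calibration(std)
  q <- seq(0, 1, by = 0.05)
  expect_lt(max(abs(cal$map(q) - q)), 1e-6)
  expect_lt(max(abs(cal$inverse(q) - q)), 1e-6)
  expect_error(fit_calibration(data.frame(known_mix = c(0, 1), raw = c(0, 1))),
               ">= 3 distinct")
  expect_error(fit_calibration(data.frame(known_mix = c(0.1, 0.5, 0.9),
                                          raw = c(0.1, 0.5, 0.9))),
               "including 0 and 1")
  expect_error(fit_calibration(data.frame(known_mix = c(0, 0.5, 1),
                                          raw = c(0.2, 0.7, 0.5))),
               "calibration failure")
})

test_that("spike calibration corrects a channel-efficiency amplification bias", {
  b <- 1.3  # methylated template amplifies 30% more efficiently
  mixes <- c(0, 0.25, 0.5, 0.75, 1)
  standards <- lapply(mixes, function(m) {
    simulate_melt(biased_mix(m, b), role = "spike_standard", known_mix = m)
  })
  cal <- fit_calibration(standards)
  truth <- seq(0.05, 0.95, by = 0.09)
  est <- cal$map(vapply(truth, function(m) {
    as.numeric(raw_area_fraction(simulate_melt(biased_mix(m, b))))
  }, numeric(1)))
  expect_lt(max(abs(est - truth)), 0.02)
})

test_that("calibrated quantification is monotone and accurate on a 21-level grid", {
  mixes <- c(0, 0.25, 0.5, 0.75, 1)
  cal <- fit_calibration(lapply(mixes, function(m) {
    simulate_melt(m, role = "spike_standard", known_mix = m)
  }))
  grid <- seq(0, 1, length.out = 21)
  est <- cal$map(vapply(grid, function(m) {
    as.numeric(raw_area_fraction(simulate_melt(m)))
  }, numeric(1)))
  expect_true(all(diff(est) >= -1e-9))
  expect_lt(max(abs(est - grid)), 0.02)
})

test_that("plate control correction recovers an injected uniform shift", {
  mixes <- c(0, 0.25, 0.5, 0.75, 1)
  cal <- fit_calibration(lapply(mixes, function(m) {
    simulate_melt(m, role = "spike_standard", known_mix = m)
  }))
  make_plate <- function(shift, truth) {
    ctrl <- c(
      list(simulate_melt(min(1, 1 + shift), role = "pws_control", well_id = "C1")),
      lapply(c(0, 0.5, 1), function(k) {
        simulate_melt(min(1, max(0, k + shift)), role = "spike_standard",
                      known_mix = k, well_id = paste0("STD", k))
      })
    )
    smp <- lapply(seq_along(truth), function(i) {
      simulate_melt(truth[i] + shift, well_id = paste0("W", i),
                    sample_id = paste0("S", i), role = "sample")
    })
    c(ctrl, smp)
  }
  truth <- c(0.3, 0.45, 0.6)
  # no deviation: calls equal the calibrated raw values
  calls0 <- quantify_plate(make_plate(0, truth), cal)
  direct <- cal$map(vapply(truth, function(m) {
    as.numeric(raw_area_fraction(simulate_melt(m)))
  }, numeric(1)))
  expect_equal(calls0$ratio, direct, tolerance = 1e-8)
  # +0.05 uniform shift: control-corrected calls recover truth within 0.01
  calls <- quantify_plate(make_plate(0.05, truth), cal)
  expect_lt(max(abs(calls$ratio - truth)), 0.01)
  # accounting: a 96-well plate yields 96 - controls calls
  plate96 <- make_plate(0, rep(0.5, 92))
  expect_identical(nrow(quantify_plate(plate96, cal)), 92L)
  # plates without control wells are rejected
  expect_error(quantify_plate(plate96[5:96], cal), "control wells missing")
})

test_that("simulated control calls reproduce the population distribution", {
  rep <- run_screen(screen_config(
    n = 10000, class_mix = NULL, exact = FALSE, profile = "archival",
    threshold_mode = "sd_rule", seed = 424242
  ))
  r <- rep$tier1_calls$ratio
  expect_lt(abs(mean(r) - 0.51), 0.01)
  expect_lt(abs(stats::sd(r) - 0.085), 0.01)
})
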