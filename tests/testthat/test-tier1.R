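test_that("threshold arithmetic follows mean -/+ k SD with clipping", {
  thr <- compute_thresholds(mean = 0.5, sd = 0.1, k = 2)
  expect_equal(c(thr$lower, thr$upper), c(0.3, 0.7))
  # constant input: lower = upper = mean
  thr0 <- compute_thresholds(rep(0.4, 200), k = 3)
  expect_equal(thr0$lower, 0.4)
  expect_equal(thr0$upper, 0.4)
  # clipping to [0, 1]
  thr1 <- compute_thresholds(mean = 0.9, sd = 0.1, k = 3)
  expect_equal(thr1$upper, 1)
  # small populations are directed to fixed thresholds
  expect_error(compute_thresholds(runif(50), k = 3), "conservative")
})

test_that("band boundaries are strict for sd_rule and inclusive for conservative", {
  thr <- compute_thresholds(mean = 0.51, sd = 0.085, k = 3)
  expect_equal(call_tier1(c(thr$lower, thr$upper), thr)$band,
               c("negative", "negative"))
  expect_equal(call_tier1(c(thr$lower - 1e-9, thr$upper + 1e-9), thr)$band,
               c("low_band", "high_band"))
  cons <- conservative_thresholds()
  expect_equal(call_tier1(c(0.12, 0.88), cons)$band, c("low_band", "high_band"))
  expect_equal(call_tier1(c(0.121, 0.879), cons)$band, c("negative", "negative"))
  expect_equal(call_tier1(0.90, cons)$band, "high_band")
  # referred <-> non-negative band
  calls <- call_tier1(seq(0, 1, by = 0.05), thr)
  expect_identical(calls$referred, calls$band != "negative")
})

test_that("an intermediate-high duplication ratio diverges between modes", {
  # the mechanism by which conservative thresholds miss a maternal duplication:
  # its ratio exceeds mean + 3 SD but stays below the fixed PWS band
  thr <- compute_thresholds(mean = 0.51, sd = 0.085, k = 3)
  cons <- conservative_thresholds()
  expect_equal(call_tier1(0.80, thr)$band, "high_band")
  expect_equal(call_tier1(0.80, cons)$band, "negative")
  # and on a simulated idic15 sample measured through the calibrated assay
  eff <- true_methylation("Dup15q_idic15")
  co <- make_cohort(1, seed = 5)
  co$genotype <- "Dup15q_idic15"; co$effective_meth <- eff
  ratio <- draw_measured_ratios(co, noise_profile("calibrated"), seed = 6)
  expect_equal(call_tier1(ratio, thr)$band, "high_band")
  expect_equal(call_tier1(ratio, cons)$band, "negative")
})

test_that("screen_cohort accounting and percent rendering are exact", {
  thr <- compute_thresholds(mean = 0.51, sd = 0.085, k = 3)
  ratios <- c(rep(0.5, 16487), rep(0.9, 50), rep(0.05, 42))
  calls <- data.frame(sample_id = sprintf("S%05d", seq_along(ratios)), ratio = ratios)
  scr <- screen_cohort(calls, thr)
  expect_identical(scr$summary$n_screened, 16579L)
  expect_identical(scr$summary$n_referred, 92L)
  expect_identical(scr$summary$n_high, 50L)
  expect_identical(scr$summary$n_low, 42L)
  expect_equal(scr$summary$percent_referred, 0.55)
  # all ratios at the mean: nothing referred
  scr0 <- screen_cohort(data.frame(sample_id = "a", ratio = 0.51), thr)
  expect_identical(scr0$summary$n_referred, 0L)
})

test_that("raising k never increases referrals; conservative positives nest in sd_rule", {
  set.seed(17)
  ratios <- clamp <- pmin(1, pmax(0, rnorm(5000, 0.51, 0.12)))
  calls <- data.frame(sample_id = as.character(seq_along(ratios)), ratio = ratios)
  referred <- vapply(c(1, 1.5, 2, 2.5, 3, 4), function(k) {
    screen_cohort(calls, compute_thresholds(ratios, k = k))$summary$n_referred
  }, numeric(1))
  expect_true(all(diff(referred) <= 0))
  # nesting: with bands outside the sd_rule normal range, every conservative
  # positive is an sd_rule positive
  thr <- compute_thresholds(mean = 0.51, sd = 0.085, k = 3)
  cons <- conservative_thresholds(as_band_max = 0.12, pws_band_min = 0.88)
  pos_cons <- call_tier1(ratios, cons)$referred
  pos_sd <- call_tier1(ratios, thr)$referred
  expect_true(all(pos_sd[pos_cons]))
})

test_that("noise-free disease samples are always referred under the sd rule", {
  thr <- compute_thresholds(mean = 0.51, sd = 0.085, k = 3)
  mixes <- c(0, 0.25, 0.5, 0.75, 1)
  cal <- fit_calibration(lapply(mixes, function(m) {
    simulate_melt(m, role = "spike_standard", known_mix = m)
  }))
  for (cls in c("PWS_deletion", "AS_deletion")) {
    r <- cal$map(as.numeric(raw_area_fraction(simulate_melt(true_methylation(cls)))))
    expect_true(call_tier1(r, thr)$referred)
  }
})
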