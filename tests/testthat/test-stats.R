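test_that("PPV arithmetic and percent rendering match screening conventions", {
  expect_equal(ppv(1, 2)$ppv, 0.5)
  expect_identical(ppv(2, 3)$percent, "66.7")
  expect_equal(ppv(0, 5)$ppv, 0)
  expect_error(ppv(1, 0))
  expect_error(ppv(4, 3))
  # rendering conventions: 1 decimal, 2 decimals below 1%
  expect_identical(render_percent(45 / 48), "93.8")
  expect_identical(render_percent(92 / 16579), "0.55")
  expect_identical(render_percent(0.665, digits = 1), "66.5")
  expect_equal(round_half_up(8289.5), 8290)
  expect_equal(round_half_up(-0.005, 2), -0.01)
})

test_that("prevalence renders 1-in-N with exact binomial intervals", {
  p2 <- prevalence(2, 16579)
  expect_identical(p2$one_in_n, 8290L)
  expect_identical(p2$label, "1 in 8290")
  p1 <- prevalence(1, 16579)
  expect_identical(p1$one_in_n, 16579L)
  expect_identical(p1$label, "1 in 16 579")
  # zero observed cases: closed-form upper bound 1 - alpha^(1/n)
  p0 <- prevalence(0, 10)
  expect_true(is.na(p0$one_in_n))
  expect_equal(p0$ci_high, 1 - 0.025^(1 / 10), tolerance = 1e-10)
  expect_equal(p0$ci_low, 0)
})

test_that("Clopper-Pearson equals brute-force binomial tail inversion", {
  cases <- list(c(2, 16579), c(5, 92), c(45, 48), c(1, 10))
  for (kn in cases) {
    got <- clopper_pearson(kn[1], kn[2])
    want <- cp_tail_inversion(kn[1], kn[2])
    expect_lt(max(abs(got - want)), 1e-9)
  }
  expect_equal(clopper_pearson(0, 50)[1], 0)
  expect_equal(clopper_pearson(50, 50)[2], 1)
})

test_that("Clopper-Pearson intervals achieve nominal coverage at rare prevalence", {
  p <- 3e-4; n <- 16579
  set.seed(2022)
  k <- rbinom(2000, n, p)
  covered <- vapply(k, function(ki) {
    ci <- clopper_pearson(ki, n)
    ci[1] <= p && p <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.93)
})

test_that("sensitivity/specificity arithmetic and renderings are exact", {
  ss <- sensitivity_specificity(tp = 45, fp = 0, tn = 100, fn = 3)
  expect_equal(ss$sensitivity, 45 / 48)
  expect_identical(ss$sensitivity_percent, "93.8")
  expect_equal(ss$specificity, 1)
  expect_equal(sensitivity_specificity(0, 0, 5, 1)$sensitivity, 0)
  expect_error(sensitivity_specificity(0, 0, 0, 0), "empty")
})

test_that("one-in-N inverts the prevalence within half a case", {
  set.seed(8)
  for (i in 1:50) {
    screened <- sample(1000:50000, 1)
    confirmed <- sample(1:12, 1)
    oin <- prevalence(confirmed, screened)$one_in_n
    expect_gte(confirmed * oin, screened - confirmed / 2)
    expect_lte(confirmed * oin, screened + confirmed / 2)
  }
})

test_that("tier-flow accounting conserves counts and is order-invariant", {
  tier1 <- data.frame(
    sample_id = sprintf("S%02d", 1:20),
    band = c(rep("negative", 15), "low_band", "low_band", "high_band",
             "high_band", "high_band"),
    stringsAsFactors = FALSE
  )
  tier1$referred <- tier1$band != "negative"
  tier2 <- data.frame(
    sample_id = c("S16", "S17", "S18", "S19", "S20"),
    confirmed = c(TRUE, FALSE, TRUE, FALSE, FALSE),
    qc_flags = c("", "", "", "saturation", ""),
    stringsAsFactors = FALSE
  )
  fl <- tier_flow(tier1, tier2,
                  conditions = c(S16 = "AS", S18 = "PWS"))
  cts <- fl$counts
  expect_identical(cts$n_screened, cts$n_negative + cts$n_flagged)
  expect_identical(cts$n_flagged,
                   cts$n_confirmed + cts$n_unconfirmed + cts$n_qc_failed)
  expect_identical(cts$n_confirmed, 2L)
  expect_identical(cts$n_qc_failed, 1L)
  expect_identical(fl$per_condition$AS$n_confirmed, 1L)
  # shuffling input order leaves every statistic unchanged
  perm <- sample(nrow(tier1))
  fl2 <- tier_flow(tier1[perm, ], tier2[sample(nrow(tier2)), ],
                   conditions = c(S18 = "PWS", S16 = "AS"))
  expect_identical(fl$counts, fl2$counts)
  expect_equal(fl$overall, fl2$overall)
  # empty tier 2: everything flagged is unconfirmed
  fl0 <- tier_flow(tier1, NULL)
  expect_identical(fl0$counts$n_unconfirmed, 5L)
  # foreign sample ids are rejected
  bad <- tier2; bad$sample_id[1] <- "S01"
  expect_error(tier_flow(tier1, bad), "not referred")
})
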