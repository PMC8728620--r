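test_that("binned read-count simulation centres on the copy-number bands", {
  flat <- simulate_bins(NULL, coverage = 100, seed = 21)
  expect_lt(abs(stats::median(flat$log2_ratio)), 0.05)
  expect_identical(nrow(flat), 300L)  # 15 Mb at 50 kb
  expect_true(all(diff(flat$bin_start) == 50000))
  del <- simulate_bins(data.frame(start = 23100000, end = 28300000, copies = 1L),
                       coverage = 100, seed = 22)
  in_del <- del$bin_start >= 23100000 & del$bin_end <= 28300000
  expect_lt(abs(mean(del$log2_ratio[in_del]) - (-1)), 0.1)
  dup <- simulate_bins(data.frame(start = 23100000, end = 28300000, copies = 3L),
                       coverage = 100, seed = 23)
  in_dup <- dup$bin_start >= 23100000 & dup$bin_end <= 28300000
  expect_lt(abs(mean(dup$log2_ratio[in_dup]) - log2(3 / 2)), 0.1)
  expect_error(simulate_bins(NULL, coverage = -1))
})

test_that("HGVS coordinate conversion is an exact bijection", {
  expect_identical(hgvs_segment(23100000, 28300000, 1),
                   "NC_000015.9:g.23100001_28300000del")
  expect_identical(hgvs_segment(22550000, 30100000, 4),
                   "NC_000015.9:g.22550001_30100000[4]")
  set.seed(77)
  for (i in 1:100) {
    s <- sort(sample(20000000:35000000, 2))
    cn <- sample(c(0L, 1L, 3L, 4L, 7L), 1)
    p <- parse_hgvs_segment(hgvs_segment(s[1], s[2], cn))
    expect_identical(c(p$start, p$end), as.numeric(s))
    if (cn >= 2) expect_identical(p$copies, cn)
  }
  expect_error(parse_hgvs_segment("NC_000015.9:g.banana"), "unparseable")
})

test_that("segmentation merges bins, absorbs short runs and is idempotent", {
  # flat diploid track: no segments
  flat <- simulate_bins(NULL, coverage = 100, seed = 31)
  expect_identical(nrow(segment_and_call(flat)), 0L)
  # single deletion: one segment within one bin of the simulated breakpoints
  del <- simulate_bins(data.frame(start = 23100000, end = 28300000, copies = 1L),
                       coverage = 100, seed = 32)
  seg <- segment_and_call(del)
  expect_identical(nrow(seg), 1L)
  expect_identical(seg$copies, 1L)
  expect_lte(abs(seg$start - 23100000), 50000)
  expect_lte(abs(seg$end - 28300000), 50000)
  # a 2-bin blip is absorbed into its neighbourhood
  blip <- segments_to_track(data.frame(start = 25000000, end = 25100000,
                                       copies = 3L, n_bins = 2L,
                                       hgvs = ""))
  expect_identical(nrow(segment_and_call(blip)), 0L)
  # idempotence: re-segmenting a rendered segmentation returns it unchanged
  idic <- simulate_bins(cn_profile_of("Dup15q_idic15"), coverage = 100, seed = 33)
  seg1 <- segment_and_call(idic)
  seg2 <- segment_and_call(segments_to_track(seg1))
  expect_equal(seg1[c("start", "end", "copies")], seg2[c("start", "end", "copies")])
})

test_that("breakpoint snapping and subtype logic cover the recurrent forms", {
  segs <- function(start, end, copies) {
    data.frame(start = start, end = end, copies = as.integer(copies),
               n_bins = 10L, hgvs = hgvs_segment(start, end, copies))
  }
  # normal
  expect_identical(assign_breakpoints(segs(1, 1, 1)[0, ])$label, "normal")
  # type II deletion, condition set by the methylation band
  d2 <- segs(23100000, 28300000, 1)
  expect_identical(assign_breakpoints(d2, meth_band = "low")$label, "AS_del_typeII")
  expect_identical(assign_breakpoints(d2, meth_band = "high")$label, "PWS_del_typeII")
  expect_identical(assign_breakpoints(d2, meth_band = "low")$breakpoints,
                   c("BP2", "BP3"))
  # type I deletion
  d1 <- segs(22300000, 28300000, 1)
  expect_identical(assign_breakpoints(d1, meth_band = "high")$label, "PWS_del_typeI")
  # interstitial duplication
  expect_identical(assign_breakpoints(segs(23100000, 28300000, 3))$label,
                   "interstitial_dup")
  # tricentric
  expect_identical(assign_breakpoints(segs(22550000, 30100000, 7))$label,
                   "tricentric")
  # boundaries far from any landmark stay unclassified with raw coordinates
  far <- segs(24000000, 26000000, 1)
  un <- assign_breakpoints(far, meth_band = "low")
  expect_identical(un$label, "unclassified")
  expect_equal(un$raw_boundaries, c(24000000, 26000000))
})

test_that("subtype recovery is perfect at screening coverage", {
  cases <- list(
    AS_deletion = "low", PWS_deletion = "high",
    Dup15q_interstitial_maternal = "high", Dup15q_idic15 = "high",
    Dup15q_tricentric = "high"
  )
  want <- c(AS_deletion = "AS_del_typeII", PWS_deletion = "PWS_del_typeII",
            Dup15q_interstitial_maternal = "interstitial_dup",
            Dup15q_idic15 = "idic15", Dup15q_tricentric = "tricentric")
  for (g in names(cases)) {
    labels <- vapply(1:100, function(i) {
      tr <- simulate_bins(cn_profile_of(g), coverage = 50, seed = 9000 + 31 * i)
      assign_breakpoints(segment_and_call(tr), meth_band = cases[[g]])$label
    }, character(1))
    expect_true(all(labels == want[[g]]), label = paste("subtype recovery for", g))
  }
})
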