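# Binning, log2 ratio computation and changepoint segmentation.

test_that("bin_genome tiles chromosomes and masks excluded bins", {
  bins <- bin_genome(c(chrA = 125000))
  expect_equal(bins$start, c(0, 50000, 100000))
  expect_equal(bins$end, c(50000, 100000, 125000))

  # exclusion covering 60% of one bin masks it, 40% does not
  excl60 <- data.frame(chrom = "chrA", start = 0, end = 30000)
  excl40 <- data.frame(chrom = "chrA", start = 0, end = 20000)
  expect_equal(bin_genome(c(chrA = 125000), exclude = excl60)$mask,
               c(TRUE, FALSE, FALSE))
  expect_equal(bin_genome(c(chrA = 125000), exclude = excl40)$mask,
               c(FALSE, FALSE, FALSE))

  expect_error(bin_genome(numeric()), "empty")
  expect_error(bin_genome(c(chrA = 1e6), bin_size = 500), ">= 1000")
})

test_that("log2 ratios are depth-normalized and median-centred", {
  # identical coverage -> all zero
  bins <- bin_genome(c(chr1 = 5e6))
  trk <- bin_track(bins, rep(100, nrow(bins)), rep(100, nrow(bins)))
  r <- compute_log2_ratio(trk)
  expect_true(all(abs(r$ratio[r$valid]) < 1e-12))

  # 100 bins, 10 at exactly 2x: those sit at 1, the rest at 0
  trk2 <- bin_track(bin_genome(c(chr1 = 5e6)),
                    c(rep(200, 10), rep(100, 90)), rep(100, 100))
  r2 <- compute_log2_ratio(trk2)
  expect_equal(r2$ratio[1:10], rep(1, 10), tolerance = 1e-6)
  expect_equal(r2$ratio[11:100], rep(0, 90), tolerance = 1e-6)
  expect_lt(abs(median(r2$ratio[r2$valid])), 1e-6)

  # zero control coverage invalidates only that bin
  cov_c <- rep(100, 100)
  cov_c[5] <- 0
  r3 <- compute_log2_ratio(bin_track(bin_genome(c(chr1 = 5e6)),
                                     rep(100, 100), cov_c))
  expect_false(r3$valid[5])
  expect_equal(sum(r3$valid), 99)

  # fully masked track errors
  trk4 <- bin_track(bins, rep(1, nrow(bins)), rep(1, nrow(bins)),
                    mask = rep(TRUE, nrow(bins)))
  expect_error(compute_log2_ratio(trk4), "all bins invalid")
})

test_that("segmentation recovers planted changepoints", {
  # noise-free constant track: one segment per chromosome at 0
  s0 <- segment_log2_ratios(ratio_track(rep(0, 100)))
  expect_equal(nrow(s0), 1)
  expect_equal(s0$log2cnr, 0)
  expect_equal(c(s0$start, s0$end), c(0, 100 * 50000))

  # single step 0 -> 1 at bin 50, sigma 0.2: two segments, breakpoint +-2
  set.seed(21)
  x <- c(rep(0, 50), rep(1, 50)) + rnorm(100, 0, 0.2)
  s1 <- segment_log2_ratios(ratio_track(x))
  expect_equal(nrow(s1), 2)
  expect_lte(abs(s1$end[1] / 50000 - 50), 2)
  expect_lt(abs(s1$log2cnr[1] - 0), 0.1)
  expect_lt(abs(s1$log2cnr[2] - 1), 0.1)

  # three levels 0 / 0.585 / -1 of 60 bins each, sigma 0.15
  set.seed(22)
  x3 <- c(rep(0, 60), rep(0.585, 60), rep(-1, 60)) + rnorm(180, 0, 0.15)
  s3 <- segment_log2_ratios(ratio_track(x3))
  expect_equal(nrow(s3), 3)
  expect_lt(max(abs(s3$log2cnr - c(0, 0.585, -1))), 0.1)
})

test_that("segmentation is idempotent on noise-free piecewise tracks", {
  x <- c(rep(0.3, 30), rep(-0.7, 40), rep(0.3, 30))
  s <- segment_log2_ratios(ratio_track(x))
  expect_equal(nrow(s), 3)
  # rebuild the track from the fitted segments and re-segment
  x2 <- rep(s$log2cnr, times = (s$end - s$start) / 50000)
  s2 <- segment_log2_ratios(ratio_track(x2))
  expect_equal(s2$start, s$start)
  expect_equal(s2$end, s$end)
  expect_equal(s2$log2cnr, s$log2cnr, tolerance = 1e-12)
})

test_that("segment means equal the mean of their member bins", {
  set.seed(30)
  x <- c(rep(0, 40), rep(0.8, 40)) + rnorm(80, 0, 0.1)
  trk <- ratio_track(x)
  s <- segment_log2_ratios(trk)
  for (i in seq_len(nrow(s))) {
    member <- trk$start >= s$start[i] & trk$start < s$end[i] & trk$valid
    expect_equal(s$log2cnr[i], mean(trk$ratio[member]))
  }
})

test_that("swapping test and control negates segment means", {
  set.seed(31)
  bins <- bin_genome(c(chr1 = 1e7))
  cov_t <- rpois(nrow(bins), rep(c(200, 400, 200, 100), each = 50))
  cov_c <- rpois(nrow(bins), 200)
  fwd <- segment_log2_ratios(compute_log2_ratio(bin_track(bins, cov_t, cov_c)))
  rev <- segment_log2_ratios(compute_log2_ratio(bin_track(bins, cov_c, cov_t)))
  expect_equal(nrow(fwd), nrow(rev))
  expect_equal(fwd$log2cnr, -rev$log2cnr, tolerance = 1e-9)
})

test_that("invalid-bin gaps are inherited by the preceding segment", {
  x <- c(rep(0, 30), rep(NA, 5), rep(1, 30))
  s <- segment_log2_ratios(ratio_track(x))
  expect_equal(nrow(s), 2)
  # the whole chromosome stays covered, gap absorbed at the boundary
  expect_equal(s$start[1], 0)
  expect_equal(s$end[2], 65 * 50000)
  expect_equal(s$end[1], s$start[2])
})

test_that("short chromosomes fall back to whole-chromosome segments", {
  expect_warning(s <- segment_log2_ratios(ratio_track(rep(0.2, 3))),
                 "fewer than min_seg_bins")
  expect_equal(nrow(s), 1)
  expect_equal(s$log2cnr, 0.2)
})

test_that("cnr_from_log2 converts and clips", {
  expect_equal(cnr_from_log2(0), 1)
  expect_equal(cnr_from_log2(log2(3 / 2)), 1.5)
  expect_equal(cnr_from_log2(-6, clip = c(0.0625, 16)), 0.0625)
  expect_equal(cnr_from_log2(10, clip = c(0.0625, 16)), 16)
  expect_error(cnr_from_log2(0, clip = c(-1, 2)), "lo > 0")
})
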