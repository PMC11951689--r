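# Peak-to-segment assignment and count scaling.

test_that("assignment follows overlap, tie-break and fallback rules", {
  segs <- segment_table(c("chr1", "chr1"), c(0, 150), c(150, 400),
                        c(0, 1))

  # containment
  pk <- peak_table("chr1", 200, 300, "inside")
  a <- assign_peaks(pk, segment_table("chr1", 0, 1000, 0.5))
  expect_equal(a$kind, "overlap")
  expect_equal(a$cnr, 2^0.5)

  # tie on overlap length: 50/50 split, A's midpoint (75) is nearer the
  # peak midpoint (150) than B's (275) -> A
  tie <- assign_peaks(peak_table("chr1", 100, 200, "tie"), segs)
  expect_equal(tie$segment_index, 1)
  expect_equal(tie$log2cnr, 0)

  # no overlap: nearest segment on the same chromosome
  near <- assign_peaks(peak_table("chr1", 500, 600, "off"), segs)
  expect_equal(near$kind, "nearest")
  expect_equal(near$segment_index, 2)
  expect_equal(near$distance, 100)

  # chromosome without segments: neutral fallback with warning
  expect_warning(fb <- assign_peaks(peak_table("chrX", 0, 100, "solo"), segs),
                 "without segments")
  expect_equal(fb$kind, "fallback")
  expect_equal(fb$cnr, 1)
  expect_true(is.na(fb$segment_index))
})

test_that("assignment clips extreme ratios", {
  seg <- segment_table("chr1", 0, 1000, -8)
  a <- assign_peaks(peak_table("chr1", 10, 20, "p"), seg)
  expect_equal(a$cnr, 1 / 16)
})

test_that("scaling shrinks exactly the higher-copy side", {
  K <- matrix(c(300, 180, 70, 100), 2, 2, byrow = TRUE,
              dimnames = list(c("gain", "loss"), c("bs", "wt")))
  m <- count_matrix(K, c(bs = "test", wt = "control"))
  asg <- data.frame(peak_name = c("gain", "loss"),
                    segment_index = c(1L, 2L),
                    log2cnr = c(log2(1.5), -1), cnr = c(1.5, 0.5),
                    kind = "overlap", distance = 0)
  out <- scale_counts(m, asg, rounding = "none")
  # trisomy case: test 300 -> 200, control untouched
  expect_equal(out$counts["gain", ], c(bs = 200, wt = 180))
  # loss case: control 100 -> 50, test untouched
  expect_equal(out$counts["loss", ], c(bs = 70, wt = 50))

  # neutral ratios are the identity
  asg1 <- transform(asg, cnr = 1, log2cnr = 0)
  expect_equal(scale_counts(m, asg1, rounding = "none")$counts, K)

  # missing assignment errors
  expect_error(scale_counts(m, asg[1, ]), "missing assignment")
})

test_that("half-even rounding keeps the exact matrix as metadata", {
  K <- matrix(c(5, 8), 1, 2, dimnames = list("p", c("a", "b")))
  m <- count_matrix(K, c(a = "test", b = "control"))
  asg <- data.frame(peak_name = "p", segment_index = 1L, log2cnr = 1,
                    cnr = 2, kind = "overlap", distance = 0)
  out <- scale_counts(m, asg, rounding = "half_even")
  expect_equal(unname(out$counts["p", "a"]), 2)  # 2.5 rounds to even
  expect_equal(unname(out$unrounded["p", "a"]), 2.5)
  expect_equal(unname(out$counts["p", "b"]), 8)
})

test_that("corrected counts never exceed the originals", {
  set.seed(40)
  n <- 300
  pk <- peak_table("chr1", (0:(n - 1)) * 2000, (0:(n - 1)) * 2000 + 500,
                   sprintf("p%03d", 1:n))
  segs <- segment_table("chr1", seq(0, 5e5, 1e5), seq(1e5, 6e5, 1e5),
                        runif(6, -2, 2))
  K <- matrix(rpois(n * 4, 80), n, 4,
              dimnames = list(pk$name, c("t1", "t2", "c1", "c2")))
  m <- count_matrix(K, c(t1 = "test", t2 = "test",
                         c1 = "control", c2 = "control"))
  norm <- cn_normalize(pk, segs, m, rounding = "none")
  expect_lte(max(norm$matrix$counts - K), 0)
  rounded <- cn_normalize(pk, segs, m, rounding = "half_even")
  expect_lte(max(rounded$matrix$counts - K), 0.5)

  # exactly one condition modified per peak (pre-rounding)
  r <- norm$assignments$cnr
  test_cols <- c("t1", "t2")
  ctrl_cols <- c("c1", "c2")
  hi <- r >= 1
  expect_equal(norm$matrix$counts[hi, ctrl_cols], K[hi, ctrl_cols] + 0, tolerance = 0)
  expect_equal(norm$matrix$counts[!hi, test_cols], K[!hi, test_cols] + 0, tolerance = 0)
})

test_that("the normalization pipeline composes and reports per peak", {
  pk <- peak_table("chr1", c(0, 1000, 2000, 3000, 4000),
                   c(500, 1500, 2500, 3500, 4500), paste0("p", 1:5))
  segs <- segment_table(c("chr1", "chr1"), c(0, 2000), c(2000, 5000),
                        c(1, 0))
  K <- matrix(100, 5, 2, dimnames = list(pk$name, c("t", "c")))
  m <- count_matrix(K, c(t = "test", c = "control"))
  res <- cn_normalize(pk, segs, m, rounding = "none")
  expect_equal(nrow(res$assignments), 5)
  # only the test counts of peaks in the gain segment halve
  expect_equal(unname(res$matrix$counts[, "t"]), c(50, 50, 100, 100, 100))
  expect_equal(unname(res$matrix$counts[, "c"]), rep(100, 5))

  # a second pass with neutral segments is the identity
  neutral <- segment_table("chr1", 0, 5000, 0)
  res2 <- cn_normalize(pk, neutral, res$matrix, rounding = "none")
  expect_equal(res2$matrix$counts, res$matrix$counts)
})

test_that("scaling centres dosage-driven fold changes at zero", {
  sim <- simulate_experiment(simulation_config(seed = 4))
  norm <- cn_normalize(sim$peaks, true_segments(sim), sim$counts,
                       rounding = "none")
  cond <- sim$counts$condition
  lfc <- function(M) {
    log2(rowMeans(M[, cond == "test"]) / rowMeans(M[, cond == "control"]))
  }
  tp <- sim$truth$peaks
  for (lc in unique(round(tp$log2cnr, 6))) {
    i <- round(tp$log2cnr, 6) == lc
    expect_lt(abs(mean(lfc(sim$counts$counts)[i]) - lc), 0.1)
    expect_lt(abs(mean(lfc(norm$matrix$counts)[i])), 0.1)
  }
})
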