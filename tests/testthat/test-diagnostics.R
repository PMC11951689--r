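# Bias diagnostics: LOESS trend, status proportions, chi-square
# enrichment, MA data, CNR-binned status.

fake_results <- function(log2fc, status = "nd", peak = NULL) {
  n <- length(log2fc)
  data.frame(peak = peak %||% sprintf("p%04d", seq_len(n)),
             base_mean = 100, log2fc = log2fc, se = 0.1,
             stat = log2fc / 0.1, p = 0.5, padj = 1,
             status = rep_len(status, n), tested = TRUE,
             stringsAsFactors = FALSE)
}

fake_assignments <- function(log2cnr, peak = NULL) {
  n <- length(log2cnr)
  data.frame(peak_name = peak %||% sprintf("p%04d", seq_len(n)),
             segment_index = 1L, log2cnr = log2cnr, cnr = 2^log2cnr,
             kind = "overlap", distance = 0, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("bias_trend reproduces exact linear and flat relations", {
  set.seed(90)
  x <- runif(200, -1.5, 1.5)

  ident <- bias_trend(fake_results(x), fake_assignments(x))
  expect_equal(ident$slope, 1, tolerance = 1e-9)
  expect_equal(ident$fitted, ident$grid, tolerance = 1e-6)
  expect_true(all(ident$ci_low <= ident$fitted + 1e-12 &
                  ident$fitted <= ident$ci_high + 1e-12))

  flat <- bias_trend(fake_results(rep(0, 200)), fake_assignments(x))
  expect_equal(flat$slope, 0, tolerance = 1e-9)
  expect_equal(flat$fitted, rep(0, 50), tolerance = 1e-6)

  expect_error(bias_trend(fake_results(x[1:10]), fake_assignments(x[1:10])),
               ">= 30 peaks")
})

test_that("bias_trend slope ignores a constant fold-change offset", {
  set.seed(91)
  x <- runif(300, -1, 1)
  y <- x + rnorm(300, 0, 0.1)
  t0 <- bias_trend(fake_results(y), fake_assignments(x))
  t1 <- bias_trend(fake_results(y + 0.7), fake_assignments(x))
  expect_equal(t1$slope, t0$slope, tolerance = 1e-9)
  expect_equal(t1$intercept, t0$intercept + 0.7, tolerance = 1e-9)
})

test_that("status proportions recompute the published genome-wide split", {
  # 143,460 peaks: 42,831 up, 46,685 down -> 29.86% / 32.54%, and
  # 89,516 significant -> 62.40%
  n <- 143460
  status <- rep("nd", n)
  status[1:42831] <- "up"
  status[42832:(42831 + 46685)] <- "down"
  res <- fake_results(rep(0, n), status = status)
  sp <- status_proportions(res)
  expect_equal(sp$pct[sp$status == "up"], 29.86)
  expect_equal(sp$pct[sp$status == "down"], 32.54)
  expect_equal(round(100 * (42831 + 46685) / n, 2), 62.40)

  # all-nd input
  sp0 <- status_proportions(fake_results(rep(0, 10)))
  expect_equal(sp0$pct, c(0, 0, 100))

  # 3 up / 2 down / 5 nd
  sp3 <- status_proportions(fake_results(rep(0, 10),
                                         c(rep("up", 3), rep("down", 2),
                                           rep("nd", 5))))
  expect_equal(sp3$pct, c(30, 20, 50))

  expect_error(status_proportions(res, subset = character(0)), "empty subset")
})

test_that("status percentages sum to 100 within rounding", {
  set.seed(92)
  for (i in 1:20) {
    n <- sample(3:997, 1)
    res <- fake_results(rep(0, n),
                        sample(c("up", "down", "nd"), n, replace = TRUE))
    expect_lt(abs(sum(status_proportions(res)$pct) - 100), 0.02)
  }
})

test_that("chi-square enrichment matches a brute-force oracle", {
  # homogeneous subset gives zero
  h <- enrichment_chisq(c(30, 30, 40), c(300, 300, 400))
  expect_equal(h$chi2, 0, tolerance = 1e-12)
  expect_equal(h$df, 2)

  # independent looped Sum((O-E)^2/E) oracle
  brute <- function(tab) {
    rs <- rowSums(tab); cs <- colSums(tab); tot <- sum(tab)
    chi <- 0
    for (i in 1:2) for (j in 1:3) {
      e <- rs[i] * cs[j] / tot
      if (e > 0) chi <- chi + (tab[i, j] - e)^2 / e
    }
    as.numeric(chi)
  }

  # exhaustive over all 2x3 tables with entries <= 3 (reference row
  # positive), plus seeded random tables with entries <= 20
  grid <- expand.grid(a = 0:3, b = 0:3, c = 0:3, d = 1:3, e = 1:3, f = 1:3)
  for (k in sample(nrow(grid), 300)) {
    g <- as.numeric(grid[k, ])
    sub <- g[1:3]; ref <- g[4:6]
    out <- enrichment_chisq(sub, ref)
    expect_equal(out$chi2, brute(out$table), tolerance = 1e-12)
  }
  set.seed(93)
  for (k in 1:200) {
    sub <- sample(0:20, 3, replace = TRUE)
    ref <- sample(1:20, 3, replace = TRUE)
    out <- enrichment_chisq(sub, ref)
    expect_equal(out$chi2, brute(out$table), tolerance = 1e-12)
  }

  # subset-of-reference construction subtracts the subset
  sub <- c(10, 0, 10); ref <- c(20, 10, 30)
  out <- enrichment_chisq(sub, ref)
  expect_equal(unname(out$table["other", ]), ref - sub)

  # the padded textbook table, checked against stats::chisq.test too
  out2 <- enrichment_chisq(c(10, 0, 10), c(10, 10, 20))
  ref2 <- suppressWarnings(chisq.test(out2$table, correct = FALSE))
  expect_equal(out2$chi2, unname(ref2$statistic), tolerance = 1e-12)
  expect_equal(out2$p, ref2$p.value, tolerance = 1e-12)

  # warning attached when an expected cell drops below 1
  expect_false(is.null(enrichment_chisq(c(1, 0, 0), c(1, 1, 50))$warning))
  expect_error(enrichment_chisq(c(1, 1, 1), c(0, 5, 5)), "> 0")
})

test_that("MA data mirrors results and round-trips through TSV", {
  set.seed(94)
  res <- fake_results(rnorm(50), sample(c("up", "down", "nd"), 50, TRUE))
  res$base_mean <- rlnorm(50, 4, 1)
  res$padj <- runif(50)
  md <- ma_data(res)
  expect_equal(nrow(md), 50)
  expect_equal(md$log10_mean, log10(md$base_mean))

  all_nd <- ma_data(fake_results(rnorm(20)))
  expect_false(any(all_nd$significant))

  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(md, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(back$log2fc, md$log2fc, tolerance = 1e-9)
  expect_equal(back$base_mean, md$base_mean, tolerance = 1e-9)
})

test_that("CNR-binned status reports per-bin proportions", {
  set.seed(95)
  x <- runif(100, -0.4, 0.4)  # all inside one central bin
  res <- fake_results(rep(0, 100),
                      sample(c("up", "down", "nd"), 100, TRUE))
  tab <- cnr_binned_status(res, fake_assignments(x), c(-2, -0.5, 0.5, 2))
  expect_equal(tab$n, c(0, 100, 0))
  glob <- status_proportions(res)
  expect_equal(tab$prop_up[2], glob$prop[glob$status == "up"])
  expect_true(is.na(tab$prop_up[1]))
  expect_error(cnr_binned_status(res, fake_assignments(x), c(1, 1)),
               "strictly increasing")
})

test_that("binned status shows and loses the dosage gradient", {
  sim <- simulate_experiment(simulation_config(seed = 6))
  norm <- cn_normalize(sim$peaks, true_segments(sim), sim$counts)
  res_raw <- wald_test(sim$counts)
  res_cn <- wald_test(norm$matrix)
  edges <- c(-1.5, -0.5, 0.25, 1.5)
  raw_tab <- cnr_binned_status(res_raw, norm$assignments, edges)
  expect_true(all(diff(raw_tab$prop_up) > 0))
  cn_tab <- cnr_binned_status(res_cn, norm$assignments, edges)
  expect_lt(max(cn_tab$prop_up) - min(cn_tab$prop_up), 0.10)
})
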