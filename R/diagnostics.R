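# Diagnostics quantifying copy-number-driven bias in differential
# results: the LOESS trend of log2 fold change against segment log2 CNR,
# status proportions for region sets, chi-square enrichment of status
# composition, MA-plot data, and status proportions binned by CNR.
# Plots are emitted as data tables; rendering is left to the user.

# Internal: join results to assigned log2cnr by peak name.
.join_results_cnr <- function(results, assignments) {
  idx <- match(results$peak, assignments$peak_name)
  data.frame(peak = results$peak, log2fc = results$log2fc,
             log2cnr = assignments$log2cnr[idx],
             tested = results$tested, status = results$status,
             stringsAsFactors = FALSE)
}

#' LOESS trend of log2 fold change against log2 CNR
#'
#' Fits a locally weighted running-line smoother (tricube weights, degree
#' 1) of per-peak log2 fold change on the assigned segment log2 CNR,
#' evaluated on an evenly spaced grid, with a 95% band from the local
#' standard errors; the overall slope comes from an ordinary least-squares
#' fit.  On copy-number-blind results from dosage-driven data the slope
#' approaches 1; after copy-number normalization it approaches 0.
#'
#' @param results Output of [wald_test()].
#' @param assignments Output of [assign_peaks()] for the same peaks.
#' @param span LOESS span; default 0.3.
#' @param grid_n Number of grid points; default 50.
#' @return A list of class `cn_bias_trend`: `grid`, `fitted`, `ci_low`,
#'   `ci_high`, `slope`, `intercept`, `n`.
#' @export
bias_trend <- function(results, assignments, span = 0.3, grid_n = 50) {
  d <- .join_results_cnr(results, assignments)
  d <- d[d$tested & is.finite(d$log2fc) & is.finite(d$log2cnr), , drop = FALSE]
  if (nrow(d) < 30) {
    stop("bias_trend needs >= 30 peaks with finite log2fc and assigned log2cnr")
  }
  fit <- suppressWarnings(stats::loess(
    log2fc ~ log2cnr, data = d, span = span, degree = 1, family = "gaussian",
    control = stats::loess.control(surface = "direct")))
  grid <- seq(min(d$log2cnr), max(d$log2cnr), length.out = grid_n)
  pr <- suppressWarnings(stats::predict(fit, newdata = data.frame(log2cnr = grid),
                                        se = TRUE))
  se <- ifelse(is.finite(pr$se.fit), pr$se.fit, 0)
  ols <- stats::lm(log2fc ~ log2cnr, data = d)
  structure(list(grid = grid, fitted = as.numeric(pr$fit),
                 ci_low = as.numeric(pr$fit) - 1.96 * se,
                 ci_high = as.numeric(pr$fit) + 1.96 * se,
                 slope = unname(stats::coef(ols)[2]),
                 intercept = unname(stats::coef(ols)[1]),
                 n = nrow(d)),
            class = "cn_bias_trend")
}

#' @export
print.cn_bias_trend <- function(x, ...) {
  cat("cn_bias_trend: slope of log2FC on log2CNR = ",
      format(x$slope, digits = 4), " (n = ", x$n, " peaks)\n", sep = "")
  invisible(x)
}

#' Differential status proportions of a peak set
#'
#' Counts and percentages of up / down / not-differential peaks, optionally
#' restricted to a subset of peak names (or a predicate on names).
#' Percentages are rounded to two decimals for reporting.
#'
#' @param results Output of [wald_test()].
#' @param subset Optional character vector of peak names, logical vector,
#'   or predicate `function(name) -> logical`.
#' @return A `data.frame` with columns `status`, `n`, `prop`, `pct`.
#' @export
status_proportions <- function(results, subset = NULL) {
  if (nrow(results) == 0) {
    stop("results must be non-empty")
  }
  sel <- rep(TRUE, nrow(results))
  if (!is.null(subset)) {
    sel <- if (is.function(subset)) {
      vapply(results$peak, subset, logical(1))
    } else if (is.logical(subset)) {
      subset
    } else {
      results$peak %in% subset
    }
  }
  d <- results[sel, , drop = FALSE]
  if (nrow(d) == 0) {
    stop("empty subset")
  }
  tab <- table(factor(d$status, levels = c("up", "down", "nd")))
  prop <- as.numeric(tab) / nrow(d)
  data.frame(status = names(tab), n = as.integer(tab), prop = prop,
             pct = round(100 * prop, 2), stringsAsFactors = FALSE)
}

#' Chi-square enrichment of status composition
#'
#' Pearson chi-square homogeneity test on the 2 x 3 table of
#' (up, down, nd) counts for a region set against a reference set.  When
#' the subset is contained in the reference (all counts less than or equal
#' and a smaller total), the second row is reference minus subset;
#' otherwise the two rows are used as given.  Empty status columns
#' contribute 0.  A warning string is attached when any expected cell is
#' below 1.
#'
#' @param subset_counts Length-3 numeric vector of (up, down, nd) counts.
#' @param reference_counts Length-3 numeric vector of (up, down, nd)
#'   counts; all must be > 0.
#' @return A list of class `cn_status_table`: `table`, `expected`, `chi2`,
#'   `df` (= 2), `p`, `proportions` and `warning` (`NULL` or a message).
#' @export
enrichment_chisq <- function(subset_counts, reference_counts) {
  subset_counts <- as.numeric(subset_counts)
  reference_counts <- as.numeric(reference_counts)
  if (length(subset_counts) != 3 || length(reference_counts) != 3) {
    stop("counts must be length-3 vectors (up, down, nd)")
  }
  if (any(reference_counts <= 0)) {
    stop("all reference counts must be > 0")
  }
  other <- if (all(subset_counts <= reference_counts) &&
               sum(subset_counts) < sum(reference_counts)) {
    reference_counts - subset_counts
  } else {
    reference_counts
  }
  tab <- rbind(subset = subset_counts, other = other)
  colnames(tab) <- c("up", "down", "nd")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  contrib <- (tab - expected)^2 / expected
  contrib[expected == 0] <- 0
  chi2 <- sum(contrib)
  warn <- if (any(expected < 1)) {
    "expected cell count < 1; chi-square approximation unreliable"
  } else {
    NULL
  }
  structure(list(table = tab, expected = expected, chi2 = chi2, df = 2,
                 p = stats::pchisq(chi2, df = 2, lower.tail = FALSE),
                 proportions = sweep(tab, 1, rowSums(tab), "/"),
                 warning = warn),
            class = "cn_status_table")
}

#' @export
print.cn_status_table <- function(x, ...) {
  cat("cn_status_table: chi2 = ", format(x$chi2, digits = 6),
      ", df = ", x$df, ", p = ", format(x$p, digits = 4), "\n", sep = "")
  print(x$table)
  if (!is.null(x$warning)) cat("warning: ", x$warning, "\n", sep = "")
  invisible(x)
}

#' Per-peak MA-plot data
#'
#' Mean normalized count (with its log10 for plotting), log2 fold change,
#' adjusted p-value and a significance flag, one row per result.
#'
#' @param results Output of [wald_test()].
#' @param alpha_sig Significance level on the adjusted p-value; default
#'   0.05.
#' @return A `data.frame` with columns `peak`, `base_mean`, `log10_mean`,
#'   `log2fc`, `padj`, `significant`.
#' @export
ma_data <- function(results, alpha_sig = 0.05) {
  data.frame(peak = results$peak, base_mean = results$base_mean,
             log10_mean = ifelse(results$base_mean > 0,
                                 log10(results$base_mean), NA_real_),
             log2fc = results$log2fc, padj = results$padj,
             significant = results$tested & results$padj < alpha_sig,
             stringsAsFactors = FALSE)
}

#' Status proportions per log2 CNR bin
#'
#' Bins peaks by their assigned segment log2 CNR into `[edge_i, edge_{i+1})`
#' intervals and reports the proportion of up / down / not-differential
#' peaks per bin.  Empty bins are reported with `n = 0`.
#'
#' @param results Output of [wald_test()].
#' @param assignments Output of [assign_peaks()] for the same peaks.
#' @param bin_edges Strictly increasing numeric vector of log2 CNR edges.
#' @return A `data.frame` with columns `bin_lo`, `bin_hi`, `n`, `prop_up`,
#'   `prop_down`, `prop_nd`.
#' @export
cnr_binned_status <- function(results, assignments, bin_edges) {
  if (length(bin_edges) < 2 || any(diff(bin_edges) <= 0)) {
    stop("bin_edges must be strictly increasing with >= 2 values")
  }
  d <- .join_results_cnr(results, assignments)
  d <- d[is.finite(d$log2cnr), , drop = FALSE]
  nb <- length(bin_edges) - 1
  bin <- findInterval(d$log2cnr, bin_edges, rightmost.closed = TRUE,
                      left.open = FALSE)
  rows <- lapply(seq_len(nb), function(i) {
    s <- d$status[bin == i]
    n <- length(s)
    data.frame(bin_lo = bin_edges[i], bin_hi = bin_edges[i + 1], n = n,
               prop_up = if (n) mean(s == "up") else NA_real_,
               prop_down = if (n) mean(s == "down") else NA_real_,
               prop_nd = if (n) mean(s == "nd") else NA_real_)
  })
  do.call(rbind, rows)
}
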