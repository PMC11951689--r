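# Copy-number normalization: assign each peak to its overlapping (or
# nearest) CNR segment and rescale the peak's counts to a common copy
# number before any data normalization.  The higher-copy side is always
# the one shrunk, so the correction can only reduce statistical power,
# never inflate it.

#' Assign peaks to copy-number segments
#'
#' Each peak receives the segment with the largest overlap; ties are broken
#' by the segment whose midpoint is closest to the peak midpoint, then by
#' the leftmost segment.  Peaks with no overlapping segment take the
#' nearest segment on the same chromosome (`kind = "nearest"`).  Peaks on a
#' chromosome with no segments fall back to a neutral ratio of 1
#' (`kind = "fallback"`) with a warning.
#'
#' @param peaks A peak `data.frame` (see [peak_table()]).
#' @param segments A segment `data.frame` (see [segment_table()]).
#' @param clip CNR clipping bounds applied to the scaling ratio;
#'   see [cnr_from_log2()].
#' @return A `data.frame` with one row per peak: `peak_name`,
#'   `segment_index` (row in the sorted segment table; `NA` for fallback),
#'   `log2cnr`, `cnr` (clipped scaling ratio), `kind`
#'   (`overlap`/`nearest`/`fallback`) and `distance` (bp gap; 0 for
#'   overlaps, `NA` for fallback).
#' @export
assign_peaks <- function(peaks, segments, clip = c(1 / 16, 16)) {
  peaks <- validate_peaks(peaks)
  segments <- validate_segments(segments)
  n <- nrow(peaks)
  seg_idx <- rep(NA_integer_, n)
  kind <- rep("fallback", n)
  distance <- rep(NA_real_, n)
  if (n == 0) {
    return(data.frame(peak_name = character(), segment_index = integer(),
                      log2cnr = numeric(), cnr = numeric(),
                      kind = character(), distance = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (nrow(segments) > 0) {
    gp <- .df_to_granges(peaks)
    gs <- .df_to_granges(segments)
    # peaks on chromosomes absent from the segment set trigger a noisy
    # seqlevel warning; the fallback path below reports them properly
    hits <- suppressWarnings(GenomicRanges::findOverlaps(gp, gs))
    if (length(hits) > 0) {
      q <- S4Vectors::queryHits(hits)
      s <- S4Vectors::subjectHits(hits)
      ov <- IRanges::width(IRanges::pintersect(gp[q], gs[s]))
      peak_mid <- (peaks$start + peaks$end) / 2
      seg_mid <- (segments$start + segments$end) / 2
      mid_dist <- abs(seg_mid[s] - peak_mid[q])
      # best overlap per peak: max width, then nearest midpoint, then leftmost
      ord <- order(q, -ov, mid_dist, segments$start[s], s)
      first <- !duplicated(q[ord])
      seg_idx[q[ord][first]] <- s[ord][first]
      kind[q[ord][first]] <- "overlap"
      distance[q[ord][first]] <- 0
    }
    todo <- which(is.na(seg_idx) & peaks$chrom %in% segments$chrom)
    if (length(todo) > 0) {
      near <- suppressWarnings(GenomicRanges::distanceToNearest(gp[todo], gs))
      qh <- S4Vectors::queryHits(near)
      seg_idx[todo[qh]] <- S4Vectors::subjectHits(near)
      kind[todo[qh]] <- "nearest"
      distance[todo[qh]] <- S4Vectors::mcols(near)$distance
    }
  }
  n_fallback <- sum(kind == "fallback")
  if (n_fallback > 0) {
    warning(n_fallback, " peak(s) on chromosomes without segments; ",
            "assigned neutral ratio 1")
  }
  log2cnr <- ifelse(is.na(seg_idx), 0, segments$log2cnr[seg_idx])
  cnr <- ifelse(is.na(seg_idx), 1, cnr_from_log2(log2cnr, clip))
  data.frame(peak_name = peaks$name, segment_index = seg_idx,
             log2cnr = log2cnr, cnr = cnr, kind = kind, distance = distance,
             stringsAsFactors = FALSE)
}

#' Rescale peak counts to a common copy number
#'
#' For each peak with scaling ratio `r` (test copy number over control copy
#' number): if `r >= 1` the counts of all test-condition samples are
#' divided by `r`; if `r < 1` the counts of all control-condition samples
#' are multiplied by `r`.  The other condition is left untouched, so the
#' correction always shrinks the higher-copy side and counts never
#' increase.  With `rounding = "half_even"` the scaled matrix is rounded to
#' integers (ties to even) for downstream integer-count engines, and the
#' pre-rounding matrix is retained in the `unrounded` element.
#'
#' @param mat A [count_matrix()] object.
#' @param assignments Output of [assign_peaks()] covering every peak in
#'   `mat`.
#' @param rounding `"half_even"` (default) or `"none"`.
#' @return A `cn_count_matrix` with scaled counts (and, when rounded, an
#'   `unrounded` element holding the exact scaled matrix).
#' @export
scale_counts <- function(mat, assignments, rounding = c("half_even", "none")) {
  rounding <- match.arg(rounding)
  stopifnot(inherits(mat, "cn_count_matrix"))
  idx <- match(rownames(mat$counts), assignments$peak_name)
  if (any(is.na(idx))) {
    stop("missing assignment for peak(s): ",
         paste(utils::head(rownames(mat$counts)[is.na(idx)], 5), collapse = ", "))
  }
  r <- assignments$cnr[idx]
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("scaling ratios must be positive and finite")
  }
  scaled <- mat$counts
  test_cols <- which(mat$condition == "test")
  ctrl_cols <- which(mat$condition == "control")
  hi <- r >= 1
  scaled[hi, test_cols] <- scaled[hi, test_cols, drop = FALSE] / r[hi]
  scaled[!hi, ctrl_cols] <- scaled[!hi, ctrl_cols, drop = FALSE] * r[!hi]
  out <- count_matrix(if (rounding == "half_even") round(scaled) else scaled,
                      mat$condition, mat$peaks)
  if (rounding == "half_even") {
    out$unrounded <- scaled
  }
  out
}

#' Copy-number normalization pipeline step
#'
#' Composition of [assign_peaks()] and [scale_counts()].  Returns the
#' corrected matrix together with a per-peak assignment report; downstream
#' size factors must be computed on the corrected matrix, never the raw
#' one.
#'
#' @param peaks Peak `data.frame`; must match the rows of `mat`.
#' @param segments Segment `data.frame`.
#' @param mat A [count_matrix()] object.
#' @param clip CNR clipping bounds (see [cnr_from_log2()]).
#' @param rounding Passed to [scale_counts()].
#' @return A list of class `cn_normalization` with elements `matrix` (the
#'   scaled `cn_count_matrix`) and `assignments` (the per-peak report:
#'   segment, log2cnr, ratio, assignment kind, distance).
#' @export
cn_normalize <- function(peaks, segments, mat, clip = c(1 / 16, 16),
                         rounding = c("half_even", "none")) {
  rounding <- match.arg(rounding)
  peaks <- validate_peaks(peaks)
  stopifnot(inherits(mat, "cn_count_matrix"))
  if (!setequal(peaks$name, rownames(mat$counts))) {
    stop("peak table and count matrix refer to different peak sets")
  }
  peaks <- peaks[match(rownames(mat$counts), peaks$name), , drop = FALSE]
  assignments <- assign_peaks(peaks, segments, clip)
  scaled <- scale_counts(mat, assignments, rounding)
  structure(list(matrix = scaled, assignments = assignments),
            class = "cn_normalization")
}

#' @export
print.cn_normalization <- function(x, ...) {
  k <- table(factor(x$assignments$kind,
                    levels = c("overlap", "nearest", "fallback")))
  cat("cn_normalization: ", nrow(x$assignments), " peaks (",
      k[["overlap"]], " overlap, ", k[["nearest"]], " nearest, ",
      k[["fallback"]], " fallback)\n", sep = "")
  invisible(x)
}
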