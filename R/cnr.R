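# Copy-number-ratio estimation from binned coverage of a test and a
# control sample: tile the genome into fixed bins, form depth-normalized
# median-centred log2 coverage ratios, and segment them into runs of
# constant CNR by recursive binary segmentation.

#' Tile a genome into fixed-width bins
#'
#' Produces non-overlapping bins of `bin_size` bp covering `[0, L)` of
#' every chromosome (the terminal bin may be shorter).  Bins whose overlap
#' with the exclusion intervals exceeds half the bin width are masked.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param bin_size Bin width in bp (>= 1000); default 50 kb.
#' @param exclude Optional data frame of intervals (`chrom`, `start`,
#'   `end`, 0-based half-open) to mask, e.g. assembly gaps or blacklists.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `mask`.
#' @export
bin_genome <- function(chrom_sizes, bin_size = 50000, exclude = NULL) {
  if (length(chrom_sizes) == 0) {
    stop("chrom_sizes must not be empty")
  }
  if (is.null(names(chrom_sizes)) || any(names(chrom_sizes) == "")) {
    stop("chrom_sizes must be a named vector")
  }
  if (any(chrom_sizes <= 0)) {
    stop("chromosome lengths must be > 0")
  }
  if (bin_size < 1000) {
    stop("bin_size must be >= 1000 bp")
  }
  pieces <- lapply(names(chrom_sizes), function(ch) {
    L <- chrom_sizes[[ch]]
    start <- seq(0, L - 1, by = bin_size)
    data.frame(chrom = ch, start = start, end = pmin(start + bin_size, L),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, pieces)
  mask <- rep(FALSE, nrow(bins))
  if (!is.null(exclude) && nrow(exclude) > 0) {
    gb <- .df_to_granges(bins)
    ge <- GenomicRanges::reduce(.df_to_granges(exclude))
    hits <- GenomicRanges::findOverlaps(gb, ge)
    if (length(hits) > 0) {
      ov <- IRanges::width(IRanges::pintersect(
        gb[S4Vectors::queryHits(hits)], ge[S4Vectors::subjectHits(hits)]))
      covered <- tapply(ov, S4Vectors::queryHits(hits), sum)
      idx <- as.integer(names(covered))
      width <- bins$end[idx] - bins$start[idx]
      mask[idx] <- as.numeric(covered) > 0.5 * width
    }
  }
  bins$mask <- mask
  rownames(bins) <- NULL
  bins
}

#' Median-centred log2 coverage ratio per bin
#'
#' For each usable bin `b`, computes
#' `log2((cov_test_b / N_test) / (cov_control_b / N_control))` with `N` the
#' total coverage of the sample over usable bins (depth normalization), and
#' then subtracts the median over usable bins so the modal copy state sits
#' at 0.  Masked bins and bins with zero coverage in either sample are
#' flagged invalid and excluded from `N` and the median.
#'
#' @param track A [bin_track()] data frame.
#' @return The track with extra columns `ratio` (log2 units, `NA` where
#'   invalid) and `valid`.
#' @export
compute_log2_ratio <- function(track) {
  stopifnot(is.data.frame(track),
            all(c("cov_test", "cov_control", "mask") %in% names(track)))
  valid <- !track$mask & track$cov_control > 0 & track$cov_test > 0
  if (!any(valid)) {
    stop("all bins invalid: no usable coverage")
  }
  n_test <- sum(track$cov_test[valid])
  n_control <- sum(track$cov_control[valid])
  ratio <- rep(NA_real_, nrow(track))
  ratio[valid] <- log2((track$cov_test[valid] / n_test) /
                       (track$cov_control[valid] / n_control))
  ratio[valid] <- ratio[valid] - stats::median(ratio[valid])
  out <- track
  out$ratio <- ratio
  out$valid <- valid
  out
}

# Internal: robust noise scale from first differences of the ratio track.
# For iid Gaussian noise, sd(diff) = sigma * sqrt(2); the MAD (which
# carries the 1.4826 consistency factor) is robust to the changepoints
# themselves contaminating the differences.
.robust_sigma <- function(x) {
  if (length(x) < 3) {
    return(if (length(x) >= 2) stats::sd(x) else 0)
  }
  s <- stats::mad(diff(x)) / sqrt(2)
  if (!is.finite(s)) 0 else s
}

# Internal: recursive binary segmentation on a numeric vector.  Returns the
# last indices of all left-hand segments (breakpoints), sorted.
.binary_segment <- function(x, sigma, min_seg_bins, penalty, min_delta) {
  recurse <- function(lo, hi) {
    n <- hi - lo + 1
    if (n < 2 * min_seg_bins) {
      return(integer())
    }
    xs <- x[lo:hi]
    cs <- cumsum(xs)
    tot <- cs[n]
    k <- min_seg_bins:(n - min_seg_bins)
    m_left <- cs[k] / k
    m_right <- (tot - cs[k]) / (n - k)
    delta <- abs(m_left - m_right)
    # noise-free tracks (sigma = 0) degenerate to infinite statistics for
    # every positive delta; a tiny floor keeps the ordering so the best
    # split is still the one maximizing the standardized mean shift
    s_eff <- max(sigma, 1e-12)
    tstat <- delta / (s_eff * sqrt(1 / k + 1 / (n - k)))
    best <- which.max(tstat)
    if (tstat[best] > penalty && delta[best] >= min_delta) {
      b <- lo + k[best] - 1
      c(recurse(lo, b), b, recurse(b + 1, hi))
    } else {
      integer()
    }
  }
  sort(recurse(1, length(x)))
}

#' Segment a log2 ratio track into runs of constant CNR
#'
#' Per chromosome, valid bins are segmented by recursive binary
#' segmentation: the candidate breakpoint maximizes the two-sample
#' t-like statistic `|mean_L - mean_R| / (s * sqrt(1/n_L + 1/n_R))` with a
#' robust pooled noise scale `s` estimated from first differences; a split
#' is accepted only if the statistic exceeds `penalty`, both sides have at
#' least `min_seg_bins` bins, and the mean shift is at least `min_delta`
#' log2 units.  Each segment's `log2cnr` is the mean of its member bins.
#' Segment boundaries snap to bin boundaries; gaps from invalid bins are
#' inherited by the preceding (or first) segment.
#'
#' @param track Output of [compute_log2_ratio()].
#' @param min_seg_bins Minimum bins per segment (>= 2); default 5.
#' @param penalty t-statistic threshold for accepting a split; default 5.
#' @param min_delta Minimum mean shift in log2 units; default 0.1.
#' @return A validated segment `data.frame` (see [segment_table()]).
#' @export
segment_log2_ratios <- function(track, min_seg_bins = 5, penalty = 5.0,
                                min_delta = 0.1) {
  stopifnot(all(c("ratio", "valid") %in% names(track)))
  if (min_seg_bins < 2) {
    stop("min_seg_bins must be >= 2")
  }
  out <- list()
  for (ch in unique(track$chrom)) {
    rows <- which(track$chrom == ch)
    vrows <- rows[track$valid[rows]]
    if (length(vrows) == 0) {
      warning("chromosome ", ch, " has no valid bins; skipped")
      next
    }
    x <- track$ratio[vrows]
    if (length(vrows) < min_seg_bins) {
      warning("chromosome ", ch, " has fewer than min_seg_bins valid bins; ",
              "returning a single whole-chromosome segment")
      breaks <- integer()
    } else {
      sigma <- .robust_sigma(x)
      breaks <- .binary_segment(x, sigma, min_seg_bins, penalty, min_delta)
    }
    bounds <- c(0, breaks, length(x))
    seg_first <- bounds[-length(bounds)] + 1
    seg_last <- bounds[-1]
    seg_mean <- vapply(seq_along(seg_first), function(i) {
      mean(x[seg_first[i]:seg_last[i]])
    }, numeric(1))
    # genomic extents: first segment reaches back to the chromosome start,
    # each segment extends forward to the next segment's first valid bin
    # (invalid-bin gaps inherit the preceding segment), the last one to the
    # chromosome end.
    start <- track$start[vrows[seg_first]]
    start[1] <- track$start[rows[1]]
    end <- c(if (length(seg_first) > 1) track$start[vrows[seg_first[-1]]],
             track$end[rows[length(rows)]])
    out[[ch]] <- data.frame(chrom = ch, start = start, end = end,
                            log2cnr = seg_mean, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    stop("no chromosome with valid bins")
  }
  res <- do.call(rbind, out)
  segment_table(res$chrom, res$start, res$end, res$log2cnr)
}

#' Convert a log2 ratio to a clipped linear CNR
#'
#' Returns `2^log2cnr` clipped into `[clip[1], clip[2]]`.  Clipping guards
#' against near-zero ratios (e.g. homozygous deletions) annihilating
#' control counts during scaling.
#'
#' @param log2cnr log2 copy-number ratio(s).
#' @param clip Length-2 positive vector `(lo, hi)`; default `c(1/16, 16)`.
#' @return Linear copy-number ratio(s), clipped.
#' @export
cnr_from_log2 <- function(log2cnr, clip = c(1 / 16, 16)) {
  if (length(clip) != 2 || clip[1] <= 0 || clip[2] < clip[1]) {
    stop("clip must be (lo, hi) with lo > 0 and hi >= lo")
  }
  pmin(pmax(2^log2cnr, clip[1]), clip[2])
}
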