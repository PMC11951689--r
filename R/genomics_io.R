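# Readers and writers for the plain-text formats the pipeline touches.
#
# All coordinates are 0-based half-open (BED convention) throughout the
# package; 1-based sources are converted at the boundary.  Chromosome names
# are matched as exact strings; `strip_chr = TRUE` removes a leading "chr"
# at read time for sources that drop the prefix.  Strand is ignored
# everywhere: the method operates on strand-agnostic fragment counts.

#' Construct and validate a peak table
#'
#' Peaks are plain data frames with columns `chrom`, `start`, `end`
#' (0-based half-open), a unique `name`, and an optional numeric `score`.
#'
#' @param chrom Chromosome names (non-empty strings).
#' @param start 0-based inclusive start positions (bp).
#' @param end Exclusive end positions (bp); must satisfy `start < end`.
#' @param name Unique peak identifiers.
#' @param score Optional enrichment scores (unitless); `NA` when absent.
#' @return A validated `data.frame` of peaks.
#' @export
peak_table <- function(chrom, start, end, name, score = NA_real_) {
  score <- rep_len(as.numeric(score), length(chrom))
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    name = as.character(name),
    score = as.numeric(score),
    stringsAsFactors = FALSE
  )
  validate_peaks(df)
}

#' Validate a peak table
#'
#' Checks the interval invariants (`0 <= start < end`, non-empty `chrom`)
#' and uniqueness of peak names.
#'
#' @param peaks A data frame with columns `chrom`, `start`, `end`, `name`.
#' @return The input, invisibly validated (returned unchanged).
#' @export
validate_peaks <- function(peaks) {
  stopifnot(is.data.frame(peaks))
  req <- c("chrom", "start", "end", "name")
  miss <- setdiff(req, names(peaks))
  if (length(miss)) {
    stop("peak table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(peaks) == 0) {
    return(peaks)
  }
  if (any(is.na(peaks$chrom) | peaks$chrom == "")) {
    stop("chromosome names must be non-empty")
  }
  if (any(!is.finite(peaks$start)) || any(!is.finite(peaks$end))) {
    stop("peak coordinates must be finite")
  }
  if (any(peaks$start < 0)) {
    stop("peak start coordinates must be >= 0")
  }
  if (any(peaks$start >= peaks$end)) {
    bad <- which(peaks$start >= peaks$end)[1]
    stop("peak '", peaks$name[bad], "': start must be < end")
  }
  if (anyDuplicated(peaks$name)) {
    dup <- peaks$name[duplicated(peaks$name)][1]
    stop("peak names must be unique (duplicated: '", dup, "')")
  }
  peaks
}

# Internal: split lines of a tab-separated file, dropping comments/track lines.
.read_tab_lines <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines) & !grepl("^(#|track\\b|browser\\b)", lines)
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE), lineno = which(keep))
}

.is_int_string <- function(x) grepl("^-?[0-9]+$", x)

#' Read peaks from a narrowPeak/BED file
#'
#' Accepts any tab-separated BED-style file with at least three columns
#' (ENCODE narrowPeak included).  Coordinates are taken as 0-based
#' half-open.  A missing name column is filled with synthesized names
#' `peak_<i>`; the 5th column, when present, is kept as `score`.
#'
#' @param path Path to the file.
#' @param strip_chr Remove a leading `"chr"` from chromosome names.
#' @return A peak `data.frame` in file order (see [peak_table()]).
#' @export
read_narrowpeak <- function(path, strip_chr = FALSE) {
  tl <- .read_tab_lines(path)
  if (length(tl$fields) == 0) {
    return(peak_table(character(), numeric(), numeric(), character()))
  }
  n_col <- lengths(tl$fields)
  if (any(n_col < 3)) {
    bad <- which(n_col < 3)[1]
    stop("parse error at line ", tl$lineno[bad],
         ": fewer than 3 tab-separated columns")
  }
  chrom <- vapply(tl$fields, `[`, character(1), 1L)
  start_s <- vapply(tl$fields, `[`, character(1), 2L)
  end_s <- vapply(tl$fields, `[`, character(1), 3L)
  ok <- .is_int_string(start_s) & .is_int_string(end_s)
  if (any(!ok)) {
    bad <- which(!ok)[1]
    stop("parse error at line ", tl$lineno[bad], ": non-integer coordinates")
  }
  start <- as.numeric(start_s)
  end <- as.numeric(end_s)
  if (any(start >= end)) {
    bad <- which(start >= end)[1]
    stop("parse error at line ", tl$lineno[bad], ": start >= end")
  }
  name <- ifelse(n_col >= 4,
                 vapply(tl$fields, function(f) if (length(f) >= 4) f[4] else "",
                        character(1)),
                 paste0("peak_", seq_along(chrom)))
  name[name == "" | name == "."] <- paste0("peak_", which(name == "" | name == "."))
  score <- vapply(tl$fields, function(f) {
    if (length(f) >= 5) suppressWarnings(as.numeric(f[5])) else NA_real_
  }, numeric(1))
  if (strip_chr) chrom <- sub("^chr", "", chrom)
  peak_table(chrom, start, end, name, score)
}

#' Write peaks as BED
#'
#' Writes `chrom`, `start`, `end`, `name`, `score` tab-separated with no
#' header (missing scores become `.`); the inverse of [read_narrowpeak()].
#'
#' @param peaks A peak `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  peaks <- validate_peaks(peaks)
  score <- if ("score" %in% names(peaks)) peaks$score else NA_real_
  out <- data.frame(peaks$chrom, format(peaks$start, scientific = FALSE, trim = TRUE),
                    format(peaks$end, scientific = FALSE, trim = TRUE),
                    peaks$name, ifelse(is.na(score), ".", as.character(score)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct and validate a segment table
#'
#' Segments are genomic intervals carrying the copy-number ratio (CNR) of
#' the test sample over the control sample: `cnr = 2^log2cnr`.  Segments on
#' one chromosome must be non-overlapping; they are sorted by position.
#'
#' @param chrom,start,end Interval coordinates (0-based half-open).
#' @param log2cnr log2 copy-number ratio test/control.
#' @return A validated, sorted segment `data.frame` with columns `chrom`,
#'   `start`, `end`, `log2cnr`, `cnr`.
#' @export
segment_table <- function(chrom, start, end, log2cnr) {
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    log2cnr = as.numeric(log2cnr),
    cnr = 2^as.numeric(log2cnr),
    stringsAsFactors = FALSE
  )
  validate_segments(df)
}

#' Validate a segment table
#'
#' Checks interval invariants, `cnr = 2^log2cnr` within `1e-9`, `cnr > 0`,
#' and per-chromosome non-overlap; returns the table sorted by chromosome
#' and start.
#'
#' @param segments A segment `data.frame`.
#' @return The sorted, validated segment table.
#' @export
validate_segments <- function(segments) {
  stopifnot(is.data.frame(segments))
  req <- c("chrom", "start", "end", "log2cnr", "cnr")
  miss <- setdiff(req, names(segments))
  if (length(miss)) {
    stop("segment table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(segments) == 0) {
    return(segments)
  }
  if (any(!is.finite(segments$log2cnr))) {
    stop("segment log2cnr must be finite")
  }
  if (any(segments$cnr <= 0)) {
    stop("segment cnr must be > 0")
  }
  if (any(abs(segments$cnr - 2^segments$log2cnr) > 1e-9)) {
    stop("segment cnr must equal 2^log2cnr within 1e-9")
  }
  if (any(segments$start < 0) || any(segments$start >= segments$end)) {
    stop("segment intervals must satisfy 0 <= start < end")
  }
  segments <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)])) {
      stop("overlapping segments on chromosome ", ch)
    }
  }
  segments
}

#' Read copy-number segments
#'
#' Two dialects are supported: `"cns"` (tab-separated with a header line
#' containing at least `chromosome`, `start`, `end`, `log2`; extra columns
#' such as `gene` are ignored) and `"bed_log2"` (headerless BED3 plus a 4th
#' column with the log2 ratio).  The linear-scale `cnr` is computed as
#' `2^log2`.
#'
#' @param path Path to the segment file.
#' @param dialect `"cns"` or `"bed_log2"`.
#' @param strip_chr Remove a leading `"chr"` from chromosome names.
#' @return A validated segment `data.frame` (see [segment_table()]).
#' @export
read_segments <- function(path, dialect = c("cns", "bed_log2"),
                          strip_chr = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  if (dialect == "cns") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE,
                            colClasses = "character")
    req <- c("chromosome", "start", "end", "log2")
    miss <- setdiff(req, names(df))
    if (length(miss)) {
      stop("cns file lacks column(s): ", paste(miss, collapse = ", "))
    }
    chrom <- df$chromosome
    start <- df$start
    end <- df$end
    log2v <- df$log2
  } else {
    tl <- .read_tab_lines(path)
    if (length(tl$fields) == 0) {
      return(segment_table(character(), numeric(), numeric(), numeric()))
    }
    if (any(lengths(tl$fields) < 4)) {
      bad <- which(lengths(tl$fields) < 4)[1]
      stop("parse error at line ", tl$lineno[bad],
           ": bed_log2 requires 4 columns")
    }
    chrom <- vapply(tl$fields, `[`, character(1), 1L)
    start <- vapply(tl$fields, `[`, character(1), 2L)
    end <- vapply(tl$fields, `[`, character(1), 3L)
    log2v <- vapply(tl$fields, `[`, character(1), 4L)
  }
  log2n <- suppressWarnings(as.numeric(log2v))
  if (any(is.na(log2n))) {
    stop("parse error: non-numeric log2 value '", log2v[which(is.na(log2n))[1]], "'")
  }
  startn <- suppressWarnings(as.numeric(start))
  endn <- suppressWarnings(as.numeric(end))
  if (any(is.na(startn)) || any(is.na(endn))) {
    stop("parse error: non-numeric segment coordinates")
  }
  if (strip_chr) chrom <- sub("^chr", "", chrom)
  segment_table(chrom, startn, endn, log2n)
}

#' Write copy-number segments
#'
#' Inverse of [read_segments()].  The `"cns"` dialect writes a header
#' `chromosome start end gene log2` (gene filled with `-`).
#'
#' @param segments A validated segment `data.frame`.
#' @param path Output path.
#' @param dialect `"cns"` or `"bed_log2"`.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path, dialect = c("cns", "bed_log2")) {
  dialect <- match.arg(dialect)
  segments <- validate_segments(segments)
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  if (dialect == "cns") {
    out <- data.frame(chromosome = segments$chrom, start = fmt(segments$start),
                      end = fmt(segments$end), gene = "-",
                      log2 = format(segments$log2cnr, digits = 17))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    out <- data.frame(segments$chrom, fmt(segments$start), fmt(segments$end),
                      format(segments$log2cnr, digits = 17))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Construct a count matrix object
#'
#' The container for per-peak per-sample fragment counts.  Counts may be
#' fractional (copy-number-scaled matrices are), but never negative.  Each
#' sample carries a condition label, `"test"` or `"control"`, and both
#' conditions must be represented.
#'
#' @param counts Numeric matrix, peaks x samples, with row and column names.
#' @param condition Named character vector (or factor) mapping each sample
#'   to `"test"` or `"control"`.
#' @param peaks Optional peak `data.frame` matching the rows.
#' @return An object of class `cn_count_matrix`.
#' @export
count_matrix <- function(counts, condition, peaks = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    stop("count matrix must have row names (peak names)")
  }
  if (is.null(colnames(counts))) {
    stop("count matrix must have column names (sample names)")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate peak names in count matrix")
  }
  if (!is.numeric(counts) || any(!is.finite(counts))) {
    stop("counts must be finite numbers")
  }
  if (any(counts < 0)) {
    stop("counts must be non-negative")
  }
  cond_names <- names(condition)
  condition <- stats::setNames(as.character(condition), cond_names)
  if (is.null(names(condition))) {
    if (length(condition) != ncol(counts)) {
      stop("condition must map every sample")
    }
    names(condition) <- colnames(counts)
  }
  miss <- setdiff(colnames(counts), names(condition))
  if (length(miss)) {
    stop("no condition given for sample(s): ", paste(miss, collapse = ", "))
  }
  condition <- condition[colnames(counts)]
  if (!all(condition %in% c("test", "control"))) {
    stop("condition labels must be 'test' or 'control'")
  }
  if (!all(c("test", "control") %in% condition)) {
    stop("both conditions must have at least one sample")
  }
  if (!is.null(peaks)) {
    peaks <- validate_peaks(peaks)
    if (!identical(sort(peaks$name), sort(rownames(counts)))) {
      stop("peak table does not match count matrix rows")
    }
    peaks <- peaks[match(rownames(counts), peaks$name), , drop = FALSE]
    rownames(peaks) <- NULL
  }
  structure(list(counts = counts, condition = condition, peaks = peaks),
            class = "cn_count_matrix")
}

#' @export
print.cn_count_matrix <- function(x, ...) {
  cat("cn_count_matrix: ", nrow(x$counts), " peaks x ", ncol(x$counts),
      " samples (", sum(x$condition == "test"), " test, ",
      sum(x$condition == "control"), " control)\n", sep = "")
  invisible(x)
}

#' @export
dim.cn_count_matrix <- function(x) dim(x$counts)

#' Read a count matrix from TSV
#'
#' The file must have a header row of sample names and peak names in the
#' first column.  Fractional values are accepted (scaled matrices are
#' fractional); negative values and duplicated peak names are errors.
#'
#' @param path Path to the tab-separated matrix.
#' @param condition_map Named character vector sample -> condition
#'   (`"test"`/`"control"`); every sample in the file must be present.
#' @return A [count_matrix()] object.
#' @export
read_count_matrix <- function(path, condition_map) {
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) {
    stop("count matrix needs a peak-name column plus >= 1 sample column")
  }
  peak_names <- as.character(df[[1]])
  if (anyDuplicated(peak_names)) {
    stop("duplicate peak names in count matrix: '",
         peak_names[duplicated(peak_names)][1], "'")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    stop("non-numeric counts in matrix")
  }
  rownames(m) <- peak_names
  count_matrix(m, condition_map[colnames(m)])
}

#' Write a count matrix as TSV
#'
#' Inverse of [read_count_matrix()]; the first column is named `peak`.
#'
#' @param mat A `cn_count_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "cn_count_matrix"))
  out <- data.frame(peak = rownames(mat$counts), mat$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample -> condition table
#'
#' Expects a tab-separated file with header columns `sample` and
#' `condition`.
#'
#' @param path Path to the table.
#' @return Named character vector mapping samples to conditions.
#' @export
read_conditions <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% names(df))) {
    stop("conditions file needs columns 'sample' and 'condition'")
  }
  stats::setNames(as.character(df$condition), as.character(df$sample))
}

#' Construct a binned coverage track
#'
#' Fixed-width, non-overlapping bins (the last bin of a chromosome may be
#' shorter) with per-bin coverage for the test and control samples and a
#' per-bin exclusion mask.
#'
#' @param bins Data frame with `chrom`, `start`, `end` (and optionally
#'   `mask`).
#' @param cov_test,cov_control Non-negative per-bin coverage.
#' @param mask Logical exclusion mask (overrides a `mask` column in `bins`).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `cov_test`,
#'   `cov_control`, `mask`.
#' @export
bin_track <- function(bins, cov_test, cov_control, mask = NULL) {
  stopifnot(is.data.frame(bins), all(c("chrom", "start", "end") %in% names(bins)))
  n <- nrow(bins)
  if (is.null(mask)) {
    mask <- if ("mask" %in% names(bins)) as.logical(bins$mask) else rep(FALSE, n)
  }
  if (length(cov_test) != n || length(cov_control) != n || length(mask) != n) {
    stop("bin track columns must have equal lengths")
  }
  if (any(cov_test < 0) || any(cov_control < 0)) {
    stop("coverage must be non-negative")
  }
  data.frame(chrom = as.character(bins$chrom), start = bins$start,
             end = bins$end, cov_test = as.numeric(cov_test),
             cov_control = as.numeric(cov_control), mask = as.logical(mask),
             stringsAsFactors = FALSE)
}

#' Read a binned coverage track from TSV
#'
#' Expects a header with columns `chrom`, `start`, `end`, `cov_test`,
#' `cov_control` and optionally `mask`.
#'
#' @param path Path to the table.
#' @return A [bin_track()] data frame.
#' @export
read_bin_track <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  req <- c("chrom", "start", "end", "cov_test", "cov_control")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("bin track file lacks column(s): ", paste(miss, collapse = ", "))
  }
  bin_track(df, df$cov_test, df$cov_control,
            if ("mask" %in% names(df)) as.logical(df$mask) else NULL)
}

#' Write a binned coverage track as TSV
#'
#' @param track A [bin_track()] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bin_track <- function(track, path) {
  utils::write.table(track, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file
#'
#' Headerless 4-column tab-separated `chrom start end value`; `track` and
#' comment lines are skipped.
#'
#' @param path Path to the bedGraph file.
#' @param strip_chr Remove a leading `"chr"` from chromosome names.
#' @return A `data.frame` with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path, strip_chr = FALSE) {
  tl <- .read_tab_lines(path)
  if (length(tl$fields) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric()))
  }
  if (any(lengths(tl$fields) < 4)) {
    bad <- which(lengths(tl$fields) < 4)[1]
    stop("parse error at line ", tl$lineno[bad], ": bedGraph requires 4 columns")
  }
  chrom <- vapply(tl$fields, `[`, character(1), 1L)
  start <- as.numeric(vapply(tl$fields, `[`, character(1), 2L))
  end <- as.numeric(vapply(tl$fields, `[`, character(1), 3L))
  value <- as.numeric(vapply(tl$fields, `[`, character(1), 4L))
  if (any(is.na(start)) || any(is.na(end)) || any(is.na(value))) {
    stop("parse error: non-numeric bedGraph fields")
  }
  if (strip_chr) chrom <- sub("^chr", "", chrom)
  data.frame(chrom = chrom, start = start, end = end, value = value,
             stringsAsFactors = FALSE)
}

#' Combine two bedGraph files into a bin track
#'
#' The two files must describe identical binnings (same chromosomes and
#' intervals in the same order).
#'
#' @param test_path bedGraph of the test sample.
#' @param control_path bedGraph of the control sample.
#' @param strip_chr Remove a leading `"chr"` from chromosome names.
#' @return A [bin_track()] data frame (unmasked).
#' @export
bin_track_from_bedgraphs <- function(test_path, control_path,
                                     strip_chr = FALSE) {
  a <- read_bedgraph(test_path, strip_chr)
  b <- read_bedgraph(control_path, strip_chr)
  if (!identical(a[c("chrom", "start", "end")], b[c("chrom", "start", "end")])) {
    stop("bedGraph files are not on the same binning")
  }
  bin_track(a[c("chrom", "start", "end")], a$value, b$value)
}

# Internal: 0-based half-open data frame -> GRanges (1-based closed).
.df_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end)
  )
}
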