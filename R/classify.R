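# Dosage / compensation classification: combine differential statuses
# obtained without copy-number normalization ("total" signal, all copies
# summed) and with it ("per-copy" signal, rescaled to a common copy
# number) into five biological categories, e.g. for a trisomic
# chromosome.  The four status combinations outside the five categories
# are reported as "other" rather than coerced.

#' Dosage category levels
#'
#' The five categories plus `other`:
#' * `I_no_change` — neither total nor per-copy signal changes;
#' * `II_overcompensatory` — total and per-copy signal both decrease
#'   (over-compensation plus CN-independent decrease);
#' * `III_compensatory` — total signal unchanged but per-copy signal
#'   decreases (dosage compensation);
#' * `IV_dosage_only` — total signal increases with no per-copy change
#'   (pure dosage effect);
#' * `V_dosage_plus_increase` — total and per-copy signal both increase;
#' * `other` — the remaining status combinations, reported explicitly.
#' @export
dosage_categories <- c("I_no_change", "II_overcompensatory",
                       "III_compensatory", "IV_dosage_only",
                       "V_dosage_plus_increase", "other")

#' Classify a region from its total and per-copy status
#'
#' Maps the pair (status without CN normalization, status with CN
#' normalization) to a dosage category: `(nd, nd) -> I`,
#' `(down, down) -> II`, `(nd, down) -> III`, `(up, nd) -> IV`,
#' `(up, up) -> V`; the four remaining combinations map to `other` with a
#' warning.
#'
#' @param total_status Status from the run without CN normalization
#'   (`up`/`down`/`nd`); vectorized.
#' @param percopy_status Status from the run with CN normalization, same
#'   length.
#' @return Factor with levels [dosage_categories].
#' @export
classify_region <- function(total_status, percopy_status) {
  total_status <- as.character(total_status)
  percopy_status <- as.character(percopy_status)
  if (length(total_status) != length(percopy_status)) {
    stop("status vectors must have equal length")
  }
  ok <- c("up", "down", "nd")
  bad <- setdiff(unique(c(total_status, percopy_status)), ok)
  if (length(bad)) {
    stop("unknown status token: '", bad[1], "'")
  }
  key <- paste(total_status, percopy_status)
  map <- c("nd nd" = "I_no_change",
           "down down" = "II_overcompensatory",
           "nd down" = "III_compensatory",
           "up nd" = "IV_dosage_only",
           "up up" = "V_dosage_plus_increase")
  cat_chr <- unname(map[key])
  cat_chr[is.na(cat_chr)] <- "other"
  n_other <- sum(cat_chr == "other")
  if (n_other > 0) {
    warning(n_other, " region(s) with status combinations outside the five ",
            "categories; reported as 'other'")
  }
  factor(cat_chr, levels = dosage_categories)
}

# Internal: parse "chr21" or "chr21:1000-5000" (0-based half-open) into a
# predicate over a peak table.
.region_predicate <- function(region, peaks) {
  m <- regmatches(region, regexec("^([^:]+)(:([0-9]+)-([0-9]+))?$", region))[[1]]
  if (length(m) == 0 || m[2] == "") {
    stop("cannot parse region '", region, "'")
  }
  sel <- peaks$chrom == m[2]
  if (m[3] != "") {
    lo <- as.numeric(m[4])
    hi <- as.numeric(m[5])
    sel <- sel & peaks$start < hi & peaks$end > lo
  }
  sel
}

#' Classify all peaks from paired differential runs
#'
#' Joins the results of the without-normalization (total) and
#' with-normalization (per-copy) runs on peak name, applies
#' [classify_region()], optionally restricts to a genomic region, and
#' tabulates category counts and proportions.
#'
#' @param results_total [wald_test()] output from the raw count matrix.
#' @param results_percopy [wald_test()] output from the CN-normalized
#'   matrix; must cover the identical peak set.
#' @param peaks Optional peak `data.frame`; required when `region` is
#'   given.
#' @param region Optional region string, `"chr21"` or
#'   `"chr21:START-END"` (0-based half-open); peaks overlapping it are
#'   kept.
#' @return A list of class `cn_classification` with `table` (per-peak
#'   `peak`, `total_status`, `percopy_status`, `category`), `counts` and
#'   `proportions` (both over [dosage_categories]).
#' @export
classify_all <- function(results_total, results_percopy, peaks = NULL,
                         region = NULL) {
  if (!setequal(results_total$peak, results_percopy$peak)) {
    only_t <- setdiff(results_total$peak, results_percopy$peak)
    only_p <- setdiff(results_percopy$peak, results_total$peak)
    stop("peak sets differ between runs; only in total: ",
         paste(utils::head(only_t, 5), collapse = ", "),
         "; only in per-copy: ", paste(utils::head(only_p, 5), collapse = ", "))
  }
  idx <- match(results_total$peak, results_percopy$peak)
  d <- data.frame(peak = results_total$peak,
                  total_status = results_total$status,
                  percopy_status = results_percopy$status[idx],
                  stringsAsFactors = FALSE)
  if (!is.null(region)) {
    if (is.null(peaks)) {
      stop("region filtering requires the peak table")
    }
    peaks <- validate_peaks(peaks)
    keep_names <- peaks$name[.region_predicate(region, peaks)]
    d <- d[d$peak %in% keep_names, , drop = FALSE]
  }
  if (nrow(d) == 0) {
    stop("no peaks left after region filtering")
  }
  d$category <- classify_region(d$total_status, d$percopy_status)
  counts <- table(d$category)
  structure(list(table = d, counts = counts,
                 proportions = as.numeric(counts) / nrow(d)),
            class = "cn_classification")
}

#' @export
print.cn_classification <- function(x, ...) {
  cat("cn_classification: ", nrow(x$table), " peaks\n", sep = "")
  out <- data.frame(category = names(x$counts), n = as.integer(x$counts),
                    pct = round(100 * x$proportions, 2))
  print(out, row.names = FALSE)
  invisible(x)
}
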