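# Synthetic experiments with known copy-number structure so that every
# pipeline stage can be checked against ground truth.  The generative
# model mirrors the assumptions of copy-number-driven bias in chromatin
# assays: the observed count in a peak is the copy-number-scaled sum of a
# per-copy accessibility signal and background fragments, and background
# inside peaks scales with copy number too (background reads are
# DNA-derived), which is exactly what makes low signal-to-noise data more
# biased by copy-number differences.

#' Simulation configuration
#'
#' Defaults describe a desk-scale experiment: two 10 Mb chromosomes, 50 kb
#' coverage bins, 2,000 peaks of 500 bp, three replicates per condition,
#' and copy-number structure with a copy-neutral majority (60% of every
#' euploid chromosome, alternating neutral/altered blocks) so the
#' median-centring assumption of the CNR module holds, as in real genomes
#' where most of the genome is copy-neutral.
#'
#' Peak counts for sample `j`, peak `i` in a block with test copy number
#' `c` are NB-distributed with mean
#' `L_j * (frip * lambda_i * delta_i(cond) + (1 - frip) * beta * w) * c(cond)/2`
#' where `lambda_i` are log-normal per-copy rates scaled so the mean peak
#' count is about `depth`, `delta_i` is the per-copy effect (2^effect for
#' true-differential peaks in the test condition, times any trisomy
#' compensation multiplier), `beta = depth / peak_width` the background
#' rate per bp, and `L_j` log-normal library scales.  Control samples have
#' copy number 2 everywhere.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Chromosome length (bp).
#' @param bin_size Coverage bin width (bp); default 50 kb.
#' @param segments_per_chrom Copy-number blocks per euploid chromosome.
#' @param copy_states Allowed test copy numbers (control fixed at 2);
#'   subset of 0:4.
#' @param neutral_frac Fraction of each euploid chromosome kept
#'   copy-neutral; default 0.6.
#' @param n_peaks Number of peaks genome-wide.
#' @param peak_width Peak width (bp).
#' @param n_reps Replicates per condition.
#' @param depth Expected fragments per peak per copy-pair.
#' @param dispersion NB dispersion of peak counts.
#' @param frip Fraction of in-peak fragments that are signal
#'   (signal-to-noise control, in (0, 1]).
#' @param frac_true_diff Fraction of peaks with a true per-copy effect.
#' @param effect_log2fc Per-copy effect size (log2) of true-differential
#'   peaks; the sign is randomized per peak.
#' @param bin_depth Expected coverage fragments per 50 kb bin at copy 2.
#' @param lambda_sdlog sdlog of the log-normal per-copy rates.
#' @param lib_sdlog sdlog of the log-normal library scales.
#' @param seed Integer seed; all randomness derives from it.
#' @param trisomy `NULL`, or a list as built by [make_trisomy_config()].
#' @return A list of class `cn_sim_config`.
#' @export
simulation_config <- function(n_chrom = 2, chrom_length = 1e7,
                              bin_size = 5e4, segments_per_chrom = 4,
                              copy_states = c(1, 2, 3, 4),
                              neutral_frac = 0.6, n_peaks = 2000,
                              peak_width = 500, n_reps = 3, depth = 100,
                              dispersion = 0.01, frip = 0.4,
                              frac_true_diff = 0, effect_log2fc = 1,
                              bin_depth = 200, lambda_sdlog = 1.5,
                              lib_sdlog = 0.15, seed = 1, trisomy = NULL) {
  cfg <- list(n_chrom = n_chrom, chrom_length = chrom_length,
              bin_size = bin_size, segments_per_chrom = segments_per_chrom,
              copy_states = copy_states, neutral_frac = neutral_frac,
              n_peaks = n_peaks, peak_width = peak_width, n_reps = n_reps,
              depth = depth, dispersion = dispersion, frip = frip,
              frac_true_diff = frac_true_diff,
              effect_log2fc = effect_log2fc, bin_depth = bin_depth,
              lambda_sdlog = lambda_sdlog, lib_sdlog = lib_sdlog,
              seed = as.integer(seed), trisomy = trisomy)
  if (cfg$n_peaks < 1 || cfg$n_reps < 1) {
    stop("infeasible config: need >= 1 peak and >= 1 replicate")
  }
  if (cfg$frip <= 0 || cfg$frip > 1) {
    stop("frip must lie in (0, 1]")
  }
  if (!all(cfg$copy_states %in% 0:4)) {
    stop("copy_states must be a subset of 0:4")
  }
  if (cfg$frac_true_diff < 0 || cfg$frac_true_diff > 1) {
    stop("frac_true_diff must lie in [0, 1]")
  }
  if (cfg$chrom_length < cfg$bin_size) {
    stop("chromosomes must span at least one bin")
  }
  if (cfg$n_chrom < 1 || cfg$segments_per_chrom < 1) {
    stop("need >= 1 chromosome and >= 1 segment per chromosome")
  }
  structure(cfg, class = "cn_sim_config")
}

#' Trisomy study configuration
#'
#' Fixes one designated chromosome at test copy number 3 (uniform
#' CNR = 3/2, the trisomy-21 construction) with all other chromosomes
#' euploid, and plants per-copy compensation classes among the peaks of
#' that chromosome: pure dosage (per-copy rate unchanged), compensatory
#' (per-copy rate times 2/3 so the expected total matches the control),
#' over-compensatory (times 1/3) and CN-independent extra increase
#' (times 2), with recorded truth.
#'
#' @param base A [simulation_config()].
#' @param chrom Designated trisomic chromosome name; default `"chr1"`.
#' @param fractions Named fractions summing to 1 over
#'   `dosage`, `compensatory`, `overcompensatory`, `increase`;
#'   default 0.80/0.10/0.05/0.05.
#' @return The config with the trisomy design attached.
#' @export
make_trisomy_config <- function(base, chrom = "chr1",
                                fractions = c(dosage = 0.8,
                                              compensatory = 0.1,
                                              overcompensatory = 0.05,
                                              increase = 0.05)) {
  stopifnot(inherits(base, "cn_sim_config"))
  req <- c("dosage", "compensatory", "overcompensatory", "increase")
  if (!setequal(names(fractions), req)) {
    stop("fractions must be named: ", paste(req, collapse = ", "))
  }
  if (abs(sum(fractions) - 1) > 1e-9 || any(fractions < 0)) {
    stop("fractions must be non-negative and sum to 1")
  }
  base$trisomy <- list(chrom = chrom, fractions = fractions[req],
                       multipliers = c(dosage = 1, compensatory = 2 / 3,
                                       overcompensatory = 1 / 3,
                                       increase = 2))
  base
}

# Internal: copy-number block layout for one chromosome.  Euploid
# chromosomes alternate neutral and altered blocks starting neutral, with
# the neutral blocks sharing `neutral_frac` of the length; boundaries snap
# to bin_size.  The trisomic chromosome is a single copy-3 block.
.sim_blocks <- function(cfg, chrom_name) {
  L <- cfg$chrom_length
  if (!is.null(cfg$trisomy)) {
    # trisomy design: the designated chromosome is uniformly three-copy
    # (CNR = 3/2), every other chromosome is euploid
    copy <- if (chrom_name == cfg$trisomy$chrom) 3 else 2
    return(data.frame(start = 0, end = L, copy = copy))
  }
  nb <- cfg$segments_per_chrom
  if (nb == 1) {
    return(data.frame(start = 0, end = L, copy = 2))
  }
  n_neut <- ceiling(nb / 2)
  n_alt <- floor(nb / 2)
  len_neut <- cfg$neutral_frac * L / n_neut
  len_alt <- (1 - cfg$neutral_frac) * L / n_alt
  lens <- ifelse(seq_len(nb) %% 2 == 1, len_neut, len_alt)
  bounds <- round(cumsum(lens) / cfg$bin_size) * cfg$bin_size
  bounds[nb] <- L
  start <- c(0, bounds[-nb])
  # Altered blocks alternate loss/gain states so that, as in real
  # aneuploid genomes where gains and losses roughly balance, the
  # median-of-ratios centring of downstream normalization is not dragged
  # to one side by the simulated copy-number structure.
  losses <- cfg$copy_states[cfg$copy_states < 2]
  gains <- cfg$copy_states[cfg$copy_states > 2]
  alt_states <- setdiff(cfg$copy_states, 2)
  copy <- rep(2, nb)
  if (length(alt_states) > 0 && n_alt > 0) {
    alt_idx <- which(seq_len(nb) %% 2 == 0)
    if (length(losses) > 0 && length(gains) > 0) {
      pick_loss <- (seq_len(n_alt) %% 2 == 1)
      copy[alt_idx[pick_loss]] <- sample(losses, sum(pick_loss),
                                         replace = TRUE)
      copy[alt_idx[!pick_loss]] <- sample(gains, sum(!pick_loss),
                                          replace = TRUE)
    } else {
      copy[alt_idx] <- sample(alt_states, n_alt, replace = TRUE)
    }
  }
  data.frame(start = start, end = bounds, copy = copy)
}

#' Simulate a copy-number-structured chromatin experiment
#'
#' Deterministic given the config seed (sub-streams use fixed seed
#' offsets, so e.g. regenerating counts does not perturb the structure
#' draws).  See [simulation_config()] for the generative model.
#'
#' @param config A [simulation_config()].
#' @return A list of class `cn_simulation`: `peaks` (peak table), `counts`
#'   (a [count_matrix()]), `bins` (a [bin_track()] of simulated coverage),
#'   `truth` (generating values: `segments` with true copy numbers and
#'   log2 CNR, per-peak `peaks` truth with per-copy rates, effects and any
#'   trisomy class, and `lib_scales`) and `config`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "cn_sim_config"))
  cfg <- config
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  chrom_sizes <- stats::setNames(rep(cfg$chrom_length, cfg$n_chrom), chroms)

  # -- copy-number structure -------------------------------------------------
  set.seed(cfg$seed + 1L)
  seg_list <- lapply(chroms, function(ch) {
    b <- .sim_blocks(cfg, ch)
    data.frame(chrom = ch, start = b$start, end = b$end, copy = b$copy,
               stringsAsFactors = FALSE)
  })
  segs <- do.call(rbind, seg_list)
  # copy 0 would give cnr = 0; represent it at the clipping floor
  segs$cnr <- pmax(segs$copy / 2, 1 / 16)
  segs$log2cnr <- log2(segs$cnr)

  # -- peak placement: one peak per genome slot, random offset ---------------
  set.seed(cfg$seed + 2L)
  genome_len <- sum(chrom_sizes)
  slot <- floor(genome_len / cfg$n_peaks)
  if (slot <= cfg$peak_width) {
    stop("infeasible config: peaks would overlap (reduce n_peaks or width)")
  }
  offset <- floor(stats::runif(cfg$n_peaks, 0, slot - cfg$peak_width))
  gstart <- (seq_len(cfg$n_peaks) - 1) * slot + offset
  chrom_of <- findInterval(gstart, cumsum(chrom_sizes), left.open = FALSE) + 1
  chrom_origin <- c(0, cumsum(chrom_sizes))[chrom_of]
  pstart <- gstart - chrom_origin
  pstart <- pmin(pstart, cfg$chrom_length - cfg$peak_width)
  peaks <- peak_table(chroms[chrom_of], pstart, pstart + cfg$peak_width,
                      sprintf("peak_%05d", seq_len(cfg$n_peaks)))

  # peak -> true segment by midpoint
  mid <- (peaks$start + peaks$end) / 2
  seg_of <- vapply(seq_len(cfg$n_peaks), function(i) {
    rows <- which(segs$chrom == peaks$chrom[i])
    rows[findInterval(mid[i], segs$start[rows], left.open = FALSE)]
  }, integer(1))

  # -- per-copy rates and effects --------------------------------------------
  set.seed(cfg$seed + 3L)
  lambda <- stats::rlnorm(cfg$n_peaks,
                          meanlog = log(cfg$depth) - cfg$lambda_sdlog^2 / 2,
                          sdlog = cfg$lambda_sdlog)

  set.seed(cfg$seed + 4L)
  true_diff <- stats::runif(cfg$n_peaks) < cfg$frac_true_diff
  sign_up <- stats::runif(cfg$n_peaks) < 0.5
  delta <- ifelse(true_diff, 2^(ifelse(sign_up, 1, -1) * cfg$effect_log2fc), 1)
  tri_class <- rep(NA_character_, cfg$n_peaks)
  if (!is.null(cfg$trisomy)) {
    on_tri <- peaks$chrom == cfg$trisomy$chrom
    if (any(on_tri)) {
      cls <- sample(names(cfg$trisomy$fractions), sum(on_tri), replace = TRUE,
                    prob = cfg$trisomy$fractions)
      tri_class[on_tri] <- cls
      delta[on_tri] <- delta[on_tri] * cfg$trisomy$multipliers[cls]
    }
  }

  # -- library scales and counts ---------------------------------------------
  set.seed(cfg$seed + 5L)
  samples <- c(paste0("test_", seq_len(cfg$n_reps)),
               paste0("control_", seq_len(cfg$n_reps)))
  condition <- stats::setNames(rep(c("test", "control"), each = cfg$n_reps),
                               samples)
  lib <- stats::setNames(
    stats::rlnorm(length(samples), -cfg$lib_sdlog^2 / 2, cfg$lib_sdlog),
    samples)

  set.seed(cfg$seed + 6L)
  beta_bg <- cfg$depth / cfg$peak_width
  copy_test <- segs$copy[seg_of]
  K <- matrix(0, cfg$n_peaks, length(samples),
              dimnames = list(peaks$name, samples))
  for (j in seq_along(samples)) {
    is_test <- condition[j] == "test"
    c_half <- if (is_test) copy_test / 2 else 1
    d_j <- if (is_test) delta else 1
    mu <- lib[j] * (cfg$frip * lambda * d_j +
                    (1 - cfg$frip) * beta_bg * cfg$peak_width) * c_half
    K[, j] <- if (cfg$dispersion > 1e-12) {
      stats::rnbinom(cfg$n_peaks, mu = mu, size = 1 / cfg$dispersion)
    } else {
      stats::rpois(cfg$n_peaks, mu)
    }
  }

  # -- bin coverage (for the CNR module) -------------------------------------
  set.seed(cfg$seed + 7L)
  bins <- bin_genome(chrom_sizes, cfg$bin_size)
  bmid <- (bins$start + bins$end) / 2
  bin_copy <- vapply(seq_len(nrow(bins)), function(i) {
    rows <- which(segs$chrom == bins$chrom[i])
    segs$copy[rows[findInterval(bmid[i], segs$start[rows])]]
  }, numeric(1))
  wfrac <- (bins$end - bins$start) / cfg$bin_size
  cov_test <- stats::rpois(nrow(bins), cfg$bin_depth * wfrac * bin_copy / 2)
  cov_control <- stats::rpois(nrow(bins), cfg$bin_depth * wfrac)
  bins_trk <- bin_track(bins, cov_test, cov_control)

  truth <- list(
    segments = segs,
    peaks = data.frame(name = peaks$name, chrom = peaks$chrom,
                       segment_index = seg_of, copy = copy_test,
                       log2cnr = segs$log2cnr[seg_of], lambda = lambda,
                       true_diff = true_diff,
                       true_percopy_log2fc = log2(delta),
                       trisomy_class = tri_class,
                       stringsAsFactors = FALSE),
    lib_scales = lib
  )
  structure(list(peaks = peaks,
                 counts = count_matrix(K, condition, peaks),
                 bins = bins_trk, truth = truth, config = cfg),
            class = "cn_simulation")
}

#' @export
print.cn_simulation <- function(x, ...) {
  cat("cn_simulation: ", nrow(x$peaks), " peaks on ", x$config$n_chrom,
      " chromosome(s), ", x$config$n_reps, " reps/condition, seed ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}

#' True segments of a simulation as a segment table
#'
#' Converts the generating copy-number blocks into the standard segment
#' representation consumed by [assign_peaks()].
#'
#' @param sim A [simulate_experiment()] result.
#' @return A validated segment `data.frame`.
#' @export
true_segments <- function(sim) {
  stopifnot(inherits(sim, "cn_simulation"))
  s <- sim$truth$segments
  segment_table(s$chrom, s$start, s$end, s$log2cnr)
}
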