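# Shared fixtures, all built in code.

# random peak table with n peaks on a couple of chromosomes
random_peaks <- function(n, seed = 1) {
  set.seed(seed)
  chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
  start <- sort(sample(0:1e6, n))
  peak_table(chrom, start, start + sample(100:1000, n, replace = TRUE),
             sprintf("rp_%04d", seq_len(n)),
             score = round(runif(n, 0, 1000), 2))
}

# a log2-ratio track from a plain numeric vector (one bin per value)
ratio_track <- function(x, chrom = "chr1", bin_size = 50000,
                        valid = is.finite(x)) {
  n <- length(x)
  data.frame(chrom = chrom, start = (0:(n - 1)) * bin_size,
             end = (1:n) * bin_size, cov_test = 1, cov_control = 1,
             mask = FALSE, ratio = x, valid = valid,
             stringsAsFactors = FALSE)
}

# NB count matrix with given group means, one condition block each
nb_matrix <- function(mu_test, mu_control, n_reps, dispersion, seed,
                      n_peaks = length(mu_test)) {
  set.seed(seed)
  mu_test <- rep_len(mu_test, n_peaks)
  mu_control <- rep_len(mu_control, n_peaks)
  draw <- function(mu) {
    if (dispersion > 1e-12) {
      rnbinom(n_peaks, mu = mu, size = 1 / dispersion)
    } else {
      rpois(n_peaks, mu)
    }
  }
  K <- cbind(sapply(seq_len(n_reps), function(j) draw(mu_test)),
             sapply(seq_len(n_reps), function(j) draw(mu_control)))
  colnames(K) <- c(paste0("t", seq_len(n_reps)), paste0("c", seq_len(n_reps)))
  rownames(K) <- sprintf("p%05d", seq_len(n_peaks))
  count_matrix(K, setNames(rep(c("test", "control"), each = n_reps),
                           colnames(K)))
}

unit_sf <- function(mat) setNames(rep(1, ncol(mat$counts)),
                                  colnames(mat$counts))

# gain-segment selector tolerant to log2(3/2) = 0.58496...
is_gain <- function(log2cnr) log2cnr >= log2(1.5) - 1e-6
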