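# Shared fixture builders and independent oracles.

make_domains <- function(chrom, start, end, label = NA_character_) {
  data.frame(chrom = chrom, start = start, end = end,
             id = paste0(chrom, ":", start, "-", end),
             subcompartment = label, stringsAsFactors = FALSE)
}

# Random symmetric nonnegative contact matrix over n_bins bins.
random_cis_cm <- function(n_bins, bin_size = 10000, chrom = "chr1",
                          seed = 1) {
  set.seed(seed)
  m <- matrix(stats::runif(n_bins^2), n_bins, n_bins)
  m <- (m + t(m)) / 2
  contact_matrix(m, chrom, chrom, bin_size)
}

# Brute-force I(a, b): explicit double loop over the bins whose midpoints
# fall inside each domain, independent of the package's vectorized path.
brute_interaction <- function(cm, a, b) {
  bs <- cm$bin_size
  mids_in <- function(d) {
    which(vapply(seq_len(nrow(cm$mat)), function(i) {
      mid <- (i - 1 + 0.5) * bs
      mid >= d$start && mid < d$end
    }, logical(1)))
  }
  bi <- mids_in(a); bj <- mids_in(b)
  s <- 0
  for (i in bi) for (j in bj) s <- s + cm$mat[i, j]
  s / ((a$end - a$start) * (b$end - b$start))
}

# Grid maximization of the tail log-likelihood of a continuous power law
# at fixed xmin; successive refinement to ~1e-8 in gamma.
grid_powerlaw_mle <- function(tail, xmin, lo = 1.000001, hi = 10) {
  n <- length(tail)
  slog <- sum(log(tail / xmin))
  loglik <- function(g) n * log(g - 1) - n * log(xmin) - g * slog
  for (pass in 1:6) {
    grid <- seq(lo, hi, length.out = 201)
    ll <- vapply(grid, loglik, numeric(1))
    k <- which.max(ll)
    lo <- grid[max(1, k - 1)]
    hi <- grid[min(length(grid), k + 1)]
  }
  (lo + hi) / 2
}

# Pure power-law sample with density ~ x^-gamma above xmin.
rplaw <- function(n, gamma = 2, xmin = 1) {
  xmin * stats::runif(n)^(-1 / (gamma - 1))
}
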