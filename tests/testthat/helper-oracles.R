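# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: probabilities come from lchoose, ranks are
# assigned by hand, window means by explicit loops.

# two-tailed Fisher p by exhaustive enumeration over all tables with the
# observed margins, summing hypergeometric point probabilities <= observed
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; k <- a + c; N <- a + b + c + d
  if (N == 0) return(1)
  lo <- max(0, k - (N - m)); hi <- min(k, m)
  logp <- function(x) {
    lchoose(m, x) + lchoose(N - m, k - x) - lchoose(N, k)
  }
  p_all <- exp(vapply(lo:hi, logp, numeric(1)))
  p_obs <- p_all[(lo:hi) == a]
  sum(p_all[p_all <= p_obs * (1 + 1e-7)])
}

# Spearman rho: average ranks assigned by hand, then the Pearson formula
oracle_spearman_rho <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# centered rolling mean over index windows i-9 .. i+10 (window 20),
# truncated at the edges, skipping NA values
oracle_rolling_mean <- function(v, window = 20L) {
  n <- length(v)
  before <- (window - 1L) %/% 2L
  after <- window - 1L - before
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- v[max(1, i - before):min(n, i + after)]
    out[i] <- mean(w, na.rm = TRUE)
  }
  out
}

# exact Gaussian kernel sum at one point
oracle_kernel_density <- function(values, h, x) {
  mean(dnorm((x - values) / h)) / h
}

# small deterministic two-chromosome genome for coordinate tests
tiny_genome <- function() {
  Biostrings::DNAStringSet(c(
    chr1 = "ACGTACGGCGTTACGGATCCGGCATCGATCGGCTAGCTAGGCTAGCATCGATGCATGCAT",
    chr2 = "TTGGCCAATTCGCGATATCGCGGCCATATCGCGATCGGCCGCGGATATCCGGTTAACCGG"))
}

# fixed-seed simulation shared by several tests (small but fully featured)
small_sim <- function(seed = 101L, ...) {
  cfg <- sim_config(seed = seed, n_genes = 24L, n_tes = 6L,
                    n_pseudogenes = 2L, gene_len = c(2500L, 3500L), ...)
  gen <- generate_genome(cfg)
  list(cfg = cfg, genome = gen$genome, models = gen$models)
}
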