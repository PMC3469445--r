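#' Spearman rank correlation with a permutation p-value
#'
#' Rank correlation with average ranks for ties; the p-value is estimated by
#' randomly permuting `y` (seeded, so reproducible) and counting permutations
#' with `|rho|` at least as extreme as observed, with the +1 continuity
#' correction, so the smallest attainable p is `1/(n_perm + 1)`.
#'
#' @param x,y paired numeric vectors, `n >= 3`, finite values.
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutations.
#' @return list with `rho` and `p_value`.
#' @export
spearman_perm <- function(x, y, n_perm = 10000L, seed = 1L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired finite values")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("Spearman correlation undefined for a constant vector")
  rho <- cor(x, y, method = "spearman")
  rx <- rank(x); ry <- rank(y)
  obs <- abs(rho)
  hits <- 0L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (i in seq_len(n_perm)) {
    r <- cor(rx, sample(ry))
    if (abs(r) >= obs - 1e-12) hits <- hits + 1L
  }
  list(rho = rho, p_value = (hits + 1) / (n_perm + 1))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed",
                                                       envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Bin genes by log2 fold change
#'
#' Half-open bins `[e_i, e_{i+1})` over monotone edges; values below the
#' first edge join the first bin and values at or above the last edge join
#' the last bin. An `"all"` pseudo-bin holding every row is always emitted,
#' matching the all-genes reference box in fold-change box plots.
#'
#' @param log2fc numeric vector.
#' @param edges increasing bin edges (e.g. `seq(-8.6, 9.8, by = 1)`).
#' @return list with `assignment` (bin label per value) and `bins`
#'   (data.frame of label, lower, upper, n, including the `"all"` row).
#' @export
bin_by_log2fc <- function(log2fc, edges) {
  if (is.unsorted(edges, strictly = TRUE)) stop("edges must be increasing")
  if (length(edges) < 2) stop("need at least two edges")
  k <- length(edges) - 1L
  idx <- findInterval(log2fc, edges, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  idx[idx > k] <- k
  labels <- sprintf("[%g,%g)", edges[-length(edges)], edges[-1])
  assignment <- labels[idx]
  n_per <- tabulate(idx, nbins = k)
  bins <- data.frame(label = c(labels, "all"),
                     lower = c(edges[-length(edges)], -Inf),
                     upper = c(edges[-1], Inf),
                     n = c(n_per, length(log2fc)))
  list(assignment = assignment, bins = bins)
}

#' Five-number box-plot summary
#'
#' Quartiles use linear interpolation of the empirical CDF
#' (`stats::quantile` type 7, R's default); whiskers extend to the most
#' extreme observations within 1.5 times the interquartile range of the box,
#' the convention of Tukey box plots.
#'
#' @param values numeric vector, `n >= 1`.
#' @return named list: `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`, `n`.
#' @export
boxplot_summary <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 1) stop("need at least one finite value")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  in_lo <- values[values >= q[1] - 1.5 * iqr]
  in_hi <- values[values <= q[3] + 1.5 * iqr]
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_lo = min(in_lo), whisker_hi = max(in_hi),
       n = length(values))
}

#' Classify transcriptional direction from log2 fold change
#'
#' Up if log2(mutant/WT) is strictly greater than `threshold`, down if
#' strictly less than `-threshold`, otherwise none.
#'
#' @param log2fc finite value(s).
#' @param threshold positive cutoff (0.5 by default).
#' @return character vector in `c("up", "down", "none")`.
#' @export
classify_direction <- function(log2fc, threshold = 0.5) {
  ifelse(log2fc > threshold, "up",
         ifelse(log2fc < -threshold, "down", "none"))
}

#' Hypergeometric test of gene-set overlap
#'
#' Builds the 2x2 table from \eqn{|A \cap B|}, \eqn{|A \setminus B|},
#' \eqn{|B \setminus A|} and the remaining universe, and applies the shared
#' two-tailed Fisher exact test ([fisher_exact_test()]).
#'
#' @param setA,setB character vectors of gene ids (subsets of the universe).
#' @param universe_size total number of genes considered.
#' @return list with `overlap`, `expected`, and `p_value`.
#' @export
overlap_test <- function(setA, setB, universe_size) {
  setA <- unique(setA); setB <- unique(setB)
  n_union <- length(union(setA, setB))
  if (universe_size < n_union)
    stop("universe smaller than the union of the two sets")
  ab <- length(intersect(setA, setB))
  a_only <- length(setA) - ab
  b_only <- length(setB) - ab
  rest <- universe_size - ab - a_only - b_only
  list(overlap = ab,
       expected = length(setA) * length(setB) / universe_size,
       p_value = fisher_exact_test(ab, a_only, b_only, rest))
}
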