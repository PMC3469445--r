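#' Two-tailed Fisher exact test for 2x2 tables
#'
#' Conditional exact test on a 2x2 contingency table
#' \preformatted{  a  b
#'   c  d}
#' with both margins fixed. The two-tailed p-value is the sum of the
#' hypergeometric probabilities of all tables (with the same margins) whose
#' point probability does not exceed that of the observed table, the standard
#' two-sided convention. A relative tolerance of 1e-7 guards the comparison
#' against floating-point ties, as in \code{stats::fisher.test}.
#'
#' This is the single shared exact test used by the differential-methylation
#' windows, the per-ecotype differential-expression test, and the gene-set
#' overlap test. All four arguments are vectorized and recycled.
#'
#' @param a,b,c,d non-negative integer cell counts; rows are the two
#'   conditions, columns the two outcomes (e.g. methylated/unmethylated).
#' @return numeric vector of two-tailed p-values in (0, 1].
#' @examples
#' fisher_exact_test(30, 70, 10, 90)
#' @export
fisher_exact_test <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(a < 0 | b < 0 | c < 0 | d < 0)) stop("negative cell count")
  if (any(a != round(a) | b != round(b) | c != round(c) | d != round(d)))
    stop("cell counts must be integers")
  vapply(seq_len(n), function(i) {
    fisher_two_tail_one(a[i], b[i], c[i], d[i])
  }, numeric(1))
}

# p for one table; margins m = a+b (row 1), k = a+c (col 1), N = a+b+c+d
fisher_two_tail_one <- function(a, b, c, d) {
  m <- a + b
  k <- a + c
  N <- a + b + c + d
  if (N == 0) return(1)
  lo <- max(0, k - (N - m))
  hi <- min(k, m)
  x <- lo:hi
  p <- dhyper(x, m, N - m, k)
  p_obs <- p[x == a]
  sum(p[p <= p_obs * (1 + 1e-7)])
}
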