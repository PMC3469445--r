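test_that("context calling reads the strand-appropriate trinucleotide", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ACGTT", chr2 = "ACAGT",
                                  chr3 = "TTCGG"))
  expect_equal(call_context(g, "chr1", 1, "+"), "CG")
  expect_equal(call_context(g, "chr2", 1, "+"), "CHG")
  # minus strand at a genomic G: base is C on -, next (leftward) is G -> CG
  expect_equal(call_context(g, "chr3", 3, "-"), "CG")
  expect_equal(call_context(g, "chr1", 0, "+"), "not_cytosine")
  expect_error(call_context(g, "chr1", 4, "+"), "downstream")
  gn <- Biostrings::DNAStringSet(c(chr1 = "ACNGT"))
  expect_error(call_context(gn, "chr1", 1, "+"), "N in trinucleotide")
})

test_that("context calls agree with brute-force reverse complementation", {
  sim <- small_sim()
  seq1 <- as.character(sim$genome[["chr1"]])
  rc <- as.character(Biostrings::reverseComplement(sim$genome[["chr1"]]))
  L <- nchar(seq1)
  set.seed(3)
  pos <- sample(2:(L - 3), 50)
  for (p in pos) {
    minus <- call_context(sim$genome, "chr1", p, "-")
    # equivalent plus-strand call in the reverse-complemented sequence
    plus_rc <- call_context(
      Biostrings::DNAStringSet(c(chr1 = rc)), "chr1", L - 1 - p, "+")
    expect_equal(minus, plus_rc)
  }
})

test_that("weighted level pools counts rather than averaging fractions", {
  expect_equal(weighted_level(c(3, 0), c(1, 4)), 0.375)
  expect_true(is.na(weighted_level(c(0, 0), c(0, 0))))
  set.seed(4)
  c_cnt <- rpois(1000, 3); t_cnt <- rpois(1000, 5)
  acc_c <- 0; acc_t <- 0
  for (i in 1:1000) { acc_c <- acc_c + c_cnt[i]; acc_t <- acc_t + t_cnt[i] }
  expect_equal(weighted_level(c_cnt, t_cnt), acc_c / (acc_c + acc_t))
})

test_that("a lone methylated CG lands in exactly its 5' bin", {
  calls <- cytosine_calls("chr1", 2050, "+", "CG", 1, 0)
  gene <- gene_models("g1", "chr1", 2000, 9000, "+")
  mp <- ends_aligned_metaplot(calls, gene, "CG", "five_prime",
                              upstream = 2000, into = 5000, bin = 100)
  expect_equal(nrow(mp), 70)
  expect_equal(mp$level[mp$offset == 0], 1.0)
  expect_equal(sum(!is.na(mp$level)), 1)
  expect_equal(sum(mp$coverage), 1)
})

test_that("metaplots are invariant under genome mirror-reversal", {
  sim <- small_sim()
  calls <- generate_methylome(sim$genome, sim$models, sim$cfg, "WT",
                              contexts = "CG")
  genes <- sim$models[sim$models$feature_class == "gene", ]
  lens <- chrom_lengths(sim$genome)
  m_calls <- mirror_calls(calls, lens)
  m_genes <- mirror_features(genes, lens)
  for (anchor in c("five_prime", "three_prime")) {
    a <- ends_aligned_metaplot(calls, genes, "CG", anchor,
                               upstream = 1000, into = 2000, bin = 100)
    b <- ends_aligned_metaplot(m_calls, m_genes, "CG", anchor,
                               upstream = 1000, into = 2000, bin = 100)
    expect_equal(a$level, b$level)
    expect_equal(a$coverage, b$coverage)
  }
})

test_that("window tiling is half-open from coordinate 0", {
  calls <- cytosine_calls(c("chr1", "chr1"), c(49, 50), "+", "CG",
                          c(1, 2), c(1, 0))
  wt <- window_table(calls, window = 50)
  expect_equal(wt$start, c(0L, 50L))
  expect_equal(wt$c, c(1L, 2L))
  empty <- window_table(cytosine_calls(character(0), integer(0),
                                       character(0), character(0),
                                       integer(0), integer(0)))
  expect_equal(nrow(empty), 0)
})

test_that("window pooling equals brute-force per-window sums", {
  sim <- small_sim()
  calls <- generate_methylome(sim$genome, sim$models, sim$cfg, "WT",
                              contexts = "CG")
  wt <- window_table(calls, window = 50, context = "CG")
  set.seed(5)
  for (i in sample(nrow(wt), 20)) {
    sel <- calls$chrom == wt$chrom[i] & calls$pos >= wt$start[i] &
      calls$pos < wt$start[i] + 50 & calls$context == "CG"
    expect_equal(wt$c[i], sum(calls$c[sel]))
    expect_equal(wt$t[i], sum(calls$t[sel]))
  }
})

test_that("differential windows apply the exact test, the 10% filter, and TE exclusion", {
  mk <- function(c_, t_) data.frame(chrom = "chr1", start = 100L,
                                    context = "CG", c = c_, t = t_,
                                    n_sites = 5L,
                                    level = c_ / (c_ + t_))
  # diff = 0.20: retained, p equals the frozen enumeration value
  r <- differential_methylation_windows(mk(30L, 70L), mk(10L, 90L))
  expect_equal(nrow(r$windows), 1)
  expect_equal(r$windows$p_value, 0.000650410707603, tolerance = 1e-10)
  expect_equal(r$windows$direction, "gain")
  # diff = 0.02 < 10%: excluded
  r2 <- differential_methylation_windows(mk(12L, 88L), mk(10L, 90L))
  expect_equal(nrow(r2$windows), 0)
  # overlap with a transposon: excluded regardless of counts
  te <- gene_models("te1", "chr1", 120, 400, "+", "transposon")
  r3 <- differential_methylation_windows(mk(30L, 70L), mk(10L, 90L),
                                         exclude = te)
  expect_equal(nrow(r3$windows), 0)
  # zero coverage in one condition: skipped and counted
  suppressMessages(
    r4 <- differential_methylation_windows(mk(0L, 0L), mk(10L, 90L)))
  expect_equal(r4$n_skipped, 1)
})

test_that("no reported window ever has |diff| below the filter", {
  sim <- small_sim()
  wt_c <- generate_methylome(sim$genome, sim$models, sim$cfg, "WT",
                             contexts = "CG")
  mut_c <- generate_methylome(sim$genome, sim$models, sim$cfg, "mutant",
                              contexts = "CG")
  r <- differential_methylation_windows(window_table(mut_c, 50, "CG"),
                                        window_table(wt_c, 50, "CG"))
  expect_true(all(abs(r$windows$diff) >= 0.10))
})

test_that("the KDE matches its closed form and brute-force kernel sums", {
  d <- kde_gaussian(5, bandwidth = 2, from = 5, to = 5, n = 1L)
  expect_equal(d$density, 1 / (2 * sqrt(2 * pi)))
  sym <- kde_gaussian(c(-0.4, 0.4), bandwidth = 0.1, from = -1, to = 1,
                      n = 201L)
  expect_equal(sym$density, rev(sym$density))
  set.seed(6)
  v <- rnorm(150, sd = 0.2)
  est <- methylation_difference_kde(v, bandwidth = 0.05, n = 101L)
  for (i in seq(1, 101, by = 10)) {
    expect_equal(est$density[i],
                 oracle_kernel_density(v, 0.05, est$x[i]), tolerance = 1e-12)
  }
  # integrates to ~1 over the grid when the mass is interior
  expect_equal(sum(est$density) * diff(est$x[1:2]), 1, tolerance = 0.01)
  expect_error(methylation_difference_kde(0.5), "at least 2")
})

test_that("locus extraction reports per-site and pooled levels", {
  calls <- cytosine_calls(rep("chr1", 2), c(110, 130), "+", "CG",
                          c(4, 0), c(0, 4))
  locus <- list(chrom = "chr1", start = 100, end = 150)
  r <- extract_locus_methylation(calls, locus, c(110, 130))
  expect_equal(r$per_site$level, c(1.0, 0.0))
  expect_equal(r$average, 0.5)
  expect_equal(r$average_percent, 50)
  expect_error(extract_locus_methylation(calls, locus, integer(0)),
               "non-empty")
  expect_error(extract_locus_methylation(calls, locus, 90), "within")
  # uncovered site is NA and excluded from the pooled denominator
  r2 <- extract_locus_methylation(calls, locus, c(110, 120, 130))
  expect_true(is.na(r2$per_site$level[2]))
  expect_equal(r2$average, 0.5)
  # pooled average equals weighted_level of the same calls
  sim <- small_sim()
  mcalls <- generate_methylome(sim$genome, sim$models, sim$cfg, "WT",
                               contexts = "CG")
  g <- sim$models[sim$models$feature_class == "gene", ][1, ]
  sel <- mcalls$chrom == g$chrom & mcalls$pos >= g$start &
    mcalls$pos < g$start + 500
  sites <- head(unique(mcalls$pos[sel]), 20)
  r3 <- extract_locus_methylation(
    mcalls, list(chrom = g$chrom, start = g$start, end = g$start + 500),
    sites)
  sub <- mcalls[mcalls$chrom == g$chrom & mcalls$pos %in% sites, ]
  expect_equal(r3$average, weighted_level(sub$c, sub$t))
})
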