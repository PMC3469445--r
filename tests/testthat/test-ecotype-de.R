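test_that("scaffolds center the SNP and differ only there", {
  sim <- small_sim()
  lens <- chrom_lengths(sim$genome)
  snps <- data.frame(chrom = "chr1", pos = c(100L, 10L),
                     allele_ws = c("A", "A"), allele_col = c("G", "G"))
  expect_message(sc <- build_scaffolds(sim$genome, snps), "dropped")
  expect_equal(nrow(sc), 1)          # the SNP at pos 10 lacks flank
  expect_equal(nchar(sc$ws_scaffold), 75)
  diffs <- which(strsplit(sc$ws_scaffold, "")[[1]] !=
                   strsplit(sc$col_scaffold, "")[[1]])
  expect_equal(diffs, 38)            # 1-based center of a 75-mer
  # scaffold equals the genome slice with a substituted center
  ref <- substring(as.character(sim$genome[["chr1"]]), 100 - 37 + 1,
                   100 + 37 + 1)
  expect_equal(substring(sc$col_scaffold, 1, 37), substring(ref, 1, 37))
  expect_equal(substring(sc$ws_scaffold, 39, 75), substring(ref, 39, 75))
  expect_equal(substring(sc$ws_scaffold, 38, 38), "A")
})

test_that("read assignment requires a center-covering exact match", {
  sim <- small_sim()
  snps <- data.frame(chrom = "chr1", pos = 200L, allele_ws = "A",
                     allele_col = "G")
  seq1 <- as.character(sim$genome[["chr1"]])
  # force a known reference base so alleles are meaningful
  substr(seq1, 201, 201) <- "G"
  genome <- Biostrings::DNAStringSet(c(chr1 = seq1,
                                       chr2 = as.character(sim$genome[["chr2"]])))
  sc <- build_scaffolds(genome, snps)
  covering_ws <- substring(sc$ws_scaffold, 21, 56)   # covers center (38)
  covering_col <- substring(sc$col_scaffold, 21, 56)
  non_covering <- substring(sc$ws_scaffold, 1, 36)   # bases 0-35, no SNP
  mism <- covering_ws
  substr(mism, 5, 5) <- chartr("ACGT", "TGCA", substring(mism, 5, 5))
  r <- assign_reads(c(covering_ws, covering_col, non_covering, mism), sc)
  expect_equal(r$ws_reads, 1L)
  expect_equal(r$col_reads, 1L)
  # reverse-complemented reads are matched too
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(covering_ws)))
  r2 <- assign_reads(rc, sc)
  expect_equal(r2$ws_reads, 1L)
  # exhaustive offset scan: every center-covering 36-mer assigns, every
  # non-covering 36-mer is discarded (it matches both scaffolds)
  for (off in 0:39) {
    km <- substring(sc$ws_scaffold, off + 1, off + 36)
    res <- assign_reads(km, sc)
    covers <- off >= 2 && off <= 37
    expect_equal(res$ws_reads, as.integer(covers))
    expect_equal(res$col_reads, 0L)
  }
})

test_that("SNP filters apply the three retention rules", {
  snps <- data.frame(chrom = "chr1", pos = c(500L, 530L, 700L, 800L),
                     allele_ws = "A", allele_col = "G",
                     gene_id = c("g1", "g1", "g2", "g3"),
                     gene_length = c(1000L, 1000L, 150L, 1000L),
                     exon_start = c(400L, 400L, 650L, 700L),
                     exon_end = c(600L, 560L, 850L, 900L),
                     ws_reads = c(5L, 5L, 20L, 4L),
                     col_reads = c(5L, 5L, 20L, 5L))
  f <- filter_snps(snps)
  # pos 500: all rules pass. pos 530: 29 bp from exon end -> removed.
  # pos 700: gene only 150 bp -> removed. pos 800: 9 reads -> removed.
  expect_equal(f$pos, 500L)
  snps$ws_reads[4] <- 5L
  expect_equal(filter_snps(snps)$pos, c(500L, 800L))
})

test_that("genotype calls follow the minor-allele thresholds", {
  expect_equal(call_genotype(20, 0), "WS")
  expect_equal(call_genotype(10, 12), "Het")
  expect_equal(call_genotype(48, 2), "WS")   # minor fraction 0.04
  expect_equal(call_genotype(45, 5), "Het")  # fraction 0.1, count 5
  expect_equal(call_genotype(9, 1, min_reads = 10), "WS")
  expect_equal(call_genotype(4, 4), "untyped")
  expect_equal(call_genotype(c(20, 10), c(0, 12)), c("WS", "Het"))
})

test_that("contribution smoothing is a centered truncated rolling mean", {
  mk <- function(f, geno = "Het", chrom = "chr1") {
    data.frame(chrom = chrom, pos = seq_along(f) * 100L,
               genotype = geno, contribution_ws = f)
  }
  # constant vector is a fixed point
  s1 <- smooth_contributions(mk(rep(0.25, 50)))
  expect_equal(s1$smoothed_contribution_ws, rep(0.25, 50))
  # block of 5 with window 20: every value is the block mean
  s2 <- smooth_contributions(mk(c(0.1, 0.2, 0.3, 0.4, 0.5)))
  expect_equal(s2$smoothed_contribution_ws, rep(0.3, 5))
  # random 100-SNP block equals the brute-force windowed mean
  set.seed(12)
  f <- runif(100)
  s3 <- smooth_contributions(mk(f))
  expect_equal(s3$smoothed_contribution_ws, oracle_rolling_mean(f))
  # homozygous interruptions split blocks
  tab <- mk(c(runif(10), NA, runif(10)))
  tab$genotype[11] <- "WS"
  s4 <- smooth_contributions(tab)
  expect_true(is.na(s4$smoothed_contribution_ws[11]))
  expect_equal(s4$smoothed_contribution_ws[1:10],
               oracle_rolling_mean(tab$contribution_ws[1:10]))
  expect_equal(s4$smoothed_contribution_ws[12:21],
               oracle_rolling_mean(tab$contribution_ws[12:21]))
})

test_that("RPKM and partitioning follow their formulas exactly", {
  expect_equal(rpkm(100, 2000, 1e7), 5)
  expect_equal(rpkm(0, 2000, 1e7), 0)
  expect_error(rpkm(10, 0, 1e6), "length")
  set.seed(13)
  cnt <- rpois(50, 200); len <- sample(500:5000, 50); lib <- 2e6
  expect_equal(rpkm(cnt, len, lib), cnt / (len / 1000) / (lib / 1e6))

  p <- partition_counts(100, "Het", 0.25)
  expect_equal(p$ws, 25); expect_equal(p$col, 75)
  p2 <- partition_counts(40, "WS")
  expect_equal(p2$ws, 40); expect_equal(p2$col, 0)
  # conservation holds exactly for random inputs
  cnts <- runif(1000, 0, 500)
  genos <- sample(c("WS", "Col", "Het"), 1000, replace = TRUE)
  fs <- runif(1000)
  pp <- partition_counts(cnts, genos, fs)
  expect_equal(pp$ws + pp$col, cnts)
  expect_error(partition_counts(10, "Het", NA), "requires a contribution")
})

test_that("the per-ecotype exact test builds the gene-vs-library table", {
  expect_equal(fisher_de_test(50, 50, 1e4, 1e4), 1)
  p <- fisher_de_test(0, 20, 1e4, 1e4)
  expect_equal(p, 1.88929709839e-06, tolerance = 1e-9)
  expect_equal(p, oracle_fisher(0, 1e4, 20, 1e4 - 20), tolerance = 1e-12)
  # doubling counts and libraries increases significance
  expect_lt(fisher_de_test(0, 40, 2e4, 2e4), p)
  # zero marginals return 1
  expect_equal(fisher_de_test(0, 0, 1e4, 1e4), 1)
})

test_that("DE calls implement the two-threshold rule", {
  # single ecotype: two-fold and p < 0.001
  expect_equal(call_de(NA, log2(2.3), NA, 5e-4), "up")
  # below two-fold never qualifies, however significant
  expect_equal(call_de(log2(1.9), NA, 1e-6, NA), "none")
  # both ecotypes at p < 0.005
  expect_equal(call_de(log2(2.5), log2(2.5), 0.003, 0.003), "up")
  expect_equal(call_de(-1.2, -1.4, 0.004, 0.002), "down")
  # both-rule requires the same direction
  expect_equal(call_de(1.2, -1.4, 0.004, 0.002), "none")
  # contradictory single-ecotype qualifications flag and yield none
  r <- call_de(1.2, -1.4, 1e-5, 1e-5)
  expect_equal(as.character(r), "none")
  expect_true(attr(r, "contradictory"))
  expect_equal(call_de(1.2, NA, 0.0009, NA), "up")
  expect_equal(call_de(1.2, NA, 0.002, NA), "none")
})

test_that("an all-Col genome reduces to a plain per-gene Fisher DE test", {
  cfg <- sim_config(seed = 77, n_genes = 60, n_tes = 0, n_pseudogenes = 0,
                    rna = list(block_pattern = "Col", n_planted = 6L))
  gen <- generate_genome(cfg)
  rna <- generate_rnaseq(gen$genome, gen$models, cfg)
  genes <- gen$models[gen$models$feature_class == "gene", ]
  scaf <- build_scaffolds(gen$genome, rna$snps)
  for (s in names(rna$reads)) {
    ct <- assign_reads(rna$reads[[s]], scaf)
    scaf[[paste0("ws_reads_", s)]] <- ct$ws_reads
    scaf[[paste0("col_reads_", s)]] <- ct$col_reads
  }
  scaf <- annotate_snps(scaf, genes)
  de <- run_ecotype_de(genes, scaf, rna$gene_counts, rna$condition,
                       library_sizes = rna$library_sizes)
  expect_true(all(de$results$genotype_mut[!is.na(de$results$genotype_mut)] ==
                    "Col"))
  expect_true(all(is.na(de$results$p_ws) | de$results$p_ws == 1))
  # oracle: direct Fisher DE on smallest-library-normalized summed counts
  libs <- rna$library_sizes
  min_lib <- min(libs)
  norm <- sweep(rna$gene_counts, 2, min_lib / libs, "*")
  sum_mut <- rowSums(norm[, rna$condition == "mut"])
  sum_wt <- rowSums(norm[, rna$condition == "wt"])
  lib_m <- round(3 * min_lib); lib_w <- round(3 * min_lib)
  usable <- !is.na(de$results$genotype_mut)
  p_oracle <- mapply(function(a, b)
    oracle_fisher(round(a), lib_m - round(a), round(b), lib_w - round(b)),
    sum_mut[usable], sum_wt[usable])
  expect_equal(de$results$p_col[usable], unname(p_oracle))
})

test_that("partition conservation holds before rounding in the full chain", {
  cfg <- sim_config(seed = 78, n_genes = 60, n_tes = 0, n_pseudogenes = 0)
  gen <- generate_genome(cfg)
  rna <- generate_rnaseq(gen$genome, gen$models, cfg)
  genes <- gen$models[gen$models$feature_class == "gene", ]
  scaf <- build_scaffolds(gen$genome, rna$snps)
  for (s in names(rna$reads)) {
    ct <- assign_reads(rna$reads[[s]], scaf)
    scaf[[paste0("ws_reads_", s)]] <- ct$ws_reads
    scaf[[paste0("col_reads_", s)]] <- ct$col_reads
  }
  scaf <- annotate_snps(scaf, genes)
  de <- run_ecotype_de(genes, scaf, rna$gene_counts, rna$condition,
                       library_sizes = rna$library_sizes)
  libs <- rna$library_sizes
  min_lib <- min(libs)
  norm <- sweep(rna$gene_counts, 2, min_lib / libs, "*")
  sum_mut <- rowSums(norm[, rna$condition == "mut"])
  ok <- !is.na(de$results$ws_mut)
  expect_equal(de$results$ws_mut[ok] + de$results$col_mut[ok],
               unname(sum_mut[ok]))
})
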