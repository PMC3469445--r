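#' Read / write a WS/Col diagnostic SNP table
#'
#' TSV with columns chrom, pos (0-based), allele_ws, allele_col (single
#' bases); header lines beginning `#` are skipped.
#'
#' @param path TSV file.
#' @return data.frame with the four columns.
#' @export
read_snp_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("chrom", "pos", "allele_ws", "allele_col")
  if (!all(need %in% names(dt)))
    stop(sprintf("SNP table '%s' must have columns: %s", path,
                 paste(need, collapse = ", ")))
  dt$pos <- as.integer(dt$pos)
  dt
}

#' @rdname read_snp_table
#' @param snps the SNP table.
#' @export
write_snp_table <- function(snps, path) {
  data.table::fwrite(snps[c("chrom", "pos", "allele_ws", "allele_col")],
                     path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Build per-SNP ecotype scaffolds
#'
#' For each SNP, extracts the genomic window centering the SNP (37 bp of
#' flank on each side for the default 75-bp scaffold) and substitutes the
#' center base with each ecotype's allele, yielding two scaffolds that differ
#' only at the center. SNPs too close to a chromosome end for a full flank
#' are dropped (and reported with a message).
#'
#' @param genome named `DNAStringSet`.
#' @param snps SNP table (chrom, pos, allele_ws, allele_col).
#' @param length odd scaffold length in bp.
#' @return the retained SNP rows with `ws_scaffold` and `col_scaffold`
#'   character columns added.
#' @export
build_scaffolds <- function(genome, snps, length = 75L) {
  if (length %% 2L != 1L) stop("scaffold length must be odd")
  flank <- (length - 1L) %/% 2L
  lens <- chrom_lengths(genome)
  L <- lens[snps$chrom]
  ok <- snps$pos >= flank & snps$pos + flank < L
  if (any(!ok))
    message(sprintf("%d SNPs dropped: insufficient flank for %d-bp scaffolds",
                    sum(!ok), length))
  snps <- snps[ok, , drop = FALSE]
  ws <- col <- character(nrow(snps))
  for (ch in unique(snps$chrom)) {
    sel <- snps$chrom == ch
    seq <- as.character(genome[[ch]])
    core <- substring(seq, snps$pos[sel] - flank + 1L, snps$pos[sel] + flank + 1L)
    substr_at <- function(s, allele) {
      substring(s, flank + 1L, flank + 1L) <- allele
      s
    }
    ws[sel] <- substr_at(core, snps$allele_ws[sel])
    col[sel] <- substr_at(core, snps$allele_col[sel])
  }
  snps$ws_scaffold <- ws
  snps$col_scaffold <- col
  rownames(snps) <- NULL
  snps
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Assign reads to ecotype scaffolds by exact matching
#'
#' Exact substring matching of fixed-length reads against each SNP's pair of
#' ecotype scaffolds, in both orientations (a read is also compared after
#' reverse complementation), with no tolerance for mismatches. A read counts
#' for an ecotype at a SNP only if it matches that ecotype's scaffold at an
#' offset covering the center (SNP) base and does not match the other
#' ecotype's scaffold at any offset; reads matching both scaffolds (possible
#' only at offsets not covering the SNP) are uninformative and discarded.
#'
#' @param reads character vector of read sequences (all the same length,
#'   at most the scaffold length).
#' @param scaffolds output of [build_scaffolds()].
#' @return `scaffolds` with integer columns `ws_reads` and `col_reads` added.
#' @export
assign_reads <- function(reads, scaffolds) {
  rl <- unique(nchar(reads))
  if (length(rl) != 1) stop("reads must all have the same length")
  sl <- nchar(scaffolds$ws_scaffold[1])
  if (rl > sl) stop("read length exceeds scaffold length")
  center <- (sl - 1L) %/% 2L
  offs <- 0:(sl - rl)                       # 0-based start offsets
  covering <- offs >= (center - rl + 1L) & offs <= center
  n_snp <- nrow(scaffolds)
  kmer_of <- function(scaf) {
    # matrix [n_snp x n_offsets] of substrings
    vapply(offs, function(o) substring(scaf, o + 1L, o + rl),
           character(n_snp))
  }
  dict <- data.table::data.table(
    kmer = c(kmer_of(scaffolds$ws_scaffold), kmer_of(scaffolds$col_scaffold)),
    snp = rep(rep(seq_len(n_snp), length(offs)), 2L),
    eco = rep(c("ws", "col"), each = n_snp * length(offs)),
    covering = rep(rep(covering, each = n_snp), 2L))
  seqs <- unique(c(reads, revcomp_chr(reads)))
  hits <- dict[dict$kmer %in% seqs]
  # per (kmer, snp, eco): does it cover the center at any matching offset,
  # and does it match at all (any offset)?
  agg <- hits[, .(covers = any(covering)), by = .(kmer, snp, eco)]
  wide <- data.table::dcast(agg, kmer + snp ~ eco, value.var = "covers")
  if (!"ws" %in% names(wide)) wide$ws <- NA
  if (!"col" %in% names(wide)) wide$col <- NA
  # assignment rule: covering match to one ecotype, no match to the other
  wide$assign <- ifelse(!is.na(wide$ws) & wide$ws & is.na(wide$col), "ws",
                 ifelse(!is.na(wide$col) & wide$col & is.na(wide$ws), "col",
                        NA_character_))
  wide <- wide[!is.na(wide$assign)]
  # count reads: each read contributes through its forward or reverse
  # orientation (a read matching in both orientations counts once)
  key <- ifelse(reads %in% wide$kmer, reads,
                ifelse(revcomp_chr(reads) %in% wide$kmer,
                       revcomp_chr(reads), NA_character_))
  counts <- data.table::data.table(kmer = key[!is.na(key)])[, .N, by = kmer]
  tallied <- merge(wide, counts, by = "kmer")
  ws_reads <- col_reads <- integer(n_snp)
  if (nrow(tallied) > 0) {
    for (e in c("ws", "col")) {
      sub <- tallied[tallied$assign == e]
      if (nrow(sub) > 0) {
        s <- rowsum(sub$N, sub$snp)
        if (e == "ws") ws_reads[as.integer(rownames(s))] <- s[, 1]
        else col_reads[as.integer(rownames(s))] <- s[, 1]
      }
    }
  }
  scaffolds$ws_reads <- ws_reads
  scaffolds$col_reads <- col_reads
  scaffolds
}

#' Assign SNPs to genes and exons
#'
#' Links each SNP to the exon (and gene) containing it; SNPs outside every
#' exon get `NA` and are removed by [filter_snps()]. When exons of several
#' models contain a SNP, the first model in `models` order wins.
#'
#' @param snps SNP table.
#' @param models a `gene_models` table.
#' @return `snps` with `gene_id`, `gene_length`, `exon_start`, `exon_end`.
#' @export
annotate_snps <- function(snps, models) {
  snps$gene_id <- NA_character_
  snps$gene_length <- NA_integer_
  snps$exon_start <- NA_integer_
  snps$exon_end <- NA_integer_
  for (i in seq_len(nrow(models))) {
    ex <- models$exons[[i]]
    for (j in seq_len(nrow(ex))) {
      hit <- is.na(snps$gene_id) & snps$chrom == models$chrom[i] &
        snps$pos >= ex[j, 1] & snps$pos < ex[j, 2]
      if (any(hit)) {
        snps$gene_id[hit] <- models$id[i]
        snps$gene_length[hit] <- models$end[i] - models$start[i]
        snps$exon_start[hit] <- ex[j, 1]
        snps$exon_end[hit] <- ex[j, 2]
      }
    }
  }
  snps
}

#' Filter SNPs for the allele-aware DE procedure
#'
#' Retains SNPs that (1) lie within an exon of a gene longer than
#' `min_gene_len` bp, (2) have at least `min_reads` scaffold-assigned reads
#' summed over all samples, and (3) lie at least one read length
#' (`min_dist_from_exon_end`, 36 bp) from both ends of their exon — a SNP
#' closer to the exon edge cannot be covered by reads at all offsets and
#' yields biased counts.
#'
#' @param snps annotated SNP table with per-sample count columns
#'   (`ws_reads_*`/`col_reads_*`, or plain `ws_reads`/`col_reads`).
#' @param min_gene_len minimum gene length in bp (exclusive).
#' @param min_reads minimum total assigned reads (inclusive).
#' @param min_dist_from_exon_end minimum distance to either exon end in bp.
#' @return the retained SNP rows.
#' @export
filter_snps <- function(snps, min_gene_len = 200L, min_reads = 10L,
                        min_dist_from_exon_end = 36L) {
  ws_cols <- grep("^ws_reads", names(snps), value = TRUE)
  col_cols <- grep("^col_reads", names(snps), value = TRUE)
  total <- rowSums(snps[, ws_cols, drop = FALSE]) +
    rowSums(snps[, col_cols, drop = FALSE])
  dist <- pmin(snps$pos - snps$exon_start,
               snps$exon_end - 1L - snps$pos)
  keep <- !is.na(snps$gene_id) & snps$gene_length > min_gene_len &
    total >= min_reads & dist >= min_dist_from_exon_end
  out <- snps[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call the local genotype at a SNP from ecotype read counts
#'
#' `Het` when the minor allele reaches at least `het_minor_frac` of reads and
#' at least `het_minor_count` reads (robust to ~1\% sequencing error at
#' depths 10-100); otherwise homozygous for the majority allele; `untyped`
#' below `min_reads` total.
#'
#' @param ws_count,col_count scaffold-assigned read counts (vectors).
#' @param min_reads minimum informative depth.
#' @param het_minor_frac,het_minor_count heterozygosity thresholds.
#' @return character vector in `c("WS", "Col", "Het", "untyped")`.
#' @examples
#' call_genotype(20, 0)   # "WS"
#' call_genotype(10, 12)  # "Het"
#' call_genotype(48, 2)   # "WS" (minor fraction 0.04)
#' @export
call_genotype <- function(ws_count, col_count, min_reads = 10L,
                          het_minor_frac = 0.1, het_minor_count = 2L) {
  total <- ws_count + col_count
  minor <- pmin(ws_count, col_count)
  out <- ifelse(total < min_reads, "untyped",
         ifelse(minor / total >= het_minor_frac & minor >= het_minor_count,
                "Het",
                ifelse(ws_count >= col_count, "WS", "Col")))
  out
}

#' Smooth heterozygous read-count contributions along the chromosome
#'
#' SNPs within a heterozygous region generally show similar WS:Col read
#' ratios, so per-SNP contributions are denoised with a centered rolling mean
#' over `window` consecutive heterozygous SNPs. Smoothing is restricted to
#' contiguous Het blocks — maximal runs of Het SNPs on one chromosome
#' uninterrupted by homozygous calls — so unrelated regions are never
#' blended; windows are truncated at block edges. For the even default
#' window of 20 the centered window spans indices `i-9 .. i+10`.
#'
#' @param snps SNP table ordered by (chrom, pos) with columns `chrom`,
#'   `genotype`, and `contribution_ws` (defined for Het SNPs; a Het SNP with
#'   an `NA` contribution stays in its block but contributes nothing to
#'   window means).
#' @param window rolling window size in SNPs.
#' @return `snps` with a `smoothed_contribution_ws` column (`NA` for
#'   non-Het SNPs).
#' @export
smooth_contributions <- function(snps, window = 20L) {
  if (is.unsorted(order(snps$chrom, snps$pos)))
    snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  sm <- rep(NA_real_, nrow(snps))
  is_het <- snps$genotype == "Het"
  # block id: new block at chrom change or interruption by non-Het
  r <- rle(paste0(snps$chrom, "|", is_het))
  block <- rep(seq_along(r$lengths), r$lengths)
  before <- (window - 1L) %/% 2L      # 9 for window 20
  after <- window - 1L - before       # 10 for window 20
  for (b in unique(block[is_het])) {
    idx <- which(block == b & is_het)
    v <- snps$contribution_ws[idx]
    n <- length(v)
    cs <- c(0, cumsum(ifelse(is.na(v), 0, v)))
    cn <- c(0, cumsum(!is.na(v)))
    lo <- pmax(seq_len(n) - before, 1L)
    hi <- pmin(seq_len(n) + after, n)
    k <- cn[hi + 1L] - cn[lo]
    sm[idx] <- ifelse(k > 0, (cs[hi + 1L] - cs[lo]) / k, NA_real_)
  }
  snps$smoothed_contribution_ws <- sm
  snps
}

#' Reads per kilobase of exon model per million mapped reads
#'
#' @param count mapped reads for the gene.
#' @param exon_model_length_bp summed exon length in bp (> 0).
#' @param library_reads total mapped reads in the library (> 0).
#' @return RPKM value(s).
#' @examples
#' rpkm(100, 2000, 1e7)  # 5
#' @export
rpkm <- function(count, exon_model_length_bp, library_reads) {
  if (any(exon_model_length_bp <= 0)) stop("exon model length must be > 0")
  if (any(library_reads <= 0)) stop("library size must be > 0")
  count / (exon_model_length_bp / 1000) / (library_reads / 1e6)
}

#' Partition a gene's read count between the WS and Col ecotypes
#'
#' Homozygous regions contribute all reads to their ecotype; in heterozygous
#' regions the count is split by the smoothed WS read-count contribution `f`
#' of the nearest retained SNP. The two parts conserve the input exactly
#' (`ws + col == count` before any rounding).
#'
#' @param count gene read count (possibly normalized, non-integer).
#' @param genotype `"WS"`, `"Col"` or `"Het"` (vectors recycle).
#' @param f smoothed WS contribution in \eqn{[0,1]} (used for Het only).
#' @return list with numeric vectors `ws` and `col`.
#' @examples
#' partition_counts(100, "Het", 0.25)  # ws 25, col 75
#' @export
partition_counts <- function(count, genotype, f = NA_real_) {
  n <- max(length(count), length(genotype), length(f))
  count <- rep_len(count, n); genotype <- rep_len(genotype, n)
  f <- rep_len(f, n)
  if (any(genotype == "Het" & (is.na(f) | f < 0 | f > 1)))
    stop("Het partition requires a contribution f in [0,1]")
  ws <- ifelse(genotype == "WS", count,
        ifelse(genotype == "Col", 0, count * f))
  list(ws = ws, col = count - ws)
}

#' Per-ecotype Fisher exact test of mutant vs wild-type expression
#'
#' Tests a gene's (ecotype-partitioned) read count against the rest of the
#' library with the two-tailed Fisher exact test on the 2x2 table
#' \code{(gene_mut, lib_mut - gene_mut; gene_wt, lib_wt - gene_wt)}. Counts
#' must already be normalized to the smallest library and rounded to
#' integers. Degenerate tables (a zero margin) return p = 1.
#'
#' @param mut_part,wt_part integer gene counts in mutant / wild type.
#' @param mut_lib,wt_lib integer normalized library sizes.
#' @return two-tailed p-value(s).
#' @export
fisher_de_test <- function(mut_part, wt_part, mut_lib, wt_lib) {
  n <- max(length(mut_part), length(wt_part))
  mut_part <- rep_len(mut_part, n); wt_part <- rep_len(wt_part, n)
  mut_lib <- rep_len(mut_lib, n); wt_lib <- rep_len(wt_lib, n)
  p <- rep(1, n)
  ok <- (mut_part + wt_part) > 0 & mut_lib > 0 & wt_lib > 0
  if (any(ok))
    p[ok] <- fisher_exact_test(mut_part[ok], mut_lib[ok] - mut_part[ok],
                               wt_part[ok], wt_lib[ok] - wt_part[ok])
  p
}

#' Two-threshold differential-expression call
#'
#' A gene is differentially expressed if for either ecotype it shows at
#' least a two-fold change (|log2FC| >= 1) with p < `p_single`, or if for
#' both ecotypes it shows at least a two-fold change in the same direction
#' with both p-values < `p_both`. Direction comes from the qualifying fold
#' changes; if both directions qualify simultaneously the call is `"none"`
#' (flagged by attribute `"contradictory"`).
#'
#' @param log2fc_ws,log2fc_col per-ecotype log2(mutant/WT); `NA` allowed.
#' @param p_ws,p_col per-ecotype two-tailed p-values; `NA` allowed.
#' @param fold fold-change threshold (2 = |log2FC| >= 1).
#' @param p_single,p_double p thresholds for the single- and both-ecotype
#'   rules.
#' @return one of `"up"`, `"down"`, `"none"`.
#' @export
call_de <- function(log2fc_ws, log2fc_col, p_ws, p_col, fold = 2,
                    p_single = 0.001, p_double = 0.005) {
  lf <- log2(fold)
  qual_single <- function(l, p) !is.na(l) && !is.na(p) && abs(l) >= lf &&
    p < p_single
  dirs <- character(0)
  if (qual_single(log2fc_ws, p_ws)) dirs <- c(dirs, sign_dir(log2fc_ws))
  if (qual_single(log2fc_col, p_col)) dirs <- c(dirs, sign_dir(log2fc_col))
  both <- !is.na(log2fc_ws) && !is.na(log2fc_col) &&
    !is.na(p_ws) && !is.na(p_col) &&
    abs(log2fc_ws) >= lf && abs(log2fc_col) >= lf &&
    p_ws < p_double && p_col < p_double &&
    sign(log2fc_ws) == sign(log2fc_col)
  if (both) dirs <- c(dirs, sign_dir(log2fc_ws))
  dirs <- unique(dirs)
  if (length(dirs) == 1) return(dirs)
  if (length(dirs) > 1) return(structure("none", contradictory = TRUE))
  "none"
}

sign_dir <- function(l) if (l > 0) "up" else "down"

# majority genotype over a gene's retained SNPs; ties favour Het, then WS
majority_genotype <- function(g) {
  tab <- table(factor(g, levels = c("Het", "WS", "Col")))
  names(tab)[which.max(tab)]
}

#' Run the allele-aware differential-expression procedure end to end
#'
#' Chains the stages: per-condition genotype calls at retained SNPs (each
#' condition pools its replicates' scaffold counts), contribution smoothing
#' within Het blocks, gene-to-SNP linkage (majority genotype of the gene's
#' retained exonic SNPs, or the nearest retained SNP within `search_radius`
#' for genes without one), RPKM-based log2 fold changes per ecotype with a
#' 0.5 RPKM pseudocount, smallest-library-normalized per-ecotype Fisher
#' tests, and the two-threshold call.
#'
#' The genotype structure (which regions are homozygous WS, homozygous Col,
#' or heterozygous) is called on counts pooled over all samples — both lines
#' descend from the same cross, and pooling makes the region calls robust at
#' moderate depth — while the read-count contributions that partition counts
#' in heterozygous regions are estimated per condition, so a genuine
#' difference between the lines surfaces as a contribution near 0 or 1
#' rather than as a noisy re-genotyping. The gene-to-SNP linkage is chosen
#' once and shared by the conditions.
#'
#' @param models a `gene_models` table (the genes to test).
#' @param snp_counts annotated SNP table with per-sample count columns
#'   `ws_reads_<sample>` / `col_reads_<sample>` for each sample name.
#' @param gene_counts integer matrix, genes x samples (rownames = gene ids).
#' @param condition character vector over samples, `"mut"` or `"wt"`.
#' @param window smoothing window (SNPs).
#' @param min_gene_len,min_reads,min_dist SNP filter parameters.
#' @param genotype_min_reads minimum per-condition depth for a genotype
#'   call at a SNP (each condition sees roughly half of a SNP's reads, so
#'   this defaults to half the retention threshold).
#' @param fold,p_single,p_double DE-call thresholds.
#' @param search_radius maximum gene-midpoint-to-SNP distance in bp.
#' @param pseudocount RPKM pseudocount for log2 fold changes.
#' @param library_sizes total mapped reads per sample (defaults to the
#'   column sums of `gene_counts`; supply the full library sizes when the
#'   count matrix covers only a subset of the transcriptome).
#' @return list with `results` (per-gene data.frame: partitioned normalized
#'   counts, per-ecotype RPKM, log2FC, p-values, and `call`), `snps` (the
#'   retained SNPs with per-condition genotypes and smoothed contributions),
#'   and `unpartitionable` (gene ids excluded for lack of a nearby SNP).
#' @export
run_ecotype_de <- function(models, snp_counts, gene_counts, condition,
                           window = 20L, min_gene_len = 200L,
                           min_reads = 10L, min_dist = 36L, fold = 2,
                           p_single = 0.001, p_double = 0.005,
                           search_radius = 50000L, pseudocount = 0.5,
                           genotype_min_reads = max(min_reads %/% 2L, 2L),
                           library_sizes = colSums(gene_counts)) {
  stopifnot(ncol(gene_counts) == length(condition),
            all(condition %in% c("mut", "wt")),
            identical(rownames(gene_counts), models$id))
  samples <- colnames(gene_counts)
  snps <- filter_snps(snp_counts, min_gene_len, min_reads, min_dist)
  if (nrow(snps) == 0) stop("no SNPs retained by the filters")
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]

  ws_all <- rowSums(snps[, grep("^ws_reads_", names(snps)), drop = FALSE])
  col_all <- rowSums(snps[, grep("^col_reads_", names(snps)), drop = FALSE])
  # regional genotype: each SNP is typed from its gene's pooled counts (all
  # retained exonic SNPs, all samples), which is far more robust at moderate
  # depth than a single-SNP call and keeps heterozygous runs intact
  gene_ws <- rowsum(ws_all, snps$gene_id)
  gene_col <- rowsum(col_all, snps$gene_id)
  gene_geno <- setNames(call_genotype(gene_ws[, 1], gene_col[, 1],
                                      min_reads = min_reads),
                        rownames(gene_ws))
  consensus <- unname(gene_geno[snps$gene_id])
  cond_tab <- list()
  for (cond in c("mut", "wt")) {
    sm <- samples[condition == cond]
    ws <- rowSums(snps[, paste0("ws_reads_", sm), drop = FALSE])
    co <- rowSums(snps[, paste0("col_reads_", sm), drop = FALSE])
    tab <- snps[c("chrom", "pos", "gene_id")]
    tab$ws <- ws; tab$col <- co
    tab$genotype <- consensus
    tab$contribution_ws <- ifelse(consensus == "Het" &
                                    (ws + co) >= genotype_min_reads,
                                  ws / (ws + co), NA_real_)
    cond_tab[[cond]] <- smooth_contributions(tab, window = window)
  }

  exon_len <- exon_model_length(models)
  libs <- library_sizes
  if (length(libs) != ncol(gene_counts) || any(libs < colSums(gene_counts)))
    stop("library_sizes must give one total >= its sample's gene counts")
  min_lib <- min(libs)
  rpkm_mat <- sapply(seq_along(samples), function(j)
    rpkm(gene_counts[, j], exon_len, libs[j]))
  norm_mat <- sweep(gene_counts, 2, min_lib / libs, "*")

  mid <- (models$start + models$end) / 2
  n <- nrow(models)
  res <- data.frame(gene_id = models$id, stringsAsFactors = FALSE)
  geno <- list(mut = rep(NA_character_, n), wt = rep(NA_character_, n))
  fs <- list(mut = rep(NA_real_, n), wt = rep(NA_real_, n))
  # linkage table, shared by the two conditions
  typed <- consensus != "untyped"
  link <- cond_tab$mut[typed, c("chrom", "pos", "gene_id", "genotype")]
  link$sm_mut <- cond_tab$mut$smoothed_contribution_ws[typed]
  link$sm_wt <- cond_tab$wt$smoothed_contribution_ws[typed]
  link$ws_all <- ws_all[typed]; link$col_all <- col_all[typed]
  for (i in seq_len(n)) {
    own <- link[!is.na(link$gene_id) & link$gene_id == models$id[i], ,
                drop = FALSE]
    g <- NA_character_
    if (nrow(own) > 0) {
      # region genotype from the gene's own retained SNPs, pooled counts
      g <- call_genotype(sum(own$ws_all), sum(own$col_all),
                         min_reads = min_reads)
      if (g == "untyped") g <- NA_character_
    } else {
      near <- link[link$chrom == models$chrom[i], , drop = FALSE]
      d <- abs(near$pos - mid[i])
      near <- near[d <= search_radius, , drop = FALSE]
      d <- d[d <= search_radius]
      if (nrow(near) > 0) g <- near$genotype[order(d, near$pos)[1]]
    }
    if (is.na(g)) next
    geno$mut[i] <- g; geno$wt[i] <- g
    if (g == "Het") {
      # nearest Het SNP with a smoothed contribution in both conditions
      hets <- link[link$genotype == "Het" & link$chrom == models$chrom[i] &
                     !is.na(link$sm_mut) & !is.na(link$sm_wt), ,
                   drop = FALSE]
      d <- abs(hets$pos - mid[i])
      hets <- hets[d <= search_radius, , drop = FALSE]
      d <- d[d <= search_radius]
      if (nrow(hets) > 0) {
        pick <- order(d, hets$pos)[1]
        fs$mut[i] <- hets$sm_mut[pick]
        fs$wt[i] <- hets$sm_wt[pick]
      } else {
        geno$mut[i] <- NA_character_; geno$wt[i] <- NA_character_
      }
    }
  }
  usable <- !is.na(geno$mut) & !is.na(geno$wt)
  unpart <- models$id[!usable]

  # per-condition RPKM means and their ecotype partitions; genes without a
  # usable genotype are filled with a placeholder here and masked below
  part_cond <- function(cond, values) {
    g <- ifelse(is.na(geno[[cond]]), "Col", geno[[cond]])
    partition_counts(values, g, fs[[cond]])
  }
  rpkm_mut <- rowMeans(rpkm_mat[, condition == "mut", drop = FALSE])
  rpkm_wt <- rowMeans(rpkm_mat[, condition == "wt", drop = FALSE])
  pm <- part_cond("mut", rpkm_mut); pw <- part_cond("wt", rpkm_wt)
  log2fc_ws <- log2((pm$ws + pseudocount) / (pw$ws + pseudocount))
  log2fc_col <- log2((pm$col + pseudocount) / (pw$col + pseudocount))

  # smallest-library-normalized summed counts, partitioned then rounded
  sum_mut <- rowSums(norm_mat[, condition == "mut", drop = FALSE])
  sum_wt <- rowSums(norm_mat[, condition == "wt", drop = FALSE])
  nm <- part_cond("mut", sum_mut); nw <- part_cond("wt", sum_wt)
  lib_mut <- round(sum(condition == "mut") * min_lib)
  lib_wt <- round(sum(condition == "wt") * min_lib)
  p_ws <- p_col <- rep(NA_real_, n)
  idx <- which(usable)
  p_ws[idx] <- fisher_de_test(round(nm$ws[idx]), round(nw$ws[idx]),
                              lib_mut, lib_wt)
  p_col[idx] <- fisher_de_test(round(nm$col[idx]), round(nw$col[idx]),
                               lib_mut, lib_wt)

  log2fc_ws[!usable] <- NA_real_; log2fc_col[!usable] <- NA_real_
  for (v in c("ws", "col")) {
    nm[[v]][!usable] <- NA_real_; nw[[v]][!usable] <- NA_real_
  }
  call <- rep("none", n)
  for (i in idx)
    call[i] <- call_de(log2fc_ws[i], log2fc_col[i], p_ws[i], p_col[i],
                       fold = fold, p_single = p_single, p_double = p_double)
  call[!usable] <- NA_character_

  res$genotype_mut <- geno$mut
  res$genotype_wt <- geno$wt
  res$rpkm_mut <- rpkm_mut; res$rpkm_wt <- rpkm_wt
  res$ws_mut <- nm$ws; res$col_mut <- nm$col
  res$ws_wt <- nw$ws; res$col_wt <- nw$col
  res$log2fc_ws <- log2fc_ws; res$log2fc_col <- log2fc_col
  res$p_ws <- p_ws; res$p_col <- p_col
  res$call <- call
  list(results = res, snps = cond_tab, unpartitionable = unpart,
       lib_mut = lib_mut, lib_wt = lib_wt)
}
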