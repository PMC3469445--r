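#' Simulation configuration with the pipeline's default study conditions
#'
#' Bundles every tunable of the synthetic-data generators with defaults
#' matching the conditions under which the pipeline's recovery properties are
#' stated: 20x bisulfite depth with a piecewise-linear genic CG profile
#' peaking at 0.40 mid-body; ChAP libraries at 30 midpoints/kb with three
#' clearly separated TSS-amplitude and body-level tiers; RNA-seq with three
#' replicates per genotype, a mean of 50 reads per gene, 36-bp reads, and a
#' WS/Col/Het block mosaic; responsiveness scores rank-correlated with body
#' enrichment at rho 0.33.
#'
#' @param seed integer seed fixing every downstream draw.
#' @param n_genes,n_tes,n_pseudogenes feature counts.
#' @param gene_len,te_len,pseudogene_len length ranges (bp); a single value
#'   gives constant lengths.
#' @param gap_len intergenic gap range (bp).
#' @param n_chrom number of chromosomes (features split evenly).
#' @param ... overrides for the nested design lists (`methylome`, `chap`,
#'   `rna`, `responsiveness`); see the vignette for every field.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 300L, n_tes = 60L,
                       n_pseudogenes = 20L, gene_len = c(3000L, 5000L),
                       te_len = c(800L, 3000L),
                       pseudogene_len = c(2500L, 4000L),
                       gap_len = c(600L, 2000L), n_chrom = 2L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_genes = n_genes, n_tes = n_tes, n_pseudogenes = n_pseudogenes,
    gene_len = gene_len, te_len = te_len, pseudogene_len = pseudogene_len,
    gap_len = gap_len, n_chrom = n_chrom,
    gene_exons = c(2L, 3L), gene_exon_frac = 0.2, min_exon_len = 200L,
    methylome = list(
      depth = 20,
      background = c(CG = 0.02, CHG = 0.01, CHH = 0.01),
      genic = c(CG = NA, CHG = 0.02, CHH = 0.02),  # CG follows the curve
      genic_cg_floor = 0.05, genic_cg_peak = 0.40,
      te = c(CG = 0.85, CHG = 0.65, CHH = 0.25),
      mutant_te_delta = c(CG = 0, CHG = -0.10, CHH = -0.10)),
    chap = list(
      rate = 0.03,                       # 30 midpoints/kb, input and IP base
      tss_extra = c(0, 0.10, 0.30),      # extra IP rate over [0,500) by tier
      tss_center = 250, tss_sd = 100,
      body_extra = c(0, 0.08, 0.24),     # extra IP rate over [500,L-500)
      read_len = 50L),
    rna = list(
      n_rep = 3L, read_len = 36L, mean_count = 50,
      count_shape = 4,                   # gamma shape of per-gene baselines
      dispersion_size = 100,             # NB size (1/dispersion)
      n_planted = 30L, planted_log2fc = 2,
      snps_per_exon = 3L, snp_margin = 45L, snp_spacing = 80L,
      block_genes = 8L,                  # genes per genotype block
      block_pattern = c("WS", "Het", "Col", "Het"),
      het_contributions = c(0.3, 0.5, 0.7),
      background_mult = 10),             # non-test-gene library mass
    responsiveness = list(
      target_rho = 0.33, shape = 1.2, rate = 0.5,
      hk_frac = 0.05, hv_frac = 0.05))
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && nm %in% names(cfg))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
    else cfg[[nm]] <- dots[[nm]]
  }
  class(cfg) <- "sim_config"
  cfg
}

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

rand_len <- function(n, range) {
  if (length(range) == 1) rep(as.integer(range), n)
  else as.integer(round(runif(n, range[1], range[2])))
}

#' Generate a random genome with non-overlapping annotated features
#'
#' Features (genes, transposons, pseudogenes) are shuffled, split across
#' chromosomes, and laid end to end with random intergenic gaps; strands are
#' random. Deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named `DNAStringSet`) and `models`
#'   (a `gene_models` table).
#' @export
generate_genome <- function(config) {
  with_seed(config$seed, {
    classes <- c(rep("gene", config$n_genes),
                 rep("transposon", config$n_tes),
                 rep("pseudogene", config$n_pseudogenes))
    n <- length(classes)
    lens <- integer(n)
    lens[classes == "gene"] <- rand_len(config$n_genes, config$gene_len)
    lens[classes == "transposon"] <- rand_len(config$n_tes, config$te_len)
    lens[classes == "pseudogene"] <-
      rand_len(config$n_pseudogenes, config$pseudogene_len)
    ord <- sample.int(n)
    classes <- classes[ord]; lens <- lens[ord]
    chrom_of <- rep(seq_len(config$n_chrom), length.out = n)
    counter <- c(gene = 0L, transposon = 0L, pseudogene = 0L)
    id <- character(n)
    for (i in seq_len(n)) {
      counter[classes[i]] <- counter[classes[i]] + 1L
      id[i] <- sprintf("%s%04d", c(gene = "AT_G", transposon = "AT_TE",
                                   pseudogene = "AT_PG")[classes[i]],
                       counter[classes[i]])
    }
    start <- integer(n); end <- integer(n); chrom <- character(n)
    seqs <- character(config$n_chrom)
    for (ch in seq_len(config$n_chrom)) {
      sel <- which(chrom_of == ch)
      pos <- 0L
      for (i in sel) {
        pos <- pos + as.integer(round(runif(1, config$gap_len[1],
                                            config$gap_len[2])))
        start[i] <- pos
        end[i] <- pos + lens[i]
        pos <- end[i]
        chrom[i] <- paste0("chr", ch)
      }
      clen <- pos + as.integer(round(runif(1, config$gap_len[1],
                                           config$gap_len[2])))
      if (!is.null(config$chrom_length)) {
        if (clen > config$chrom_length)
          stop("infeasible packing: features exceed the configured chromosome length")
        clen <- config$chrom_length
      }
      seqs[ch] <- paste(sample(c("A", "C", "G", "T"), clen, replace = TRUE),
                        collapse = "")
    }
    genome <- Biostrings::DNAStringSet(setNames(seqs,
                                                paste0("chr",
                                                       seq_len(config$n_chrom))))
    # genes get a multi-exon structure (exon union ~ gene_exon_frac of the
    # span, evenly interleaved with introns); TEs/pseudogenes are one exon
    exons <- vector("list", n)
    for (i in seq_len(n)) {
      if (classes[i] != "gene") {
        exons[[i]] <- cbind(start = start[i], end = end[i])
        next
      }
      L <- lens[i]
      k <- if (length(config$gene_exons) == 1) config$gene_exons else
        sample(config$gene_exons[1]:config$gene_exons[2], 1)
      ex_total <- max(k * config$min_exon_len,
                      as.integer(round(config$gene_exon_frac * L)))
      ex_len <- rep(ex_total %/% k, k)
      ex_len[1] <- ex_len[1] + ex_total %% k
      intron <- L - ex_total
      int_len <- if (k > 1) rep(intron %/% (k - 1), k - 1) else integer(0)
      if (k > 1) int_len[1] <- int_len[1] + intron %% (k - 1)
      s <- start[i] + c(0L, cumsum(ex_len[-k] + int_len))
      exons[[i]] <- cbind(start = as.integer(s),
                          end = as.integer(s + ex_len))
    }
    models <- if (n > 0)
      gene_models(id = id, chrom = chrom, start = start, end = end,
                  strand = sample(c("+", "-"), n, replace = TRUE),
                  feature_class = classes, exons = exons)
    else gene_models(character(0), character(0), integer(0), integer(0),
                     character(0))
    list(genome = genome, models = models)
  })
}

#' Designed genic CG methylation level at a transcription offset
#'
#' The generator's genic CG curve: piecewise linear from `floor` at the gene
#' ends to `peak` at mid-body. Exposed so recovery tests can compare a
#' measured metaplot bin against its design expectation.
#'
#' @param offset transcription-oriented offset(s) from the TSS, in bp.
#' @param gene_length gene length L in bp.
#' @param floor,peak edge and mid-body CG levels.
#' @return designed level(s); `NA` outside `[0, L)`.
#' @export
designed_genic_cg <- function(offset, gene_length, floor = 0.05, peak = 0.40) {
  rel <- offset / gene_length
  ifelse(rel < 0 | rel >= 1, NA_real_,
         floor + (peak - floor) * (1 - abs(2 * rel - 1)))
}

#' Simulate a per-cytosine bisulfite methylome
#'
#' Every cytosine of the genome (both strands) receives a true methylation
#' level from the design — a background level per context, the piecewise
#' linear genic CG curve ([designed_genic_cg()]), flat genic CHG/CHH levels,
#' and flat all-context TE levels — then a read depth drawn Poisson around
#' the nominal depth and a methylated count drawn Binomial(depth, level).
#' The mutant condition applies the designed TE deltas (global CHG/CHH TE
#' hypomethylation; genic levels unchanged) and any planted window deltas.
#' Sites with zero drawn depth are omitted (they carry no information).
#'
#' @param genome named `DNAStringSet`.
#' @param models a `gene_models` table.
#' @param config a [sim_config()]; the `methylome` design is used.
#' @param condition `"WT"` or `"mutant"`.
#' @param contexts which contexts to emit (all three by default).
#' @param planted_windows optional data.frame (chrom, start, end, delta,
#'   optional context) of windows whose true level is shifted by `delta` in
#'   the mutant.
#' @param seed seed for this draw; defaults to the config seed (offset by
#'   condition so WT and mutant are independent draws).
#' @return a `cytosine_calls` table.
#' @export
generate_methylome <- function(genome, models, config,
                               condition = c("WT", "mutant"),
                               contexts = c("CG", "CHG", "CHH"),
                               planted_windows = NULL, seed = NULL) {
  condition <- match.arg(condition)
  des <- config$methylome
  if (is.null(seed))
    seed <- config$seed + if (condition == "mutant") 1000L else 2000L
  with_seed(seed, {
    out <- vector("list", length(genome))
    for (ci in seq_along(genome)) {
      ch <- names(genome)[ci]
      chars <- strsplit(as.character(genome[[ci]]), "")[[1]]
      L <- length(chars)
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      site <- list()
      # plus-strand cytosines with two downstream bases
      p <- which(chars == "C"); p <- p[p <= L - 2]
      if (length(p)) {
        b2 <- chars[p + 1]; b3 <- chars[p + 2]
        ctx <- ifelse(b2 == "G", "CG", ifelse(b3 == "G", "CHG", "CHH"))
        site$plus <- data.frame(pos = p - 1L, strand = "+", context = ctx)
      }
      m <- which(chars == "G"); m <- m[m >= 3]
      if (length(m)) {
        b2 <- comp[chars[m - 1]]; b3 <- comp[chars[m - 2]]
        ctx <- ifelse(b2 == "G", "CG", ifelse(b3 == "G", "CHG", "CHH"))
        site$minus <- data.frame(pos = m - 1L, strand = "-", context = ctx)
      }
      sites <- do.call(rbind, site)
      if (is.null(sites) || nrow(sites) == 0) next
      sites <- sites[sites$context %in% contexts, , drop = FALSE]
      sites <- sites[order(sites$pos), , drop = FALSE]
      # true level per site: background, then feature overrides
      lvl <- unname(des$background[sites$context])
      feats <- models[models$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(feats))) {
        inside <- sites$pos >= feats$start[i] & sites$pos < feats$end[i]
        if (!any(inside)) next
        if (feats$feature_class[i] == "transposon") {
          te <- des$te[sites$context[inside]]
          if (condition == "mutant")
            te <- pmax(0, te + des$mutant_te_delta[sites$context[inside]])
          lvl[inside] <- unname(te)
        } else {
          # genes and pseudogenes share the genic design
          g_lvl <- unname(des$genic[sites$context[inside]])
          cg <- sites$context[inside] == "CG"
          if (any(cg)) {
            off <- tx_offset(feats$start[i], feats$end[i], feats$strand[i],
                             sites$pos[inside][cg], "five_prime")
            g_lvl[cg] <- designed_genic_cg(off, feats$end[i] - feats$start[i],
                                           des$genic_cg_floor,
                                           des$genic_cg_peak)
          }
          lvl[inside] <- g_lvl
        }
      }
      if (!is.null(planted_windows) && condition == "mutant") {
        pw <- planted_windows[planted_windows$chrom == ch, , drop = FALSE]
        for (i in seq_len(nrow(pw))) {
          hit <- sites$pos >= pw$start[i] & sites$pos < pw$end[i]
          if (!is.null(pw$context) && !is.na(pw$context[i]))
            hit <- hit & sites$context == pw$context[i]
          lvl[hit] <- pmin(1, pmax(0, lvl[hit] + pw$delta[i]))
        }
      }
      depth <- rpois(nrow(sites), des$depth)
      cc <- rbinom(nrow(sites), depth, lvl)
      keep <- depth > 0
      out[[ci]] <- data.frame(chrom = ch, pos = sites$pos[keep],
                              strand = sites$strand[keep],
                              context = sites$context[keep],
                              c = cc[keep], t = depth[keep] - cc[keep])
    }
    tab <- do.call(rbind, out)
    cytosine_calls(tab$chrom, tab$pos, tab$strand, tab$context, tab$c, tab$t)
  })
}

#' Simulate ChAP-seq IP and input read sets with designed enrichment tiers
#'
#' Input midpoints fall uniformly at the base rate; IP midpoints add, per
#' eligible gene (length >= 2100, not a pseudogene), a Gaussian TSS peak
#' whose amplitude is set by the gene's TSS tier and a body plateau over
#' \[500, L-500) set by its body tier. Genes are assigned to the nine
#' (TSS tier x body tier) classes in a balanced, seeded way; pseudogenes get
#' no extra signal. Midpoints become 50-bp reads on a random strand through
#' the inverse of the [estimate_midpoints()] rule, so midpoint estimation
#' recovers them exactly.
#'
#' @param genome named `DNAStringSet` (lengths only).
#' @param models a `gene_models` table.
#' @param config a [sim_config()]; the `chap` design is used.
#' @param seed seed; defaults to config seed + 3000.
#' @return list with `ip`, `input` (`read_intervals`) and `truth`
#'   (data.frame id, tss_tier, body_tier).
#' @export
generate_chap <- function(genome, models, config, seed = NULL) {
  des <- config$chap
  if (is.null(seed)) seed <- config$seed + 3000L
  lens <- chrom_lengths(genome)
  with_seed(seed, {
    eligible <- models$feature_class != "pseudogene" &
      (models$end - models$start) >= 2100L
    idx <- which(eligible)
    classes <- expand.grid(tss = 1:3, body = 1:3)
    assign <- classes[rep_len(sample.int(9), length(idx)), ]
    truth <- data.frame(id = models$id[idx], tss_tier = assign$tss,
                        body_tier = assign$body, stringsAsFactors = FALSE)
    mid_input <- list(); mid_ip <- list()
    for (ch in names(lens)) {
      Lc <- lens[[ch]]
      n_in <- rpois(1, Lc * des$rate)
      mid_input[[ch]] <- sort(sample.int(Lc, n_in, replace = TRUE) - 1L)
      mid_ip[[ch]] <- sample.int(Lc, rpois(1, Lc * des$rate),
                                 replace = TRUE) - 1L
    }
    for (k in seq_along(idx)) {
      i <- idx[k]
      L <- models$end[i] - models$start[i]
      tx_pos <- integer(0)
      amp <- des$tss_extra[truth$tss_tier[k]] * 500
      if (amp > 0) {
        n_pk <- rpois(1, amp)
        pk <- round(rnorm(n_pk, des$tss_center, des$tss_sd))
        tx_pos <- c(tx_pos, pk[pk >= 0 & pk < L])
      }
      body_rate <- des$body_extra[truth$body_tier[k]]
      if (body_rate > 0 && L > 1000) {
        n_b <- rpois(1, body_rate * (L - 1000))
        tx_pos <- c(tx_pos, 500L + sample.int(L - 1000L, n_b,
                                              replace = TRUE) - 1L)
      }
      if (length(tx_pos)) {
        g <- if (models$strand[i] == "+") models$start[i] + tx_pos else
          (models$end[i] - 1L) - tx_pos
        mid_ip[[models$chrom[i]]] <- c(mid_ip[[models$chrom[i]]], g)
      }
    }
    to_reads <- function(mids) {
      chrom <- rep(names(mids), lengths(mids))
      m <- unlist(mids, use.names = FALSE)
      strand <- sample(c("+", "-"), length(m), replace = TRUE)
      start <- ifelse(strand == "+", m - 75L, m + 76L - des$read_len)
      end <- start + des$read_len
      ok <- start >= 0 & end <= lens[chrom]
      read_intervals(chrom[ok], start[ok], end[ok], strand[ok])
    }
    list(ip = to_reads(mid_ip), input = to_reads(mid_input), truth = truth)
  })
}

#' Simulate allele-aware RNA-seq over a WS/Col mosaic
#'
#' Places diagnostic SNPs in gene exons (clear of exon ends and spaced so a
#' read covers at most one SNP), segments each chromosome into homozygous
#' WS, homozygous Col, and heterozygous blocks shared by both lines, draws
#' per-gene Negative-Binomial counts with planted log2 fold changes for a
#' random subset of genes, and emits 36-mer reads from each gene's transcript
#' carrying the block-appropriate allele (in Het blocks each read picks the
#' WS haplotype with the block's designed contribution). The reference
#' genome sequence carries the Col allele.
#'
#' @param genome named `DNAStringSet`.
#' @param models a `gene_models` table.
#' @param config a [sim_config()]; the `rna` design is used.
#' @param seed seed; defaults to config seed + 4000.
#' @return list with `snps` (chrom, pos, allele_ws, allele_col), `reads`
#'   (named list of per-sample character vectors), `gene_counts` (genes x
#'   samples integer matrix), `condition` (per-sample "mut"/"wt"),
#'   `library_sizes` (total mapped reads per sample, including background
#'   transcriptome mass outside the test genes), and `truth` (per-gene
#'   planted log2fc, block genotype, WS contribution).
#' @export
generate_rnaseq <- function(genome, models, config, seed = NULL) {
  des <- config$rna
  if (is.null(seed)) seed <- config$seed + 4000L
  genes <- models[models$feature_class == "gene", , drop = FALSE]
  with_seed(seed, {
    # --- SNPs ---
    snp_list <- list()
    for (i in seq_len(nrow(genes))) {
      ex <- genes$exons[[i]]
      for (j in seq_len(nrow(ex))) {
        lo <- ex[j, 1] + des$snp_margin
        hi <- ex[j, 2] - des$snp_margin
        if (hi <= lo) next
        cand <- seq(lo, hi - 1L, by = des$snp_spacing)
        take <- head(cand, des$snps_per_exon)
        if (length(take))
          snp_list[[length(snp_list) + 1L]] <-
            data.frame(chrom = genes$chrom[i], pos = as.integer(take))
      }
    }
    snps <- do.call(rbind, snp_list)
    snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
    ref <- character(nrow(snps))
    for (ch in unique(snps$chrom)) {
      sel <- snps$chrom == ch
      ref[sel] <- substring(as.character(genome[[ch]]), snps$pos[sel] + 1L,
                            snps$pos[sel] + 1L)
    }
    others <- c(A = "C", C = "G", G = "T", T = "A")
    snps$allele_col <- ref
    snps$allele_ws <- unname(others[ref])
    rownames(snps) <- NULL

    # --- genotype blocks (shared by both lines) ---
    ord <- order(genes$chrom, genes$start)
    n_g <- nrow(genes)
    block_of <- integer(n_g)
    block_of[ord] <- (seq_len(n_g) - 1L) %/% des$block_genes
    n_blocks <- max(block_of) + 1L
    block_geno <- rep_len(des$block_pattern, n_blocks)
    block_f <- rep(NA_real_, n_blocks)
    het_blocks <- which(block_geno == "Het")
    block_f[het_blocks] <- rep_len(des$het_contributions, length(het_blocks))
    gene_geno <- block_geno[block_of + 1L]
    gene_f <- block_f[block_of + 1L]

    # --- planted fold changes and per-gene baselines ---
    planted <- sample(seq_len(n_g), min(des$n_planted, n_g))
    log2fc <- rep(0, n_g)
    log2fc[planted] <- des$planted_log2fc
    base_mu <- rgamma(n_g, shape = des$count_shape,
                      rate = des$count_shape / des$mean_count)

    samples <- c(paste0("mut", seq_len(des$n_rep)),
                 paste0("wt", seq_len(des$n_rep)))
    condition <- rep(c("mut", "wt"), each = des$n_rep)
    counts <- matrix(0L, n_g, length(samples),
                     dimnames = list(genes$id, samples))
    for (j in seq_along(samples)) {
      mu <- if (condition[j] == "mut") base_mu * 2^log2fc else base_mu
      counts[, j] <- as.integer(rnbinom(n_g, mu = mu,
                                        size = des$dispersion_size))
    }

    # --- reads ---
    tx_seq <- character(n_g)
    tx_snp <- vector("list", n_g)   # per-gene SNP positions in tx coords
    for (i in seq_len(n_g)) {
      ex <- genes$exons[[i]]
      parts <- character(nrow(ex))
      seq_ch <- as.character(genome[[genes$chrom[i]]])
      for (j in seq_len(nrow(ex)))
        parts[j] <- substring(seq_ch, ex[j, 1] + 1L, ex[j, 2])
      s <- paste(parts, collapse = "")
      # exon-union coordinates of this gene's SNPs (plus-strand tx space)
      gsnp <- snps[snps$chrom == genes$chrom[i], , drop = FALSE]
      offs <- c(0L, cumsum(ex[, 2] - ex[, 1]))
      tpos <- integer(0); tws <- character(0)
      for (j in seq_len(nrow(ex))) {
        inj <- gsnp$pos >= ex[j, 1] & gsnp$pos < ex[j, 2]
        if (any(inj)) {
          tpos <- c(tpos, offs[j] + (gsnp$pos[inj] - ex[j, 1]))
          tws <- c(tws, gsnp$allele_ws[inj])
        }
      }
      tx_seq[i] <- s
      tx_snp[[i]] <- list(pos = tpos, ws = tws)
    }
    rl <- des$read_len
    reads <- vector("list", length(samples))
    names(reads) <- samples
    for (j in seq_along(samples)) {
      per_gene <- vector("list", n_g)
      for (i in seq_len(n_g)) {
        nread <- counts[i, j]
        tlen <- nchar(tx_seq[i])
        if (nread == 0 || tlen < rl) next
        starts <- sample.int(tlen - rl + 1L, nread, replace = TRUE) - 1L
        rs <- substring(tx_seq[i], starts + 1L, starts + rl)
        sp <- tx_snp[[i]]
        if (length(sp$pos)) {
          hap_ws <- if (gene_geno[i] == "WS") rep(TRUE, nread)
            else if (gene_geno[i] == "Col") rep(FALSE, nread)
            else runif(nread) < gene_f[i]
          if (any(hap_ws)) {
            for (k in seq_along(sp$pos)) {
              covered <- hap_ws & starts <= sp$pos[k] &
                starts > sp$pos[k] - rl
              if (any(covered)) {
                at <- sp$pos[k] - starts[covered] + 1L
                rs_cov <- rs[covered]
                rs[covered] <- paste0(substring(rs_cov, 1L, at - 1L),
                                      sp$ws[k],
                                      substring(rs_cov, at + 1L, rl))
              }
            }
          }
        }
        # transcript orientation vs genome: minus-strand genes transcribe the
        # reverse complement; reads are emitted in sequencing orientation
        # (random strand), so flip half of them
        if (genes$strand[i] == "-") rs <- revcomp_chr(rs)
        flip <- runif(nread) < 0.5
        if (any(flip)) rs[flip] <- revcomp_chr(rs[flip])
        per_gene[[i]] <- rs
      }
      reads[[j]] <- unlist(per_gene, use.names = FALSE)
    }
    truth <- data.frame(id = genes$id, planted_log2fc = log2fc,
                        genotype = gene_geno, contribution_ws = gene_f,
                        stringsAsFactors = FALSE)
    # library sizes include the rest of the transcriptome (reads not from
    # the simulated test genes), so a handful of strongly induced genes
    # cannot shift the totals the way they would in a genes-only library
    background <- rpois(length(samples),
                        des$background_mult * des$mean_count * n_g)
    library_sizes <- setNames(colSums(counts) + background, samples)
    list(snps = snps[c("chrom", "pos", "allele_ws", "allele_col")],
         reads = reads, gene_counts = counts, condition = condition,
         library_sizes = library_sizes, truth = truth)
  })
}

#' Simulate responsiveness scores correlated with body enrichment
#'
#' Draws per-gene responsiveness scores through a Gaussian copula so their
#' rank correlation with the supplied body-enrichment scores targets
#' `target_rho` (the copula's Pearson parameter is `2*sin(pi*rho/6)`); the
#' marginal is Gamma-distributed (non-negative, right-skewed, like published
#' responsiveness scores). Tissue/abiotic/biotic subscores are noisy shares
#' of the total. The lowest-scoring `hk_frac` of genes are labelled
#' housekeeping and the highest-scoring `hv_frac` hypervariable.
#'
#' @param ids gene identifiers.
#' @param body_scores per-gene body-enrichment scores (same length).
#' @param config a [sim_config()]; the `responsiveness` design is used.
#' @param seed seed; defaults to config seed + 5000.
#' @return data.frame: `gene_id`, `responsiveness_score`, `tissue`,
#'   `abiotic`, `biotic`, `label`.
#' @export
generate_responsiveness <- function(ids, body_scores, config, seed = NULL) {
  des <- config$responsiveness
  if (is.null(seed)) seed <- config$seed + 5000L
  if (abs(des$target_rho) > 1) stop("|target_rho| must be <= 1")
  n <- length(ids)
  with_seed(seed, {
    u1 <- (rank(body_scores, ties.method = "first") - 0.5) / n
    z1 <- qnorm(u1)
    r <- 2 * sin(pi * des$target_rho / 6)
    z2 <- if (abs(r) == 1) sign(r) * z1 else
      r * z1 + sqrt(1 - r^2) * rnorm(n)
    score <- qgamma(pnorm(z2), shape = des$shape, rate = des$rate)
    w <- matrix(rgamma(3 * n, shape = 2), ncol = 3)
    w <- w / rowSums(w)
    qlo <- quantile(score, des$hk_frac, type = 7)
    qhi <- quantile(score, 1 - des$hv_frac, type = 7)
    label <- ifelse(score <= qlo, "housekeeping",
                    ifelse(score >= qhi, "hypervariable", "none"))
    data.frame(gene_id = ids, responsiveness_score = score,
               tissue = score * w[, 1], abiotic = score * w[, 2],
               biotic = score * w[, 3], label = label,
               stringsAsFactors = FALSE)
  })
}

#' Write / read simulated reads as FASTQ
#'
#' Plain four-line FASTQ records with constant quality; sequence only is
#' meaningful for scaffold matching.
#'
#' @param reads character vector of read sequences.
#' @param path output file.
#' @return `path` invisibly; `read_fastq` returns the sequences.
#' @export
write_fastq <- function(reads, path) {
  if (length(reads) == 0) {
    file.create(path)
    return(invisible(path))
  }
  qual <- strrep("I", nchar(reads))
  out <- character(4L * length(reads))
  out[seq(1, length(out), 4)] <- paste0("@read", seq_along(reads))
  out[seq(2, length(out), 4)] <- reads
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- qual
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  unname(as.character(Biostrings::readDNAStringSet(path, format = "fastq")))
}
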