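#' Build and validate a pipeline run configuration
#'
#' Collects every stage parameter of the end-to-end pipeline with the
#' documented defaults (metaplot geometry 2 kb/5 kb at 100 bp for
#' methylation and 1 kb/3 kb at 50 bp for enrichment, 50-bp
#' differential-methylation windows with the 10\% filter, the 20-SNP
#' smoothing window, the 10-read and 36-bp SNP filters, two-fold /
#' p < 0.001 / p < 0.005 DE thresholds). Unknown keys are rejected.
#'
#' @param seed integer seed for the simulation stage.
#' @param out_dir output directory.
#' @param stages subset of `c("sim","meth","chap","de","stats")`, executed
#'   in dependency order.
#' @param sim a [sim_config()] (rebuilt from `seed` if omitted).
#' @param ... parameter overrides (see `run_config_defaults()` in the
#'   source for the full list).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("zedchrom_run_"),
                       stages = c("sim", "meth", "chap", "de", "stats"),
                       sim = NULL, ...) {
  defaults <- list(
    meth_upstream = 2000L, meth_into = 5000L, meth_bin = 100L,
    dmw_window = 50L, dmw_min_diff = 0.10,
    chap_upstream = 1000L, chap_into = 3000L, chap_bin = 50L,
    chap_exclusion = 1000L,
    de_window = 20L, de_min_reads = 10L, de_min_dist = 36L,
    de_fold = 2, de_p_single = 0.001, de_p_double = 0.005,
    scaffold_length = 75L, log_level = "info")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown configuration keys: %s",
                 paste(unknown, collapse = ", ")))
  params <- utils::modifyList(defaults, dots)
  bad <- !stages %in% c("sim", "meth", "chap", "de", "stats")
  if (any(bad)) stop("unknown stages: ", paste(stages[bad], collapse = ", "))
  cfg <- c(list(seed = as.integer(seed), out_dir = out_dir, stages = stages,
                sim = if (is.null(sim)) sim_config(seed = seed) else sim),
           params)
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Top-level keys `seed`, `out_dir`, `stages`, plus any stage parameter
#' accepted by [run_config()]; unknown keys are rejected.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  top <- c("seed", "out_dir", "stages")
  args <- y[setdiff(names(y), top)]
  do.call(run_config, c(y[intersect(top, names(y))], args))
}

#' Write a result table as TSV with `#` provenance header lines
#'
#' @param df data.frame.
#' @param path output file.
#' @param header character vector of comment lines (without the leading
#'   `#`).
#' @return `path` invisibly.
#' @export
write_result_tsv <- function(df, path, header = character(0)) {
  con <- file(path, "w")
  if (length(header)) writeLines(paste0("# ", header), con)
  close(con)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_result_tsv
#' @export
read_result_tsv <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
}

stage_cache_ok <- function(dir, stage, key, outputs) {
  f <- file.path(dir, sprintf(".stage_%s.json", stage))
  if (!file.exists(f)) return(FALSE)
  prev <- tryCatch(jsonlite::read_json(f, simplifyVector = TRUE),
                   error = function(e) NULL)
  identical(prev$key, key) && all(file.exists(file.path(dir, outputs)))
}

stage_cache_write <- function(dir, stage, key, outputs) {
  jsonlite::write_json(list(key = key, outputs = outputs),
                       file.path(dir, sprintf(".stage_%s.json", stage)),
                       auto_unbox = TRUE)
}

#' Run the full pipeline on simulated data
#'
#' Executes the requested stages in dependency order on one seeded synthetic
#' dataset: `sim` writes the genome (FASTA), annotation (BED), WT and mutant
#' methylomes (TSV), ChAP IP/input reads (BED), RNA-seq reads (FASTQ), SNP
#' table, gene counts and truth ledger; `meth` computes the genic CG
#' metaplot and differential-methylation windows; `chap` builds the
#' enrichment track (bedGraph), gene scores, and the nine-cluster partition;
#' `de` runs the allele-aware differential-expression chain from the FASTQ
#' reads; `stats` computes the body-enrichment/responsiveness Spearman
#' correlation and fold-change summaries. A stage whose inputs and
#' parameters are unchanged since the previous run (by checksum) is skipped.
#'
#' A `manifest.json` records the package version, seed, parameters, and the
#' MD5 checksum of every file written, so identical configurations produce
#' identical manifests.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `dir`, `manifest`, and `skipped` (stages
#'   served from cache).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir <- config$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stages <- intersect(c("sim", "meth", "chap", "de", "stats"), config$stages)
  skipped <- character(0)
  log_msg <- function(...) if (config$log_level != "quiet")
    message(sprintf(...))

  param_key <- function(...) {
    digest_input <- jsonlite::toJSON(list(...), auto_unbox = TRUE, digits = NA)
    as.character(digest_input)
  }
  file_key <- function(files) unname(md5sum(file.path(dir, files)))

  sim_out <- c("genome.fa", "annotation.bed", "meth_wt.tsv", "meth_mut.tsv",
               "chap_ip.bed", "chap_input.bed", "snps.tsv",
               "gene_counts.tsv", "library_sizes.tsv", "rna_truth.tsv",
               "chap_truth.tsv",
               "responsiveness.tsv",
               paste0("reads_",
                      c(paste0("mut", seq_len(config$sim$rna$n_rep)),
                        paste0("wt", seq_len(config$sim$rna$n_rep))),
                      ".fastq"))

  if ("sim" %in% stages) {
    key <- param_key(stage = "sim", seed = config$seed,
                     sim = config$sim[setdiff(names(config$sim), "seed")],
                     sim_seed = config$sim$seed)
    if (stage_cache_ok(dir, "sim", key, sim_out)) {
      log_msg("sim: cached, skipping")
      skipped <- c(skipped, "sim")
    } else {
      log_msg("sim: generating synthetic dataset (seed %d)", config$sim$seed)
      gen <- generate_genome(config$sim)
      Biostrings::writeXStringSet(gen$genome, file.path(dir, "genome.fa"))
      write_bed(gen$models, file.path(dir, "annotation.bed"))
      wt <- generate_methylome(gen$genome, gen$models, config$sim, "WT")
      mu <- generate_methylome(gen$genome, gen$models, config$sim, "mutant")
      write_cytosine_calls(wt, file.path(dir, "meth_wt.tsv"))
      write_cytosine_calls(mu, file.path(dir, "meth_mut.tsv"))
      chap <- generate_chap(gen$genome, gen$models, config$sim)
      write_reads_bed(chap$ip, file.path(dir, "chap_ip.bed"))
      write_reads_bed(chap$input, file.path(dir, "chap_input.bed"))
      write_result_tsv(chap$truth, file.path(dir, "chap_truth.tsv"))
      rna <- generate_rnaseq(gen$genome, gen$models, config$sim)
      write_snp_table(rna$snps, file.path(dir, "snps.tsv"))
      for (s in names(rna$reads))
        write_fastq(rna$reads[[s]],
                    file.path(dir, sprintf("reads_%s.fastq", s)))
      counts_df <- data.frame(gene_id = rownames(rna$gene_counts),
                              rna$gene_counts, check.names = FALSE)
      write_result_tsv(counts_df, file.path(dir, "gene_counts.tsv"))
      write_result_tsv(data.frame(sample = names(rna$library_sizes),
                                  library_reads = unname(rna$library_sizes)),
                       file.path(dir, "library_sizes.tsv"))
      write_result_tsv(rna$truth, file.path(dir, "rna_truth.tsv"))
      # responsiveness needs body scores: quick track from the chap reads
      lens <- chrom_lengths(gen$genome)
      track <- build_track(estimate_midpoints(chap$ip, lens),
                           estimate_midpoints(chap$input, lens))
      sc <- gene_scores(track, gen$models)
      ok <- !is.na(sc$body_score)
      resp <- generate_responsiveness(sc$id[ok], sc$body_score[ok],
                                      config$sim)
      write_result_tsv(resp, file.path(dir, "responsiveness.tsv"))
      stage_cache_write(dir, "sim", key, sim_out)
    }
  }

  models <- load_annotation(file.path(dir, "annotation.bed"))
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  names(genome) <- sub(" .*", "", names(genome))
  lens <- chrom_lengths(genome)

  if ("meth" %in% stages) {
    key <- param_key(stage = "meth", files = file_key(c("meth_wt.tsv",
                                                        "meth_mut.tsv",
                                                        "annotation.bed")),
                     up = config$meth_upstream, into = config$meth_into,
                     bin = config$meth_bin, w = config$dmw_window,
                     md = config$dmw_min_diff)
    outs <- c("metaplot_cg_genes.tsv", "dmw.tsv")
    if (stage_cache_ok(dir, "meth", key, outs)) {
      skipped <- c(skipped, "meth")
    } else {
      log_msg("meth: metaplots and differential-methylation windows")
      wt <- read_cytosine_calls(file.path(dir, "meth_wt.tsv"))
      mu <- read_cytosine_calls(file.path(dir, "meth_mut.tsv"))
      genes <- models[models$feature_class == "gene", ]
      mp <- ends_aligned_metaplot(wt, genes, "CG", "five_prime",
                                  config$meth_upstream, config$meth_into,
                                  config$meth_bin)
      write_result_tsv(mp, file.path(dir, "metaplot_cg_genes.tsv"),
                       "genic CG metaplot, WT, 5' anchor")
      tes <- models[models$feature_class == "transposon", ]
      dmw <- differential_methylation_windows(
        window_table(mu, config$dmw_window, "CG"),
        window_table(wt, config$dmw_window, "CG"),
        min_diff = config$dmw_min_diff, exclude = tes)
      write_result_tsv(dmw$windows, file.path(dir, "dmw.tsv"),
                       sprintf("CG differential methylation windows, min_diff=%g",
                               config$dmw_min_diff))
      stage_cache_write(dir, "meth", key, outs)
    }
  }

  if ("chap" %in% stages) {
    key <- param_key(stage = "chap",
                     files = file_key(c("chap_ip.bed", "chap_input.bed",
                                        "annotation.bed")),
                     up = config$chap_upstream, into = config$chap_into,
                     bin = config$chap_bin, ex = config$chap_exclusion)
    outs <- c("track.bedgraph", "gene_scores.tsv", "clusters.tsv",
              "enrichment_metaplot.tsv")
    if (stage_cache_ok(dir, "chap", key, outs)) {
      skipped <- c(skipped, "chap")
    } else {
      log_msg("chap: enrichment track, scores, nine-cluster partition")
      ip <- estimate_midpoints(read_reads_bed(file.path(dir, "chap_ip.bed")),
                               lens)
      input <- estimate_midpoints(
        read_reads_bed(file.path(dir, "chap_input.bed")), lens)
      track <- build_track(ip, input)
      write_bedgraph(track, file.path(dir, "track.bedgraph"))
      sc <- gene_scores(track, models)
      write_result_tsv(sc, file.path(dir, "gene_scores.tsv"))
      cl <- nine_cluster_partition(sc)
      write_result_tsv(cl, file.path(dir, "clusters.tsv"))
      mp <- enrichment_metaplot(track,
                                models[models$feature_class == "gene", ],
                                "five_prime", config$chap_upstream,
                                config$chap_into, config$chap_bin,
                                config$chap_exclusion)
      write_result_tsv(mp, file.path(dir, "enrichment_metaplot.tsv"))
      stage_cache_write(dir, "chap", key, outs)
    }
  }

  if ("de" %in% stages) {
    fq <- list.files(dir, pattern = "^reads_.*\\.fastq$")
    key <- param_key(stage = "de",
                     files = file_key(c(fq, "snps.tsv", "gene_counts.tsv",
                                        "library_sizes.tsv",
                                        "annotation.bed")),
                     w = config$de_window, mr = config$de_min_reads,
                     md = config$de_min_dist, f = config$de_fold,
                     p1 = config$de_p_single, p2 = config$de_p_double,
                     sl = config$scaffold_length)
    outs <- "de_results.tsv"
    if (stage_cache_ok(dir, "de", key, outs)) {
      skipped <- c(skipped, "de")
    } else {
      log_msg("de: allele-aware differential expression")
      snps <- read_snp_table(file.path(dir, "snps.tsv"))
      scaf <- build_scaffolds(genome, snps, config$scaffold_length)
      samples <- sub("^reads_(.*)\\.fastq$", "\\1", fq)
      for (s in samples) {
        counts <- assign_reads(read_fastq(file.path(dir,
                                                    sprintf("reads_%s.fastq", s))),
                               scaf)
        scaf[[paste0("ws_reads_", s)]] <- counts$ws_reads
        scaf[[paste0("col_reads_", s)]] <- counts$col_reads
      }
      genes <- models[models$feature_class == "gene", ]
      scaf <- annotate_snps(scaf, genes)
      counts_df <- read_result_tsv(file.path(dir, "gene_counts.tsv"))
      cm <- as.matrix(counts_df[, samples, drop = FALSE])
      rownames(cm) <- counts_df$gene_id
      cm <- cm[genes$id, , drop = FALSE]
      condition <- ifelse(grepl("^mut", samples), "mut", "wt")
      lib_df <- read_result_tsv(file.path(dir, "library_sizes.tsv"))
      libs <- setNames(lib_df$library_reads, lib_df$sample)[samples]
      de <- run_ecotype_de(genes, scaf, cm, condition,
                           library_sizes = libs,
                           window = config$de_window,
                           min_reads = config$de_min_reads,
                           min_dist = config$de_min_dist,
                           fold = config$de_fold,
                           p_single = config$de_p_single,
                           p_double = config$de_p_double)
      write_result_tsv(de$results, file.path(dir, "de_results.tsv"))
      stage_cache_write(dir, "de", key, outs)
    }
  }

  if ("stats" %in% stages) {
    key <- param_key(stage = "stats",
                     files = file_key(c("gene_scores.tsv",
                                        "responsiveness.tsv")))
    outs <- "assoc_stats.tsv"
    if (stage_cache_ok(dir, "stats", key, outs)) {
      skipped <- c(skipped, "stats")
    } else {
      log_msg("stats: association statistics")
      sc <- read_result_tsv(file.path(dir, "gene_scores.tsv"))
      resp <- read_result_tsv(file.path(dir, "responsiveness.tsv"))
      mrg <- merge(sc, resp, by.x = "id", by.y = "gene_id")
      mrg <- mrg[!is.na(mrg$body_score), ]
      sp <- spearman_perm(mrg$body_score, mrg$responsiveness_score,
                          n_perm = 1000L, seed = config$seed)
      stats_df <- data.frame(
        statistic = c("spearman_rho_body_responsiveness", "spearman_p", "n"),
        value = c(sp$rho, sp$p_value, nrow(mrg)))
      write_result_tsv(stats_df, file.path(dir, "assoc_stats.tsv"))
      stage_cache_write(dir, "stats", key, outs)
    }
  }

  all_files <- sort(setdiff(list.files(dir),
                            c("manifest.json",
                              list.files(dir, pattern = "^\\.stage_"))))
  manifest <- list(
    package = "zedchrom",
    version = as.character(utils::packageVersion("zedchrom")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("out_dir", "sim"))],
    sim = config$sim[setdiff(names(config$sim), character(0))],
    checksums = as.list(setNames(unname(md5sum(file.path(dir, all_files))),
                                 all_files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(dir = dir, manifest = manifest, skipped = skipped))
}
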