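#' Aligned-read interval table
#'
#' BED-like container for single-end aligned reads (0-based half-open).
#'
#' @param chrom,start,end,strand parallel vectors; `end > start`.
#' @return data.frame of class `read_intervals`.
#' @export
read_intervals <- function(chrom, start, end, strand) {
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) == 0) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0))
    class(out) <- c("read_intervals", "data.frame")
    return(out)
  }
  if (any(end <= start)) stop("read intervals must have end > start")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    strand = strand, stringsAsFactors = FALSE)
  class(out) <- c("read_intervals", "data.frame")
  out
}

#' Read / write read intervals as 6-column BED
#' @param path BED file (chrom, start, end, name, score, strand).
#' @return a `read_intervals` table.
#' @export
read_reads_bed <- function(path) {
  bed <- data.table::fread(path, header = FALSE, sep = "\t",
                           data.table = FALSE)
  if (ncol(bed) < 6) stop(sprintf("'%s' is not 6-column BED", path))
  read_intervals(bed[[1]], bed[[2]], bed[[3]], bed[[6]])
}

#' @rdname read_reads_bed
#' @param reads a `read_intervals` table.
#' @export
write_reads_bed <- function(reads, path) {
  df <- data.frame(reads$chrom, reads$start, reads$end, ".", 0L, reads$strand)
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Estimate nucleosome midpoints from single-end reads
#'
#' Each read's nucleosomal midpoint is estimated from an average 150-bp
#' nucleosome length by shifting 75 bp from the read's 5' end in the read's
#' orientation: `start + 75` for plus-strand reads, `end - 1 - 75` for
#' minus-strand reads. `literal_start = TRUE` reproduces the strand-naive
#' reading (`start + 75` for every read). Midpoints falling outside their
#' chromosome are dropped (and counted in `n_dropped`).
#'
#' @param reads a `read_intervals` table.
#' @param lens named chromosome lengths.
#' @param shift midpoint shift in bp (half the nucleosome length).
#' @param literal_start ignore strand when shifting.
#' @return object of class `midpoint_counts`: a list with `counts` (one
#'   integer vector per chromosome, one entry per base), `n_midpoints`, and
#'   `n_dropped`.
#' @export
estimate_midpoints <- function(reads, lens, shift = 75L,
                               literal_start = FALSE) {
  mid <- if (literal_start) reads$start + shift else
    ifelse(reads$strand == "+", reads$start + shift,
           reads$end - 1L - shift)
  L <- lens[reads$chrom]
  ok <- mid >= 0 & mid < L & !is.na(L)
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(sprintf("%d midpoints fell outside their chromosome and were dropped",
                    n_dropped))
  counts <- lapply(setNames(names(lens), names(lens)), function(ch) {
    sel <- ok & reads$chrom == ch
    tabulate(mid[sel] + 1L, nbins = lens[[ch]])
  })
  structure(list(counts = counts, n_midpoints = sum(ok),
                 n_dropped = n_dropped),
            class = "midpoint_counts")
}

#' Build an IP - input enrichment track
#'
#' Scales the per-base midpoint counts of each library to counts per million
#' midpoints (making unequal library sizes comparable) and subtracts
#' base-wise: track = IP(cpm) - input(cpm). The track is defined at every
#' base of every chromosome (zero where neither library has midpoints).
#'
#' @param ip_midpoints,input_midpoints `midpoint_counts` objects over the
#'   same chromosomes.
#' @return object of class `enrichment_track`: list with `signal` (one
#'   numeric vector per chromosome) and the two library sizes.
#' @export
build_track <- function(ip_midpoints, input_midpoints) {
  if (ip_midpoints$n_midpoints == 0 || input_midpoints$n_midpoints == 0)
    stop("both IP and input libraries must be non-empty")
  chroms <- names(ip_midpoints$counts)
  if (!identical(chroms, names(input_midpoints$counts)))
    stop("IP and input midpoints cover different chromosomes")
  ip_scale <- 1e6 / ip_midpoints$n_midpoints
  in_scale <- 1e6 / input_midpoints$n_midpoints
  signal <- lapply(setNames(chroms, chroms), function(ch)
    ip_midpoints$counts[[ch]] * ip_scale -
      input_midpoints$counts[[ch]] * in_scale)
  structure(list(signal = signal,
                 ip_library = ip_midpoints$n_midpoints,
                 input_library = input_midpoints$n_midpoints),
            class = "enrichment_track")
}

#' @export
print.enrichment_track <- function(x, ...) {
  cat(sprintf("enrichment_track: %d chromosomes, IP %d / input %d midpoints\n",
              length(x$signal), x$ip_library, x$input_library))
  invisible(x)
}

#' Export an enrichment track as bedGraph
#' @param track an `enrichment_track`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  blocks <- lapply(names(track$signal), function(ch) {
    v <- track$signal[[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, start = starts[keep], end = ends[keep],
               value = signif(r$values[keep], 8))
  })
  writeLines("track type=bedGraph", path)
  df <- do.call(rbind, blocks)
  if (!is.null(df))
    data.table::fwrite(df, path, sep = "\t", col.names = FALSE,
                       append = TRUE)
  invisible(path)
}

# per-gene per-bin (sum, count) of track values with opposite-end exclusion.
# A base at transcription-oriented plot offset o contributes only when its
# distance from the opposite end of the gene is at least `excl`:
#   five_prime anchor: o < L - excl   (bases at or past L - excl omitted)
#   three_prime anchor: o >= excl - L (bases within excl of the 5' end omitted)
gene_bin_stats <- function(track, chrom, start, end, strand, anchor,
                           upstream, into, bin, excl) {
  geom <- plot_bin(integer(0), anchor, upstream, into, bin)
  o <- seq.int(geom$lo, geom$lo + geom$n_bins * bin - 1L)
  L <- end - start
  valid <- if (anchor == "five_prime") o < L - excl else o >= excl - L
  g <- if (anchor == "five_prime") {
    if (strand == "+") start + o else (end - 1L) - o
  } else {
    if (strand == "+") end + o else (start - 1L) - o
  }
  sig <- track$signal[[chrom]]
  valid <- valid & g >= 0 & g < length(sig)
  idx <- (o - geom$lo) %/% bin + 1L
  vals <- numeric(length(o))
  vals[valid] <- sig[g[valid] + 1L]
  list(sums = tapply_sum(vals, idx, geom$n_bins),
       counts = tapply_sum(as.numeric(valid), idx, geom$n_bins),
       lo = geom$lo, n_bins = geom$n_bins)
}

#' Ends-aligned enrichment metaplot with opposite-end exclusion
#'
#' Average per-base enrichment in fixed bins over features aligned at one
#' end. To avoid averaging the 5' and 3' enrichment peaks of short genes into
#' the body signal, each gene omits bases within `opposite_end_exclusion` bp
#' of the end opposite the anchor. Bin values are means over all contributing
#' bases pooled across genes; bins with no contributing bases are `NA`.
#'
#' @param track an `enrichment_track`.
#' @param features a `gene_models` table.
#' @param anchor `"five_prime"` or `"three_prime"`.
#' @param upstream,into plot extent in bp.
#' @param bin bin width in bp.
#' @param opposite_end_exclusion bp excluded at the opposite end (>= 0).
#' @return data.frame with `offset`, `value`, `n_bases`.
#' @export
enrichment_metaplot <- function(track, features,
                                anchor = c("five_prime", "three_prime"),
                                upstream = 1000L, into = 3000L, bin = 50L,
                                opposite_end_exclusion = 1000L) {
  anchor <- match.arg(anchor)
  stopifnot(opposite_end_exclusion >= 0)
  geom <- plot_bin(integer(0), anchor, upstream, into, bin)
  sums <- numeric(geom$n_bins); counts <- numeric(geom$n_bins)
  for (i in seq_len(nrow(features))) {
    st <- gene_bin_stats(track, features$chrom[i], features$start[i],
                         features$end[i], features$strand[i], anchor,
                         upstream, into, bin, opposite_end_exclusion)
    sums <- sums + st$sums
    counts <- counts + st$counts
  }
  data.frame(offset = geom$lo + bin * (seq_len(geom$n_bins) - 1L),
             value = ifelse(counts > 0, sums / counts, NA_real_),
             n_bases = counts)
}

#' Per-gene TSS and gene-body enrichment scores
#'
#' Means of per-base enrichment over three transcription-oriented intervals:
#' `tss_score` over \[0, 500) bp from the TSS; `body_score` over
#' \[1000, L-1000) (defined only for genes of length L >= 2100 bp, so the
#' body window avoids the 5' and 3' peaks); `sort_body_score` over
#' \[500, L-500), used for heat-map row ordering.
#'
#' @param track an `enrichment_track`.
#' @param genes a `gene_models` table.
#' @param min_body_length minimum gene length for a defined `body_score`.
#' @return data.frame with `id`, `length`, `tss_score`, `body_score`,
#'   `sort_body_score`, `feature_class`.
#' @export
gene_scores <- function(track, genes, min_body_length = 2100L) {
  n <- nrow(genes)
  tss <- body <- sortb <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    sig <- track$signal[[genes$chrom[i]]]
    s <- genes$start[i]; e <- genes$end[i]; L <- e - s
    region_mean <- function(t0, t1) {
      # tx offsets [t0, t1) -> genomic interval (same for both strands except
      # the TSS window, handled through strand-aware mapping)
      if (t1 <= t0) return(NA_real_)
      g <- if (genes$strand[i] == "+") (s + t0):(s + t1 - 1L) else
        (e - t1):(e - t0 - 1L)
      g <- g[g >= 0 & g < length(sig)]
      if (length(g) == 0) return(NA_real_)
      mean(sig[g + 1L])
    }
    tss[i] <- region_mean(0L, min(500L, L))
    if (L >= min_body_length) body[i] <- region_mean(1000L, L - 1000L)
    if (L > 1000L) sortb[i] <- region_mean(500L, L - 500L)
  }
  data.frame(id = genes$id, length = genes$end - genes$start,
             tss_score = tss, body_score = body, sort_body_score = sortb,
             feature_class = genes$feature_class,
             stringsAsFactors = FALSE)
}

# stable tercile assignment: rank by (score, id); extras go to lower tiers
tercile_assign <- function(score, id) {
  n <- length(score)
  k <- n %/% 3L; r <- n %% 3L
  sizes <- rep(k, 3L) + c(r >= 1L, r >= 2L, 0L)
  ord <- order(score, id)
  tier <- integer(n)
  tier[ord] <- rep.int(1:3, sizes)
  tier
}

#' Nine-cluster partition of genes by TSS and body enrichment
#'
#' Genes with a defined body score are split into terciles (low/mid/high)
#' independently on the TSS score and on the body score (ties broken by gene
#' id order, so the partition is deterministic), giving nine approximately
#' equal-sized clusters. Pseudogenes, which carry very low enrichment, are
#' removed from the lowest-enrichment category and clustered together as
#' their own group (`"pG"`).
#'
#' @param scores output of [gene_scores()] (rows with `NA` body scores are
#'   ignored).
#' @param pseudogene_ids ids to set aside as the pseudogene group; defaults
#'   to rows with `feature_class == "pseudogene"`.
#' @return data.frame with `id`, `tss_tier`, `body_tier` (1 = low, 3 = high),
#'   and `cluster` ("1".."9", TSS tier major, or "pG").
#' @export
nine_cluster_partition <- function(scores, pseudogene_ids = NULL) {
  if (is.null(pseudogene_ids))
    pseudogene_ids <- scores$id[scores$feature_class == "pseudogene"]
  eligible <- scores[!is.na(scores$body_score), , drop = FALSE]
  is_pg <- eligible$id %in% pseudogene_ids
  pg <- eligible[is_pg, , drop = FALSE]
  el <- eligible[!is_pg, , drop = FALSE]
  if (nrow(el) < 9) stop("need at least 9 eligible genes to form 9 clusters")
  tss_tier <- tercile_assign(el$tss_score, el$id)
  body_tier <- tercile_assign(el$body_score, el$id)
  out <- data.frame(id = el$id, tss_tier = tss_tier, body_tier = body_tier,
                    cluster = as.character((tss_tier - 1L) * 3L + body_tier),
                    stringsAsFactors = FALSE)
  if (nrow(pg) > 0) {
    out <- rbind(out, data.frame(id = pg$id, tss_tier = NA_integer_,
                                 body_tier = NA_integer_, cluster = "pG"))
  }
  rownames(out) <- NULL
  out
}

#' Per-gene enrichment heat-map matrix
#'
#' One row per gene, columns the metaplot bins (per-gene means, no pooling
#' across genes), rows sorted from lowest to highest `sort_body_score`
#' (500 bp after the TSS to 500 bp before the 3' end). With `track2`, the
#' matrix holds the difference of the two tracks (track - track2), e.g. a
#' mutant-minus-WT comparison. Cells with no contributing bases are `NA`.
#'
#' @param track an `enrichment_track`.
#' @param features a `gene_models` table.
#' @param anchor,upstream,into,bin,opposite_end_exclusion as in
#'   [enrichment_metaplot()].
#' @param track2 optional second track for difference mode.
#' @param sort `"body_asc"` (the only implemented order) or `"none"`.
#' @return numeric matrix with gene-id row names and bin-offset column names.
#' @export
heatmap_matrix <- function(track, features,
                           anchor = c("five_prime", "three_prime"),
                           upstream = 1000L, into = 3000L, bin = 50L,
                           opposite_end_exclusion = 1000L, track2 = NULL,
                           sort = c("body_asc", "none")) {
  anchor <- match.arg(anchor)
  sort <- match.arg(sort)
  geom <- plot_bin(integer(0), anchor, upstream, into, bin)
  rows <- matrix(NA_real_, nrow(features), geom$n_bins,
                 dimnames = list(features$id,
                                 geom$lo + bin * (seq_len(geom$n_bins) - 1L)))
  for (i in seq_len(nrow(features))) {
    st <- gene_bin_stats(track, features$chrom[i], features$start[i],
                         features$end[i], features$strand[i], anchor,
                         upstream, into, bin, opposite_end_exclusion)
    vals <- ifelse(st$counts > 0, st$sums / st$counts, NA_real_)
    if (!is.null(track2)) {
      st2 <- gene_bin_stats(track2, features$chrom[i], features$start[i],
                            features$end[i], features$strand[i], anchor,
                            upstream, into, bin, opposite_end_exclusion)
      vals <- vals - ifelse(st2$counts > 0, st2$sums / st2$counts, NA_real_)
    }
    rows[i, ] <- vals
  }
  if (sort == "body_asc") {
    sb <- gene_scores(track, features)$sort_body_score
    rows <- rows[order(sb, features$id), , drop = FALSE]
  }
  rows
}
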