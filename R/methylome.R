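#' Per-cytosine methylation call table
#'
#' One row per cytosine: its position (0-based), strand, trinucleotide
#' context, and the methylated (`c`) and unmethylated (`t`) read counts from
#' bisulfite sequencing. Cytosines with `c + t = 0` carry no information and
#' contribute nothing to any aggregate.
#'
#' @param chrom,pos,strand,context,c,t parallel vectors; `context` in
#'   CG/CHG/CHH, counts non-negative integers.
#' @return a data.frame of class `cytosine_calls`, sorted by (chrom, pos).
#' @export
cytosine_calls <- function(chrom, pos, strand, context, c, t) {
  if (!all(context %in% c("CG", "CHG", "CHH")))
    stop("context must be CG, CHG or CHH")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  c <- as.integer(c); t <- as.integer(t)
  if (any(c < 0 | t < 0)) stop("counts must be non-negative")
  out <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                    strand = strand, context = context, c = c, t = t,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cytosine_calls", "data.frame")
  out
}

#' Read / write per-cytosine call tables
#'
#' TSV with columns chrom, pos, strand, context, count_methylated,
#' count_unmethylated; header lines beginning `#` are skipped. Positions are
#' 0-based by default; `one_based = TRUE` accepts 1-based input (e.g. a
#' CX-report-like dialect) and shifts on read.
#'
#' @param path TSV file.
#' @param one_based shift input positions down by one.
#' @return a `cytosine_calls` table.
#' @export
read_cytosine_calls <- function(path, one_based = FALSE) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("chrom", "pos", "strand", "context",
            "count_methylated", "count_unmethylated")
  if (!all(need %in% names(dt)))
    stop(sprintf("call table '%s' must have columns: %s", path,
                 paste(need, collapse = ", ")))
  pos <- dt$pos - if (one_based) 1L else 0L
  cytosine_calls(dt$chrom, pos, dt$strand, dt$context,
                 dt$count_methylated, dt$count_unmethylated)
}

#' @rdname read_cytosine_calls
#' @param calls a `cytosine_calls` table.
#' @export
write_cytosine_calls <- function(calls, path) {
  df <- data.frame(chrom = calls$chrom, pos = calls$pos, strand = calls$strand,
                   context = calls$context, count_methylated = calls$c,
                   count_unmethylated = calls$t)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Call the methylation context of a cytosine
#'
#' Reads the strand-appropriate trinucleotide starting at `pos` (the reverse
#' complement, read leftward, for the minus strand) and classifies it: CG if
#' the next base is G; CHG if the next base is H (A, T or C) and the one after
#' is G; CHH otherwise. Returns `"not_cytosine"` when the base at `pos` on
#' `strand` is not C. Vectorized over `pos`/`strand`.
#'
#' @param genome named `DNAStringSet` (or named character vector).
#' @param chrom chromosome name.
#' @param pos 0-based position(s).
#' @param strand `"+"` or `"-"`.
#' @return character vector in `c("CG","CHG","CHH","not_cytosine")`.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ACGTT"))
#' call_context(g, "chr1", 1, "+")  # "CG"
#' @export
call_context <- function(genome, chrom, pos, strand) {
  seq <- if (is.character(genome)) genome[[chrom]] else
    as.character(genome[[chrom]])
  L <- nchar(seq)
  n <- max(length(pos), length(strand))
  pos <- rep_len(as.integer(pos), n); strand <- rep_len(strand, n)
  if (any(pos < 0 | pos >= L)) stop("position outside chromosome")
  # need two downstream bases in read orientation
  if (any(strand == "+" & pos > L - 3) || any(strand == "-" & pos < 2))
    stop("context undeterminable: fewer than two downstream bases")
  base_at <- function(p) substring(seq, p + 1, p + 1)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  b1 <- character(n); b2 <- character(n); b3 <- character(n)
  plus <- strand == "+"
  if (any(plus)) {
    b1[plus] <- base_at(pos[plus]); b2[plus] <- base_at(pos[plus] + 1L)
    b3[plus] <- base_at(pos[plus] + 2L)
  }
  if (any(!plus)) {
    b1[!plus] <- comp[base_at(pos[!plus])]
    b2[!plus] <- comp[base_at(pos[!plus] - 1L)]
    b3[!plus] <- comp[base_at(pos[!plus] - 2L)]
  }
  if (any(b1 == "N" | b2 == "N" | b3 == "N"))
    stop("context undeterminable: N in trinucleotide")
  out <- rep("not_cytosine", n)
  isc <- b1 == "C"
  out[isc & b2 == "G"] <- "CG"
  out[isc & b2 != "G" & b3 == "G"] <- "CHG"
  out[isc & b2 != "G" & b3 != "G"] <- "CHH"
  out
}

#' Pooled (weighted) methylation level
#'
#' The weighted methylation level of a set of cytosine calls is
#' \eqn{\sum c / (\sum c + \sum t)} — pooled read counts, not a mean of
#' per-site fractions — making it robust to low-coverage sites. `NA` when
#' total coverage is zero.
#'
#' @param c,t methylated / unmethylated read counts (vectors).
#' @return a fraction in \eqn{[0,1]}, or `NA`.
#' @examples
#' weighted_level(c(3, 0), c(1, 4))  # 0.375
#' @export
weighted_level <- function(c, t) {
  tot <- sum(c) + sum(t)
  if (tot == 0) return(NA_real_)
  sum(c) / tot
}

# bin index and in-range mask for plot offsets. five_prime plots cover
# offsets [-upstream, into); three_prime plots cover [-into, upstream), so
# that "into the gene" is the same number of bins on both sides.
plot_bin <- function(offset, anchor, upstream, into, bin) {
  lo <- if (anchor == "five_prime") -upstream else -into
  hi <- if (anchor == "five_prime") into else upstream
  ok <- offset >= lo & offset < hi
  idx <- (offset - lo) %/% bin + 1L
  list(ok = ok, idx = idx, lo = lo, n_bins = (hi - lo) %/% bin)
}

#' Ends-aligned methylation metaplot
#'
#' Average methylation profile over a set of features aligned at a common
#' anchor. Every cytosine of the requested context contributes its pooled
#' (c, t) counts to the bin of its signed transcription-oriented offset, for
#' every feature whose plot window covers it (overlapping features each
#' contribute independently). Bin values are pooled weighted levels
#' \eqn{\sum c/(\sum c + \sum t)}; bins with zero coverage are `NA`.
#'
#' For the `five_prime` anchor, bins cover offsets
#' `[-upstream, into)`; for `three_prime`, `[-into, upstream)` (negative
#' numbers run into the gene body).
#'
#' @param calls a `cytosine_calls` table.
#' @param features a `gene_models` table (typically one feature class).
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param anchor `"five_prime"` or `"three_prime"`.
#' @param upstream,into plot extent in bp away from / into the feature.
#' @param bin bin width in bp.
#' @return data.frame with columns `offset` (bin left edge), `level`,
#'   `coverage` (pooled c+t).
#' @export
ends_aligned_metaplot <- function(calls, features, context,
                                  anchor = c("five_prime", "three_prime"),
                                  upstream = 2000L, into = 5000L, bin = 100L) {
  anchor <- match.arg(anchor)
  if (nrow(features) == 0) stop("features must be non-empty")
  calls <- calls[calls$context == context & (calls$c + calls$t) > 0, ,
                 drop = FALSE]
  geom <- plot_bin(integer(0), anchor, upstream, into, bin)
  csum <- numeric(geom$n_bins); tsum <- numeric(geom$n_bins)
  by_chrom <- split(calls, calls$chrom)
  for (i in seq_len(nrow(features))) {
    cc <- by_chrom[[features$chrom[i]]]
    if (is.null(cc) || nrow(cc) == 0) next
    off <- tx_offset(features$start[i], features$end[i], features$strand[i],
                     cc$pos, anchor)
    pb <- plot_bin(off, anchor, upstream, into, bin)
    if (!any(pb$ok)) next
    csum <- csum + unname(tapply_sum(cc$c[pb$ok], pb$idx[pb$ok], geom$n_bins))
    tsum <- tsum + unname(tapply_sum(cc$t[pb$ok], pb$idx[pb$ok], geom$n_bins))
  }
  cov <- csum + tsum
  data.frame(offset = geom$lo + bin * (seq_len(geom$n_bins) - 1L),
             level = ifelse(cov > 0, csum / cov, NA_real_),
             coverage = cov)
}

# sum x into n bins by integer index (dense tabulation)
tapply_sum <- function(x, idx, n) {
  out <- numeric(n)
  agg <- rowsum(as.numeric(x), idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Tile the genome into fixed windows and pool methylation counts
#'
#' Deterministic non-overlapping tiling starting at coordinate 0 of every
#' chromosome; each window pools the (c, t) counts of the calls it contains.
#'
#' @param calls a `cytosine_calls` table.
#' @param window window size in bp (50 by default).
#' @param context optional context filter.
#' @return data.frame keyed by (chrom, start) with pooled `c`, `t`, `level`,
#'   and `n_sites`.
#' @export
window_table <- function(calls, window = 50L, context = NULL) {
  if (!is.null(context)) calls <- calls[calls$context == context, , drop = FALSE]
  if (nrow(calls) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      context = character(), c = integer(), t = integer(),
                      n_sites = integer(), level = numeric()))
  dt <- data.table::as.data.table(unclass(calls)[c("chrom", "pos", "context",
                                                   "c", "t")])
  dt[, start := (pos %/% window) * as.integer(window)]
  out <- dt[, .(c = sum(c), t = sum(t), n_sites = .N),
            by = .(chrom, start, context)]
  out[, level := ifelse(c + t > 0, c / (c + t), NA_real_)]
  data.table::setorder(out, chrom, start, context)
  as.data.frame(out)
}

#' Differential-methylation windows between mutant and wild type
#'
#' Matches mutant and wild-type window tables by (chrom, start, context),
#' computes per-window pooled levels and their difference (mutant - WT), and
#' tests each window with the two-tailed Fisher exact test on the pooled 2x2
#' count table \code{(c_mut, t_mut; c_wt, t_wt)}. Replicates must be pooled by
#' summing counts before calling this function (see [pool_window_tables()]).
#'
#' Windows with an absolute difference below `min_diff` (10\% by default), or
#' overlapping any excluded feature (typically transposon annotations), are
#' absent from the output. Windows with zero coverage in either condition are
#' skipped and counted in the returned `n_skipped`.
#'
#' @param mut_windows,wt_windows window tables from [window_table()].
#' @param min_diff minimum absolute level difference to retain a window.
#' @param exclude optional `gene_models` table (or data.frame with
#'   chrom/start/end) of intervals whose overlapping windows are dropped.
#' @param p_breaks p-value bin edges for the significance-frequency histogram.
#' @return list with `windows` (retained windows with `diff`, `p_value`, and
#'   `direction` gain/loss), `histogram` (window counts per p-value bin and
#'   direction), and `n_skipped`.
#' @export
differential_methylation_windows <- function(mut_windows, wt_windows,
                                             min_diff = 0.10, exclude = NULL,
                                             p_breaks = 10^seq(-10, 0)) {
  m <- data.table::as.data.table(mut_windows)
  w <- data.table::as.data.table(wt_windows)
  merged <- merge(m, w, by = c("chrom", "start", "context"),
                  suffixes = c("_mut", "_wt"))
  merged <- as.data.frame(merged)
  if (nrow(merged) == 0)
    return(list(windows = merged, histogram = NULL, n_skipped = 0L))
  window <- infer_window_size(mut_windows, wt_windows)
  covered <- (merged$c_mut + merged$t_mut) > 0 & (merged$c_wt + merged$t_wt) > 0
  n_skipped <- sum(!covered)
  if (n_skipped > 0)
    message(sprintf("%d windows skipped for zero coverage in one condition",
                    n_skipped))
  merged <- merged[covered, , drop = FALSE]
  merged$level_mut <- merged$c_mut / (merged$c_mut + merged$t_mut)
  merged$level_wt <- merged$c_wt / (merged$c_wt + merged$t_wt)
  merged$diff <- merged$level_mut - merged$level_wt
  merged <- merged[abs(merged$diff) >= min_diff, , drop = FALSE]
  if (!is.null(exclude) && nrow(merged) > 0) {
    win_r <- GenomicRanges::GRanges(merged$chrom,
      IRanges::IRanges(merged$start + 1L, merged$start + window))
    ex_r <- GenomicRanges::GRanges(exclude$chrom,
      IRanges::IRanges(exclude$start + 1L, exclude$end))
    hit <- GenomicRanges::countOverlaps(win_r, ex_r) > 0
    merged <- merged[!hit, , drop = FALSE]
  }
  if (nrow(merged) > 0) {
    merged$p_value <- fisher_exact_test(merged$c_mut, merged$t_mut,
                                        merged$c_wt, merged$t_wt)
    merged$direction <- ifelse(merged$diff > 0, "gain", "loss")
  } else {
    merged$p_value <- numeric(0)
    merged$direction <- character(0)
  }
  hist <- if (nrow(merged) > 0) {
    bins <- cut(merged$p_value, breaks = p_breaks, include.lowest = TRUE)
    as.data.frame(table(p_bin = bins, direction = merged$direction))
  } else NULL
  rownames(merged) <- NULL
  list(windows = merged, histogram = hist, n_skipped = n_skipped)
}

infer_window_size <- function(...) {
  for (tab in list(...)) {
    s <- sort(unique(tab$start))
    if (length(s) > 1) return(min(diff(s)))
  }
  50L
}

#' Pool replicate window tables by summing counts
#'
#' @param ... window tables from [window_table()] for replicate datasets.
#' @return one pooled window table.
#' @export
pool_window_tables <- function(...) {
  dt <- data.table::rbindlist(lapply(list(...), data.table::as.data.table))
  out <- dt[, .(c = sum(c), t = sum(t), n_sites = sum(n_sites)),
            by = .(chrom, start, context)]
  out[, level := ifelse(c + t > 0, c / (c + t), NA_real_)]
  data.table::setorder(out, chrom, start, context)
  as.data.frame(out)
}

#' In-silico extraction of locus methylation
#'
#' Per-site and average percent methylation at a requested list of cytosine
#' sites within a locus, mirroring locus-specific bisulfite PCR: per-site
#' levels are c/(c+t) at exactly the requested sites; the locus average is the
#' pooled level across those sites. Sites with no coverage are reported as
#' `NA` and excluded from the pooled average's denominator.
#'
#' @param calls a `cytosine_calls` table.
#' @param locus list or data.frame row with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param site_list 0-based positions, all within the locus.
#' @return list with `per_site` (site, c, t, level, percent) and `average`
#'   (pooled fraction) / `average_percent`.
#' @export
extract_locus_methylation <- function(calls, locus, site_list) {
  if (length(site_list) == 0) stop("site_list must be non-empty")
  if (any(site_list < locus$start | site_list >= locus$end))
    stop("all sites must lie within the locus")
  sel <- calls[calls$chrom == locus$chrom & calls$pos %in% site_list, ,
               drop = FALSE]
  per_site <- data.frame(site = sort(unique(site_list)))
  agg <- rowsum(cbind(c = sel$c, t = sel$t), sel$pos)
  idx <- match(per_site$site, as.integer(rownames(agg)))
  per_site$c <- ifelse(is.na(idx), 0L, agg[idx, "c"])
  per_site$t <- ifelse(is.na(idx), 0L, agg[idx, "t"])
  tot <- per_site$c + per_site$t
  per_site$level <- ifelse(tot > 0, per_site$c / tot, NA_real_)
  per_site$percent <- 100 * per_site$level
  avg <- weighted_level(per_site$c, per_site$t)
  list(per_site = per_site, average = avg, average_percent = 100 * avg)
}
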