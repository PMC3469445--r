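#' Construct a table of gene models
#'
#' A gene model is a strand-aware genomic feature (gene, transposon, or
#' pseudogene) with an exon structure. All coordinates are 0-based half-open
#' (BED convention) throughout the package; GFF3 input is shifted on read.
#'
#' @param id character feature identifiers (unique).
#' @param chrom character chromosome names.
#' @param start,end integer 0-based half-open bounds, `start < end`.
#' @param strand `"+"` or `"-"`.
#' @param feature_class one of `"gene"`, `"transposon"`, `"pseudogene"`.
#' @param exons optional list of two-column matrices (start, end), 0-based
#'   half-open, sorted, non-overlapping, contained in `[start, end)`. Default:
#'   one exon spanning the whole model.
#' @return a `gene_models` data.frame with one row per feature and an `exons`
#'   list column.
#' @export
gene_models <- function(id, chrom, start, end, strand,
                        feature_class = "gene", exons = NULL) {
  n <- length(id)
  start <- as.integer(start); end <- as.integer(end)
  strand <- rep_len(strand, n); feature_class <- rep_len(feature_class, n)
  if (anyDuplicated(id)) stop("gene model ids must be unique")
  if (any(start >= end)) stop("gene model start must be < end")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!all(feature_class %in% c("gene", "transposon", "pseudogene")))
    stop("feature_class must be gene, transposon or pseudogene")
  if (is.null(exons)) {
    exons <- lapply(seq_len(n), function(i)
      cbind(start = start[i], end = end[i]))
  }
  for (i in seq_len(n)) {
    ex <- exons[[i]]
    if (!is.matrix(ex) || ncol(ex) != 2 || nrow(ex) < 1)
      stop("exons must be non-empty two-column matrices")
    if (any(ex[, 1] >= ex[, 2]))
      stop(sprintf("model '%s': exon start must be < end", id[i]))
    if (any(ex[, 1] < start[i]) || any(ex[, 2] > end[i]))
      stop(sprintf("model '%s': exon outside gene bounds", id[i]))
    if (nrow(ex) > 1) {
      if (is.unsorted(ex[, 1], strictly = TRUE) ||
          any(ex[-1, 1] < ex[-nrow(ex), 2]))
        stop(sprintf("model '%s': exons must be sorted and non-overlapping",
                     id[i]))
    }
  }
  out <- data.frame(id = as.character(id), chrom = as.character(chrom),
                    start = start, end = end, strand = strand,
                    feature_class = feature_class,
                    stringsAsFactors = FALSE)
  out$exons <- exons
  class(out) <- c("gene_models", "data.frame")
  out
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d features (%s)\n", nrow(x),
              paste(sprintf("%d %s", table(x$feature_class),
                            names(table(x$feature_class))), collapse = ", ")))
  print.data.frame(head(as.data.frame(x[, setdiff(names(x), "exons")]), 10))
  invisible(x)
}

#' Total exon length of each model, in bp
#' @param models a `gene_models` table.
#' @return integer vector of summed exon lengths.
#' @export
exon_model_length <- function(models) {
  vapply(models$exons, function(ex) sum(ex[, 2] - ex[, 1]), numeric(1))
}

# light structural pre-validation so parse errors can name the offending line
validate_annotation_lines <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (format == "gff3") {
      ok <- length(f) == 9 && !is.na(suppressWarnings(as.integer(f[4]))) &&
        !is.na(suppressWarnings(as.integer(f[5])))
    } else {
      ok <- length(f) >= 6 && !is.na(suppressWarnings(as.integer(f[2]))) &&
        !is.na(suppressWarnings(as.integer(f[3])))
    }
    if (!ok) stop(sprintf("malformed %s line %d in '%s'", format, i, path))
  }
  invisible(TRUE)
}

#' Load gene models from a GFF3 or BED file
#'
#' GFF3 coordinates (1-based closed) are converted to the package's 0-based
#' half-open convention; BED is read as-is. For GFF3, rows whose `type` occurs
#' in `feature_class_map` become models, and child rows of type `exon` (linked
#' by `Parent`) supply the exon structure; features without annotated exons
#' get a single exon spanning the model. For BED, the feature class is taken
#' from `feature_class_map` applied to an optional 7th column, defaulting to
#' `"gene"`.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED file.
#' @param feature_class_map named character vector mapping source feature
#'   types to `gene`/`transposon`/`pseudogene`.
#' @return a `gene_models` table.
#' @export
load_annotation <- function(path,
                            feature_class_map = c(
                              gene = "gene",
                              transposable_element = "transposon",
                              transposable_element_gene = "transposon",
                              transposon = "transposon",
                              pseudogene = "pseudogene")) {
  if (!file.exists(path)) stop(sprintf("annotation file '%s' not found", path))
  fmt <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "bed"
  validate_annotation_lines(path, fmt)
  if (fmt == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    keep <- as.character(gr$type) %in% names(feature_class_map)
    feats <- gr[keep]
    if (length(feats) == 0) stop("no features of a mapped type in annotation")
    fid <- if (!is.null(feats$ID)) as.character(feats$ID) else
      paste0("feature", seq_along(feats))
    ex_rows <- gr[as.character(gr$type) == "exon"]
    exons <- vector("list", length(feats))
    if (length(ex_rows) > 0 && !is.null(ex_rows$Parent)) {
      parent <- vapply(ex_rows$Parent, function(p)
        if (length(p)) as.character(p[1]) else NA_character_, character(1))
      for (i in seq_along(feats)) {
        sel <- which(parent == fid[i])
        if (length(sel)) {
          ex <- cbind(start = GenomicRanges::start(ex_rows)[sel] - 1L,
                      end = GenomicRanges::end(ex_rows)[sel])
          ex <- ex[order(ex[, 1]), , drop = FALSE]
          exons[[i]] <- ex
        }
      }
    }
    no_ex <- vapply(exons, is.null, logical(1))
    st <- GenomicRanges::start(feats) - 1L
    en <- GenomicRanges::end(feats)
    exons[no_ex] <- lapply(which(no_ex), function(i)
      cbind(start = st[i], end = en[i]))
    gene_models(id = fid, chrom = as.character(GenomicRanges::seqnames(feats)),
                start = st, end = en,
                strand = as.character(GenomicRanges::strand(feats)),
                feature_class = unname(feature_class_map[as.character(feats$type)]),
                exons = exons)
  } else {
    bed <- data.table::fread(path, header = FALSE, sep = "\t",
                             data.table = FALSE)
    cls <- if (ncol(bed) >= 7) {
      mapped <- feature_class_map[as.character(bed[[7]])]
      ifelse(is.na(mapped), "gene", unname(mapped))
    } else "gene"
    gene_models(id = as.character(bed[[4]]), chrom = as.character(bed[[1]]),
                start = bed[[2]], end = bed[[3]], strand = as.character(bed[[6]]),
                feature_class = cls)
  }
}

#' Write gene models as 6-column BED (plus feature class in column 7)
#'
#' Re-loading the written file with [load_annotation()] reproduces the
#' coordinates exactly (exon structure collapses to the model span).
#'
#' @param models a `gene_models` table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(models, path) {
  df <- data.frame(models$chrom, models$start, models$end, models$id,
                   0L, models$strand, models$feature_class)
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

# vectorized signed offset; offset 0 is the first base at the anchor in
# transcription orientation (five_prime: first transcribed base; three_prime:
# first base past the gene). Upstream of the anchor is strictly negative.
tx_offset <- function(start, end, strand, pos, anchor) {
  n <- max(length(start), length(pos))
  start <- rep_len(start, n); end <- rep_len(end, n)
  strand <- rep_len(strand, n); pos <- rep_len(pos, n)
  if (anchor == "five_prime") {
    ifelse(strand == "+", pos - start, (end - 1L) - pos)
  } else {
    ifelse(strand == "+", pos - end, (start - 1L) - pos)
  }
}

#' Signed transcription-oriented offset of a genomic position
#'
#' Offset of `pos` from a gene-model anchor, measured in the direction of
#' transcription. For the `five_prime` anchor, offset 0 is the first
#' transcribed base and upstream positions are strictly negative; for the
#' `three_prime` anchor, offset 0 is the first base past the gene (the last
#' transcribed base has offset -1). On the minus strand offsets increase
#' toward lower genomic coordinates.
#'
#' @param model a single-row `gene_models` table (or any list with `start`,
#'   `end`, `strand`).
#' @param pos genomic position(s), 0-based.
#' @param anchor `"five_prime"` or `"three_prime"`.
#' @return integer vector of signed offsets.
#' @examples
#' m <- gene_models("g1", "chr1", 2000, 9000, "+")
#' genic_position(m[1, ], 2050)  # +50
#' @export
genic_position <- function(model, pos, anchor = c("five_prime", "three_prime")) {
  anchor <- match.arg(anchor)
  as.integer(tx_offset(model$start[1], model$end[1], model$strand[1],
                       pos, anchor))
}

#' Chromosome lengths of a genome
#' @param genome a named `DNAStringSet` (or named character vector).
#' @return named integer vector of lengths.
#' @export
chrom_lengths <- function(genome) {
  if (is.character(genome)) return(setNames(nchar(genome), names(genome)))
  setNames(Biostrings::width(genome), names(genome))
}

#' Mirror-reverse a genome and its companion objects
#'
#' Utilities for strand-symmetry validation: `mirror_genome()`
#' reverse-complements every chromosome; the companions flip coordinates
#' (`pos' = L - 1 - pos`, intervals `[s,e) -> [L-e, L-s)`) and strands so that
#' a mirrored fixture is the exact biological mirror image of the original.
#' Metaplots and enrichment profiles are invariant under this transformation.
#'
#' @param genome named `DNAStringSet`.
#' @return `mirror_genome`: the reverse-complemented genome.
#' @export
mirror_genome <- function(genome) {
  Biostrings::reverseComplement(genome)
}

#' @rdname mirror_genome
#' @param models a `gene_models` table.
#' @param lens named chromosome lengths (see [chrom_lengths()]).
#' @return `mirror_features`: the coordinate-flipped, strand-flipped models.
#' @export
mirror_features <- function(models, lens) {
  L <- lens[models$chrom]
  exons <- lapply(seq_len(nrow(models)), function(i) {
    ex <- models$exons[[i]]
    li <- lens[[models$chrom[i]]]
    flipped <- cbind(start = li - ex[, 2], end = li - ex[, 1])
    flipped[order(flipped[, 1]), , drop = FALSE]
  })
  gene_models(id = models$id, chrom = models$chrom,
              start = L - models$end, end = L - models$start,
              strand = ifelse(models$strand == "+", "-", "+"),
              feature_class = models$feature_class, exons = exons)
}

#' @rdname mirror_genome
#' @param calls a cytosine-call table (see [cytosine_calls()]).
#' @return `mirror_calls`: the flipped call table (contexts are preserved by
#'   reverse complementation).
#' @export
mirror_calls <- function(calls, lens) {
  out <- calls
  out$pos <- lens[calls$chrom] - 1L - calls$pos
  out$strand <- ifelse(calls$strand == "+", "-", "+")
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' @rdname mirror_genome
#' @param reads a read-interval table (see [read_intervals()]).
#' @return `mirror_reads`: the flipped read intervals.
#' @export
mirror_reads <- function(reads, lens) {
  L <- lens[reads$chrom]
  out <- reads
  out$start <- as.integer(L - reads$end)
  out$end <- as.integer(L - reads$start)
  out$strand <- ifelse(reads$strand == "+", "-", "+")
  out
}
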