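#' Construct a gene model
#'
#' A gene model is one transcript isoform of a gene: its exon structure in
#' genomic coordinates plus the CDS location in transcript coordinates. All
#' coordinates are 0-based half-open; transcript coordinates run 5' to 3'
#' (so on the minus strand, transcript position 0 is the rightmost exonic
#' genomic base). A noncoding transcript carries an empty CDS
#' (`cds_start_tx == cds_end_tx`).
#'
#' @param gene_id,transcript_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix or data.frame of genomic `start`,`end`
#'   intervals (0-based half-open). Must be non-overlapping; they are sorted
#'   by start on construction.
#' @param cds_start_tx,cds_end_tx CDS bounds in transcript coordinates
#'   (0-based half-open). Both 0 (the default) for a noncoding transcript.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, transcript_id, chrom, strand, exons,
                       cds_start_tx = 0L, cds_end_tx = 0L) {
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L]))
    stop("exon intervals must have end > start")
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("exons overlap in gene model for ", transcript_id)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  len <- sum(exons[, 2L] - exons[, 1L])
  cds_start_tx <- as.integer(cds_start_tx)
  cds_end_tx <- as.integer(cds_end_tx)
  if (cds_start_tx < 0L || cds_end_tx < cds_start_tx || cds_end_tx > len)
    stop("CDS bounds out of range for ", transcript_id)
  structure(
    list(gene_id = gene_id, transcript_id = transcript_id, chrom = chrom,
         strand = strand, exons = exons, cds_start_tx = cds_start_tx,
         cds_end_tx = cds_end_tx, transcript_length = len),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s) %s:%s %d exon(s), %d nt, CDS [%d,%d)\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), x$transcript_length,
              x$cds_start_tx, x$cds_end_tx))
  invisible(x)
}

is_coding <- function(model) model$cds_end_tx > model$cds_start_tx

#' Segment lengths of a gene model
#'
#' @param model A [gene_model()].
#' @return Named integer vector with elements `utr5`, `cds`, `utr3`;
#'   all `NA` for a noncoding model.
#' @export
tx_segments <- function(model) {
  if (!is_coding(model)) return(c(utr5 = NA_integer_, cds = NA_integer_,
                                  utr3 = NA_integer_))
  c(utr5 = model$cds_start_tx,
    cds = model$cds_end_tx - model$cds_start_tx,
    utr3 = model$transcript_length - model$cds_end_tx)
}

#' Region of a transcript position
#'
#' @param model A [gene_model()].
#' @param tpos Transcript positions (0-based).
#' @return Character vector: `"5'UTR"`, `"CDS"`, `"3'UTR"` for coding
#'   models, `"noncoding"` otherwise.
#' @export
region_of_tpos <- function(model, tpos) {
  if (any(tpos < 0L | tpos >= model$transcript_length))
    stop("transcript position out of range")
  if (!is_coding(model)) return(rep("noncoding", length(tpos)))
  ifelse(tpos < model$cds_start_tx, "5'UTR",
         ifelse(tpos < model$cds_end_tx, "CDS", "3'UTR"))
}

#' Project genomic positions onto transcript coordinates
#'
#' Intronic or intergenic positions map to `NA`. Minus-strand transcripts
#' count from the genomic right end, so the 5' end of the transcript is the
#' rightmost exonic base.
#'
#' @param model A [gene_model()].
#' @param gpos Genomic positions (0-based), vectorised.
#' @return Integer vector of transcript positions, `NA` where non-exonic.
#' @export
genome_to_transcript <- function(model, gpos) {
  ex <- model$exons
  widths <- ex[, 2L] - ex[, 1L]
  before <- cumsum(c(0L, widths[-length(widths)]))
  idx <- findInterval(gpos, ex[, 1L])
  inside <- idx >= 1L & gpos < ex[pmax(idx, 1L), 2L]
  plus_off <- rep(NA_integer_, length(gpos))
  ok <- which(inside)
  plus_off[ok] <- before[idx[ok]] + (gpos[ok] - ex[idx[ok], 1L])
  if (model$strand == "+") plus_off
  else ifelse(is.na(plus_off), NA_integer_,
              model$transcript_length - 1L - plus_off)
}

#' Project transcript positions onto genomic coordinates
#'
#' Inverse of [genome_to_transcript()]: the round trip is the identity on
#' every exonic position.
#'
#' @param model A [gene_model()].
#' @param tpos Transcript positions (0-based), vectorised.
#' @return Integer vector of genomic positions.
#' @export
transcript_to_genome <- function(model, tpos) {
  if (any(tpos < 0L | tpos >= model$transcript_length))
    stop("transcript position out of range [0, ", model$transcript_length, ")")
  ex <- model$exons
  widths <- ex[, 2L] - ex[, 1L]
  ends <- cumsum(widths)
  plus_off <- if (model$strand == "+") as.integer(tpos)
              else model$transcript_length - 1L - as.integer(tpos)
  idx <- findInterval(plus_off, c(0L, ends[-length(ends)]))
  unname(ex[idx, 1L] + (plus_off - c(0L, ends)[idx]))
}

#' Project a transcript interval onto genomic blocks
#'
#' Splits a transcript-coordinate interval at exon junctions, yielding the
#' contiguous genomic blocks it covers (sorted by genomic start).
#'
#' @param model A [gene_model()].
#' @param start,end Transcript interval (0-based half-open).
#' @return data.frame with columns `start`, `end` (genomic, 0-based
#'   half-open).
#' @export
project_interval <- function(model, start, end) {
  stopifnot(end > start)
  g <- transcript_to_genome(model, start:(end - 1L))
  g <- sort(g)
  brk <- c(0L, which(diff(g) != 1L), length(g))
  data.frame(start = g[brk[-length(brk)] + 1L], end = g[brk[-1L]] + 1L)
}

#' Select the longest isoform of each gene
#'
#' Length is measured as summed exon length (not genomic span); equal-length
#' ties are broken by the lexicographically smallest transcript id. Genes
#' without exon features are skipped with a warning.
#'
#' @param gtf A `GRanges` of GTF records (e.g. from `rtracklayer::import`)
#'   with metadata columns `type`, `gene_id`, `transcript_id`, or a
#'   data.frame with columns `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `type`, `gene_id`, `transcript_id`.
#' @return Named list of [gene_model()] objects, one per gene, keyed by
#'   `gene_id`.
#' @export
select_longest_isoform <- function(gtf) {
  df <- gtf_to_df(gtf)
  feat <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  out <- list()
  skipped <- character()
  for (gid in unique(feat$gene_id)) {
    g <- feat[feat$gene_id == gid, , drop = FALSE]
    txs <- unique(g$transcript_id[g$type == "exon"])
    if (length(txs) == 0L) { skipped <- c(skipped, gid); next }
    lens <- vapply(txs, function(tx) {
      e <- g[g$transcript_id == tx & g$type == "exon", ]
      sum(e$end - e$start)
    }, numeric(1))
    best <- txs[order(-lens, txs)][1L]
    e <- g[g$transcript_id == best & g$type == "exon", ]
    cds <- g[g$transcript_id == best & g$type == "CDS", ]
    model <- gene_model(gid, best, e$chrom[1L], e$strand[1L],
                        cbind(e$start, e$end))
    if (nrow(cds) > 0L) {
      gmin <- min(cds$start); gmax <- max(cds$end)
      if (model$strand == "+") {
        model$cds_start_tx <- genome_to_transcript(model, gmin)
        model$cds_end_tx <- genome_to_transcript(model, gmax - 1L) + 1L
      } else {
        model$cds_start_tx <- genome_to_transcript(model, gmax - 1L)
        model$cds_end_tx <- genome_to_transcript(model, gmin) + 1L
      }
    }
    out[[gid]] <- model
  }
  if (length(skipped) > 0L)
    warning("skipped gene(s) with no exon features: ",
            paste(skipped, collapse = ", "))
  out
}

gtf_to_df <- function(gtf) {
  if (is.data.frame(gtf)) {
    stopifnot(all(c("chrom", "start", "end", "strand", "type", "gene_id",
                    "transcript_id") %in% names(gtf)))
    return(gtf)
  }
  # GRanges (1-based closed) -> 0-based half-open
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gtf)),
    start = GenomicRanges::start(gtf) - 1L,
    end = GenomicRanges::end(gtf),
    strand = as.character(GenomicRanges::strand(gtf)),
    type = as.character(gtf$type),
    gene_id = gtf$gene_id,
    transcript_id = gtf$transcript_id,
    stringsAsFactors = FALSE)
}

#' Read gene models from a GTF file
#'
#' Parses a Gencode-dialect GTF with `rtracklayer` and keeps the longest
#' isoform per gene.
#'
#' @param path Path to a GTF file.
#' @return Named list of [gene_model()] objects (see
#'   [select_longest_isoform()]).
#' @export
read_gtf_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  select_longest_isoform(gr)
}

#' Write gene models as GTF
#'
#' Emits exon and CDS features (1-based inclusive, Gencode-style
#' attributes) for each model.
#'
#' @param models Named list of [gene_model()] objects.
#' @param path Output path.
#' @export
write_gtf <- function(models, path) {
  lines <- character()
  for (m in models) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     m$gene_id, m$transcript_id)
    ex <- m$exons
    lines <- c(lines, sprintf("%s\tmeriptools\texon\t%d\t%d\t.\t%s\t.\t%s",
                              m$chrom, ex[, 1L] + 1L, ex[, 2L], m$strand,
                              attrs))
    if (is_coding(m)) {
      cds <- project_interval(m, m$cds_start_tx, m$cds_end_tx)
      lines <- c(lines, sprintf("%s\tmeriptools\tCDS\t%d\t%d\t.\t%s\t.\t%s",
                                m$chrom, cds$start + 1L, cds$end, m$strand,
                                attrs))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
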