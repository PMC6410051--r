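#' Rescale a transcript position onto the metagene axis
#'
#' Maps a transcript position into `[0, 3)`: the 5'UTR onto `[0, 1)`, the
#' CDS onto `[1, 2)` and the 3'UTR onto `[2, 3)`, each segment stretched to
#' unit length. Noncoding models are excluded (return `NA`): the
#' three-segment model applies to mRNA only.
#'
#' @param tpos Transcript positions (0-based), vectorised.
#' @param model A [gene_model()].
#' @return Numeric vector in `[0, 3)`, or `NA` for a noncoding model.
#' @export
rescale_position <- function(tpos, model) {
  if (!is_coding(model)) return(rep(NA_real_, length(tpos)))
  seg <- tx_segments(model)
  if (any(seg == 0L))
    stop("rescale_position requires non-empty 5'UTR, CDS and 3'UTR segments")
  if (any(tpos < 0L | tpos >= model$transcript_length))
    stop("transcript position out of range")
  starts <- c(0L, model$cds_start_tx, model$cds_end_tx)
  idx <- findInterval(tpos, starts)
  unname((idx - 1) + (tpos - starts[idx]) / seg[idx])
}

#' Signed distance of a peak summit from the stop codon
#'
#' Negative values are upstream of the stop codon (within the CDS),
#' positive values downstream (in the 3'UTR).
#'
#' @param summit Summit transcript positions, vectorised.
#' @param model A coding [gene_model()].
#' @return Integer offsets `summit - cds_end_tx`.
#' @export
stop_offset <- function(summit, model) {
  if (!is_coding(model)) stop("stop_offset requires a coding model")
  as.integer(summit) - model$cds_end_tx
}

#' Metagene positions of a peak set
#'
#' Computes, for each peak on a coding transcript, the rescaled metagene
#' coordinate of its midpoint (or summit) and the signed summit offset from
#' the stop codon. Peaks on noncoding transcripts are dropped.
#'
#' @param peaks Peak data.frame from [call_peaks()].
#' @param models Named list of [gene_model()] objects keyed by gene id.
#' @param position `"midpoint"` (default) or `"summit"`: which peak
#'   position is rescaled.
#' @return data.frame with columns `transcript_id`, `tpos`, `x` (rescaled,
#'   in `[0, 3)`), `region_class`, `stop_offset`.
#' @export
metagene_positions <- function(peaks, models, position = c("midpoint",
                                                           "summit")) {
  position <- match.arg(position)
  by_tx <- stats::setNames(models, vapply(models, `[[`, "", "transcript_id"))
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    m <- by_tx[[peaks$transcript_id[i]]]
    if (is.null(m) || !is_coding(m)) return(NULL)
    tpos <- if (position == "midpoint")
      peaks$start[i] + (peaks$end[i] - peaks$start[i]) %/% 2L
    else peaks$summit[i]
    data.frame(transcript_id = peaks$transcript_id[i], tpos = tpos,
               x = rescale_position(tpos, m),
               region_class = region_of_tpos(m, tpos),
               stop_offset = stop_offset(peaks$summit[i], m))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(transcript_id = character(), tpos = integer(),
                      x = numeric(), region_class = character(),
                      stop_offset = integer())
  rownames(out) <- NULL
  out
}

#' Peaks-per-gene histogram
#'
#' @param peaks Peak data.frame with a `gene_id` (or `transcript_id`)
#'   column.
#' @return List with `histogram` (table of genes by peak count, over genes
#'   with at least one peak) and `fraction_one` (fraction of peak-bearing
#'   genes with exactly one peak; `NA` when there are no peaks).
#' @export
peaks_per_gene <- function(peaks) {
  key <- if ("gene_id" %in% names(peaks)) peaks$gene_id
         else peaks$transcript_id
  if (length(key) == 0L)
    return(list(histogram = table(integer()), fraction_one = NA_real_))
  counts <- table(key)
  hist <- table(factor(as.integer(counts)))
  list(histogram = hist,
       fraction_one = unname(sum(counts == 1L) / length(counts)))
}

#' Count motif occurrences in a sequence
#'
#' IUPAC-aware motif counting (e.g. `R = A/G`); overlapping matches are
#' counted.
#'
#' @param sequence Character DNA sequence.
#' @param motif IUPAC motif (default `"RRAC"`, the m6A consensus core).
#' @return Integer occurrence count.
#' @export
count_motif <- function(sequence, motif = "RRAC") {
  length(Biostrings::matchPattern(motif,
                                  Biostrings::DNAString(sequence),
                                  fixed = FALSE))
}

#' Correlate peak enrichment with consensus-site count
#'
#' Counts IUPAC motif occurrences in each peak sequence and computes the
#' Spearman rank correlation against the peak enrichment scores. With
#' constant scores or constant counts the correlation is undefined and
#' returned as `NA` with a warning.
#'
#' @param scores Numeric peak enrichment scores.
#' @param sequences Character vector of peak sequences (same length).
#' @param motif IUPAC motif (default `"RRAC"`).
#' @return List with `rho`, `p_value`, and `motif_counts`.
#' @export
score_vs_motif_count <- function(scores, sequences, motif = "RRAC") {
  stopifnot(length(scores) == length(sequences))
  counts <- vapply(sequences, count_motif, integer(1), motif = motif,
                   USE.NAMES = FALSE)
  if (length(scores) < 3L || stats::sd(scores) == 0 ||
      stats::sd(counts) == 0) {
    warning("rank correlation undefined (constant input or n < 3)")
    return(list(rho = NA_real_, p_value = NA_real_, motif_counts = counts))
  }
  ct <- suppressWarnings(stats::cor.test(scores, counts,
                                         method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       motif_counts = counts)
}
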