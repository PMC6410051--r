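#' Tile a transcript with scan windows
#'
#' Windows are 100 nt wide with 50 nt overlap: starts at 0, 50, 100, ...
#' while the start lies inside the transcript, each window clipped at the
#' transcript end. Trailing windows that do not extend beyond their
#' predecessor (clipped to 50 nt or less) are dropped.
#'
#' @param transcript_length Transcript length in nt.
#' @param width Window width (default 100).
#' @param step Step between window starts (default 50).
#' @return data.frame with columns `start`, `end` (0-based half-open
#'   transcript coordinates); zero rows if `transcript_length < step`.
#' @export
make_windows <- function(transcript_length, width = 100L, step = 50L) {
  transcript_length <- as.integer(transcript_length)
  width <- as.integer(width)
  step <- as.integer(step)
  if (transcript_length < step) {
    message("transcript shorter than ", step, " nt: no windows")
    return(data.frame(start = integer(), end = integer()))
  }
  starts <- seq.int(0L, transcript_length - 1L, by = step)
  ends <- pmin(starts + width, transcript_length)
  # trailing windows fully covered by their predecessor add nothing
  keep <- starts == 0L | (ends - starts) > step
  data.frame(start = starts[keep], end = ends[keep])
}

#' Window enrichment score
#'
#' The log2 enrichment of IP over input for a scan window, each library
#' normalised by its gene-median coverage:
#' `log2((mean_win_ip / median_gene_ip) / (mean_win_ctrl / median_gene_ctrl))`.
#' Inputs are expected to be pseudocounted by the caller; the function
#' evaluates the formula exactly.
#'
#' @param mean_win_ip,mean_win_ctrl Mean per-nt coverage of the window in
#'   the IP and control libraries.
#' @param median_gene_ip,median_gene_ctrl Median per-nt coverage of the
#'   whole transcript in each library.
#' @return Numeric log2 enrichment (vectorised).
#' @export
win_score <- function(mean_win_ip, median_gene_ip,
                      mean_win_ctrl, median_gene_ctrl) {
  log2((mean_win_ip / median_gene_ip) / (mean_win_ctrl / median_gene_ctrl))
}

#' One-sided Fisher exact test for window enrichment
#'
#' Tests the 2x2 table
#' `[[read_ip, gene_ip - read_ip], [read_ctrl, gene_ctrl - read_ctrl]]`
#' (window reads vs rest-of-gene reads, IP vs control) one-sided toward IP
#' enrichment. The p-value is the hypergeometric upper-tail sum
#' `P(X >= read_ip)` with `X ~ Hypergeom(gene_ip, gene_ctrl,
#' read_ip + read_ctrl)`.
#'
#' @param read_ip,read_ctrl Window read counts in IP and control.
#' @param gene_ip,gene_ctrl Whole-transcript read counts in IP and control
#'   (must be >= the window counts).
#' @return One-sided p-value (vectorised).
#' @export
fisher_window_test <- function(read_ip, gene_ip, read_ctrl, gene_ctrl) {
  if (any(read_ip < 0 | read_ctrl < 0 | gene_ip - read_ip < 0 |
          gene_ctrl - read_ctrl < 0))
    stop("negative cell in Fisher table: require gene counts >= window counts >= 0")
  stats::phyper(read_ip - 1, gene_ip, gene_ctrl, read_ip + read_ctrl,
                lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate correction with monotonicity
#' enforcement, applied across all tested windows transcriptome-wide in one
#' batch.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
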