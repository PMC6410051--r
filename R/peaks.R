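#' Call m6A peaks from IP and control coverage
#'
#' The window-scan peak caller. Per transcript shared by both libraries:
#' tile 100-nt windows with 50-nt overlap ([make_windows()]); compute the
#' gene-median-normalised log2 enrichment [win_score()] of each window
#' (with a pseudocount added to all four inputs); test only windows at or
#' above `enrichment_cutoff` with a one-sided Fisher exact test
#' ([fisher_window_test()]) on read-unit counts (coverage sums divided by
#' `read_length`, +1 read-unit pseudocount); adjust all tested windows
#' transcriptome-wide in one Benjamini-Hochberg batch; keep windows with
#' adjusted p below `alpha`; merge overlapping or adjacent kept windows
#' into peaks.
#'
#' A peak's `enrichment_score` is the maximum window score among its merged
#' windows, its `p_adjusted` the minimum adjusted p, and its `summit` the
#' transcript position of maximum depth-normalised IP coverage (leftmost on
#' ties). Transcripts absent from either library, shorter than 50 nt, or
#' with zero median coverage in either library are skipped with a message.
#'
#' @param ip,ctrl [coverage_set()] objects for the IP and input libraries.
#' @param models Optional named list of [gene_model()] objects (keyed by
#'   gene id, with matching `transcript_id`); when given, peaks gain
#'   `gene_id` and a `region_class` (`"5'UTR"`, `"CDS"`, `"3'UTR"` by the
#'   peak midpoint; `"noncoding"` for models without a CDS).
#' @param enrichment_cutoff Minimum window score to test (log2 units;
#'   default 1, i.e. 2-fold).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param read_length Read length for the coverage-to-count conversion.
#' @param pseudocount Added to the four score inputs (per-nt units) and,
#'   as one read-unit, to the four Fisher totals.
#' @return data.frame of peaks with columns `transcript_id`, `start`,
#'   `end`, `enrichment_score`, `p_adjusted`, `summit`, `n_windows` (plus
#'   `gene_id`, `region_class` when `models` is given). The full window
#'   table is attached as attribute `"windows"`.
#' @export
call_peaks <- function(ip, ctrl, models = NULL, enrichment_cutoff = 1,
                       alpha = 0.05, read_length = 50, pseudocount = 1) {
  stopifnot(inherits(ip, "coverage_set"), inherits(ctrl, "coverage_set"))
  shared <- intersect(names(ip$tracks), names(ctrl$tracks))
  miss <- setdiff(union(names(ip$tracks), names(ctrl$tracks)), shared)
  if (length(miss) > 0L)
    message(length(miss), " transcript(s) absent from one library skipped")

  win_list <- vector("list", length(shared))
  names(win_list) <- shared
  for (tx in shared) {
    cov_ip <- ip$tracks[[tx]]
    cov_ctrl <- ctrl$tracks[[tx]]
    if (length(cov_ip) != length(cov_ctrl))
      stop("track length mismatch for ", tx)
    med_ip <- stats::median(cov_ip)
    med_ctrl <- stats::median(cov_ctrl)
    if (med_ip == 0 || med_ctrl == 0) {
      message("transcript ", tx, " has zero median coverage: excluded")
      next
    }
    w <- make_windows(length(cov_ip))
    if (nrow(w) == 0L) next
    sums_ip <- vapply(seq_len(nrow(w)), function(i)
      sum(cov_ip[(w$start[i] + 1L):w$end[i]]), numeric(1))
    sums_ctrl <- vapply(seq_len(nrow(w)), function(i)
      sum(cov_ctrl[(w$start[i] + 1L):w$end[i]]), numeric(1))
    wl <- w$end - w$start
    score <- win_score(sums_ip / wl + pseudocount, med_ip + pseudocount,
                       sums_ctrl / wl + pseudocount, med_ctrl + pseudocount)
    win_list[[tx]] <- data.frame(
      transcript_id = tx, start = w$start, end = w$end,
      mean_win_ip = sums_ip / wl, mean_win_ctrl = sums_ctrl / wl,
      median_gene_ip = med_ip, median_gene_ctrl = med_ctrl,
      win_score = score,
      read_ip = round(sums_ip / read_length) + 1,
      read_ctrl = round(sums_ctrl / read_length) + 1,
      gene_ip = round(sum(cov_ip) / read_length) + 1,
      gene_ctrl = round(sum(cov_ctrl) / read_length) + 1)
  }
  windows <- do.call(rbind, win_list)
  empty <- data.frame(transcript_id = character(), start = integer(),
                      end = integer(), enrichment_score = numeric(),
                      p_adjusted = numeric(), summit = integer(),
                      n_windows = integer())
  if (is.null(windows) || nrow(windows) == 0L)
    return(structure(empty, windows = windows))
  rownames(windows) <- NULL

  tested <- windows$win_score >= enrichment_cutoff
  windows$p_value <- NA_real_
  windows$p_value[tested] <- fisher_window_test(
    windows$read_ip[tested], windows$gene_ip[tested],
    windows$read_ctrl[tested], windows$gene_ctrl[tested])
  windows$p_adjusted <- NA_real_
  windows$p_adjusted[tested] <- bh_adjust(windows$p_value[tested])

  sig <- windows[tested & windows$p_adjusted < alpha, , drop = FALSE]
  if (nrow(sig) == 0L) return(structure(empty, windows = windows))

  peaks <- do.call(rbind, lapply(split(sig, sig$transcript_id), function(s) {
    s <- s[order(s$start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(s$start[-1L] > cummax(s$end)[-nrow(s)])))
    do.call(rbind, lapply(split(s, grp), function(m) {
      cov_ip <- ip$tracks[[m$transcript_id[1L]]]
      pk_start <- min(m$start); pk_end <- max(m$end)
      seg <- normalize_track(cov_ip[(pk_start + 1L):pk_end], ip$library_size)
      data.frame(transcript_id = m$transcript_id[1L],
                 start = pk_start, end = pk_end,
                 enrichment_score = max(m$win_score),
                 p_adjusted = min(m$p_adjusted),
                 summit = pk_start + which.max(seg) - 1L,
                 n_windows = nrow(m))
    }))
  }))
  rownames(peaks) <- NULL

  if (!is.null(models)) {
    by_tx <- stats::setNames(models,
                             vapply(models, `[[`, "", "transcript_id"))
    peaks$gene_id <- vapply(peaks$transcript_id, function(tx)
      if (tx %in% names(by_tx)) by_tx[[tx]]$gene_id else NA_character_, "")
    mid <- peaks$start + (peaks$end - peaks$start) %/% 2L
    peaks$region_class <- vapply(seq_len(nrow(peaks)), function(i) {
      m <- by_tx[[peaks$transcript_id[i]]]
      if (is.null(m)) return(NA_character_)
      region_of_tpos(m, mid[i])
    }, "")
  }
  structure(peaks, windows = windows)
}

#' Extract the summit-flanking sequence of a peak
#'
#' Returns the 50 nt upstream and downstream of the peak summit (a 101-nt
#' window), clipped at the transcript ends, for use with external motif
#' tools.
#'
#' @param summit Summit position (0-based transcript coordinate).
#' @param transcript_sequence Transcript sequence (character or
#'   `Biostrings::DNAString`).
#' @param flank Flank size in nt (default 50).
#' @return Character sequence of length at most `2 * flank + 1`.
#' @export
summit_flanks <- function(summit, transcript_sequence, flank = 50L) {
  s <- as.character(transcript_sequence)
  len <- nchar(s)
  stopifnot(summit >= 0L, summit < len)
  lo <- max(0L, summit - flank)
  hi <- min(len, summit + flank + 1L)
  substr(s, lo + 1L, hi)
}

#' Write summit flank sequences as FASTA
#'
#' @param peaks Peak data.frame from [call_peaks()].
#' @param sequences Named character vector or `DNAStringSet` of transcript
#'   sequences keyed by transcript id.
#' @param path Output FASTA path.
#' @param flank Flank size in nt.
#' @export
write_summit_fasta <- function(peaks, sequences, path, flank = 50L) {
  seqs <- vapply(seq_len(nrow(peaks)), function(i)
    summit_flanks(peaks$summit[i],
                  sequences[[peaks$transcript_id[i]]], flank), "")
  names(seqs) <- sprintf("%s_peak%d_summit%d", peaks$transcript_id,
                         seq_len(nrow(peaks)), peaks$summit)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write peaks as TSV
#'
#' @param peaks Peak data.frame from [call_peaks()].
#' @param path Output path.
#' @export
write_peaks_tsv <- function(peaks, path) {
  utils::write.table(peaks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read peaks from TSV
#'
#' @param path Path written by [write_peaks_tsv()].
#' @return Peak data.frame.
#' @export
read_peaks_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Project peaks to genome-coordinate BED6
#'
#' Each peak is split at exon junctions into contiguous genomic blocks; one
#' BED line is written per block, scored by the peak enrichment score.
#'
#' @param peaks Peak data.frame from [call_peaks()].
#' @param models Named list of [gene_model()] objects keyed by gene id.
#' @param path Output BED path.
#' @export
peaks_to_bed <- function(peaks, models, path) {
  by_tx <- stats::setNames(models, vapply(models, `[[`, "", "transcript_id"))
  lines <- character()
  for (i in seq_len(nrow(peaks))) {
    m <- by_tx[[peaks$transcript_id[i]]]
    if (is.null(m)) next
    blocks <- project_interval(m, peaks$start[i], peaks$end[i])
    lines <- c(lines, sprintf("%s\t%d\t%d\t%s_peak%d\t%.3f\t%s",
                              m$chrom, blocks$start, blocks$end,
                              peaks$transcript_id[i], i,
                              peaks$enrichment_score[i], m$strand))
  }
  writeLines(lines, path)
  invisible(path)
}
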