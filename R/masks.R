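#' Construct an interval mask
#'
#' A named set of genomic intervals (Alu elements, simple repeats, known
#' SNPs, splice-junction points, similarity regions) queryable per position.
#' Backed by a `GRanges`, so point queries are logarithmic.
#'
#' @param name Mask name, one of `"alu"`, `"simple_repeat"`, `"snp"`,
#'   `"splice_junction"`, `"similarity"` (free names allowed).
#' @param intervals data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), or a `GRanges`.
#' @return An object of class `interval_mask`.
#' @export
interval_mask <- function(name, intervals) {
  if (inherits(intervals, "GRanges")) {
    gr <- intervals
  } else {
    stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
    if (nrow(intervals) > 0 && any(intervals$end <= intervals$start))
      stop("mask intervals must have end > start (0-based half-open)")
    gr <- GenomicRanges::GRanges(
      intervals$chrom,
      IRanges::IRanges(start = intervals$start + 1L, end = intervals$end))
  }
  gr <- GenomicRanges::sort(gr)
  structure(list(name = name, ranges = gr), class = "interval_mask")
}

#' @export
print.interval_mask <- function(x, ...) {
  cat(sprintf("interval_mask '%s': %d interval(s)\n", x$name,
              length(x$ranges)))
  invisible(x)
}

#' Test positions for mask membership
#'
#' @param mask An [interval_mask()].
#' @param chrom Chromosome names (recycled to `pos`).
#' @param pos Genomic positions (0-based).
#' @return Logical vector, `TRUE` where the position lies inside a mask
#'   interval.
#' @export
mask_overlaps <- function(mask, chrom, pos) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
  IRanges::overlapsAny(q, mask$ranges)
}

#' Test positions for proximity to a mask
#'
#' `TRUE` where the position lies inside a mask interval or within `dist`
#' coordinate units of one (so a splice-junction point 4 nt away is flagged
#' at `dist = 4`, one 5 nt away is not).
#'
#' @param mask An [interval_mask()].
#' @param chrom Chromosome names.
#' @param pos Genomic positions (0-based).
#' @param dist Maximum coordinate distance (>= 1).
#' @return Logical vector.
#' @export
mask_within <- function(mask, chrom, pos, dist) {
  stopifnot(dist >= 1)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
  hit <- GenomicRanges::distanceToNearest(q, mask$ranges)
  out <- rep(FALSE, length(pos))
  # GRanges distance counts bases strictly between, so coordinate distance
  # d maps to GRanges distance d - 1 for disjoint ranges.
  out[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance <= dist - 1L
  out
}

#' Read a BED file as an interval mask
#'
#' @param path Path to a BED3/BED6 file.
#' @param name Mask name (defaults to the file base name).
#' @return An [interval_mask()].
#' @export
read_bed_mask <- function(path, name = sub("\\.bed$", "", basename(path))) {
  interval_mask(name, rtracklayer::import(path, format = "bed"))
}

#' Write an interval mask as BED3
#'
#' @param mask An [interval_mask()].
#' @param path Output path.
#' @export
write_bed_mask <- function(mask, path) {
  gr <- mask$ranges
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
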