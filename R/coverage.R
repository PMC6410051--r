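#' Construct a coverage set
#'
#' Per-nucleotide read coverage on transcript coordinates for one library,
#' plus the library size (total mapped reads) used for normalisation.
#'
#' @param tracks Named list of numeric vectors, one per transcript; element
#'   `i` of a vector is the read coverage at transcript position `i - 1`.
#' @param library_size Total mapped reads in the library. If `NULL`,
#'   estimated as the summed coverage divided by `read_length`.
#' @param read_length Read length used for the default library size.
#' @return An object of class `coverage_set`.
#' @export
coverage_set <- function(tracks, library_size = NULL, read_length = 50) {
  stopifnot(is.list(tracks), !is.null(names(tracks)))
  if (is.null(library_size))
    library_size <- round(sum(vapply(tracks, sum, numeric(1))) / read_length)
  if (library_size <= 0) stop("library_size must be positive")
  structure(list(tracks = tracks, library_size = library_size),
            class = "coverage_set")
}

#' @export
print.coverage_set <- function(x, ...) {
  cat(sprintf("coverage_set: %d transcript(s), library size %g\n",
              length(x$tracks), x$library_size))
  invisible(x)
}

#' Normalise a coverage track to one million reads
#'
#' Scales per-nucleotide coverage by `1e6 / total_reads` so tracks from
#' libraries of different depth are comparable. A positive rescaling, so
#' summit (argmax) positions are unchanged.
#'
#' @param track Numeric vector of per-nucleotide coverage.
#' @param total_reads Total mapped reads in the library (> 0).
#' @return Numeric vector of normalised coverage.
#' @export
normalize_track <- function(track, total_reads) {
  if (!is.numeric(total_reads) || length(total_reads) != 1L ||
      total_reads <= 0)
    stop("total_reads must be a single positive number")
  track * 1e6 / total_reads
}

#' Write a coverage set as per-base TSV
#'
#' Long format with columns `transcript_id`, `pos` (0-based), `coverage`;
#' the library size is recorded in a `# library_size=` header line.
#'
#' @param cov A [coverage_set()].
#' @param path Output path.
#' @export
write_coverage_tsv <- function(cov, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# library_size=%g", cov$library_size), con)
  writeLines("transcript_id\tpos\tcoverage", con)
  for (tx in names(cov$tracks)) {
    v <- cov$tracks[[tx]]
    writeLines(sprintf("%s\t%d\t%g", tx, seq_along(v) - 1L, v), con)
  }
  invisible(path)
}

#' Read a coverage set from per-base TSV
#'
#' @param path Path written by [write_coverage_tsv()].
#' @return A [coverage_set()].
#' @export
read_coverage_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  lib <- as.numeric(sub("^# library_size=", "", first))
  df <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  tracks <- lapply(split(df, df$transcript_id), function(d) {
    d$coverage[order(d$pos)]
  })
  coverage_set(tracks, library_size = lib)
}
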