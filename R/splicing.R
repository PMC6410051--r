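#' Filter rMATS-format differential-splicing events
#'
#' Keeps events with `FDR < fdr`, absolute inclusion-level difference at
#' least `min_dpsi` (PSI units, so the default 0.05 is five percentage
#' points), and at least `min_count` inclusion reads and `min_count`
#' skipping reads in each condition (counts are replicate sums).
#' Idempotent: filtering a filtered table changes nothing.
#'
#' @param events data.frame with columns `event_type`, `gene_id`, `IJC_1`,
#'   `SJC_1`, `IJC_2`, `SJC_2`, `IncLevel1`, `IncLevel2`,
#'   `IncLevelDifference`, `FDR`.
#' @param fdr FDR cutoff (default 0.05, strict).
#' @param min_dpsi Minimum `|IncLevelDifference|` (default 0.05,
#'   inclusive).
#' @param min_count Minimum inclusion and skipping counts per condition
#'   (default 10, inclusive).
#' @return The retained rows.
#' @export
filter_events <- function(events, fdr = 0.05, min_dpsi = 0.05,
                          min_count = 10L) {
  need <- c("event_type", "IJC_1", "SJC_1", "IJC_2", "SJC_2",
            "IncLevelDifference", "FDR")
  stopifnot(all(need %in% names(events)))
  keep <- events$FDR < fdr &
    abs(events$IncLevelDifference) >= min_dpsi &
    events$IJC_1 >= min_count & events$SJC_1 >= min_count &
    events$IJC_2 >= min_count & events$SJC_2 >= min_count
  events[keep, , drop = FALSE]
}

#' Compare inclusion levels between conditions per event type
#'
#' Wilcoxon rank-sum test of the PSI (inclusion-level) distributions of
#' condition 1 vs condition 2, separately for each event type (SE, RI,
#' A5SS, A3SS, MXE). Types with fewer than three events yield `NA` with a
#' warning.
#'
#' @param events Event data.frame with `event_type`, `IncLevel1`,
#'   `IncLevel2`.
#' @return data.frame with `event_type`, `n`, `median_1`, `median_2`,
#'   `p_value`.
#' @export
compare_inclusion_by_type <- function(events) {
  do.call(rbind, lapply(split(events, events$event_type), function(e) {
    p <- if (nrow(e) < 3L) {
      warning("fewer than 3 events of type ", e$event_type[1L],
              ": no test")
      NA_real_
    } else {
      suppressWarnings(stats::wilcox.test(e$IncLevel1,
                                          e$IncLevel2)$p.value)
    }
    data.frame(event_type = e$event_type[1L], n = nrow(e),
               median_1 = stats::median(e$IncLevel1),
               median_2 = stats::median(e$IncLevel2), p_value = p)
  }))
}

#' Test m6A dependence of exon skipping
#'
#' For skipped-exon (SE) events: flags whether the alternative exon's
#' transcript interval overlaps any control-condition m6A peak on the same
#' gene, and compares the inclusion-difference (delta-PSI) distributions
#' of events in m6A-modified genes vs genes without peaks with a
#' Kolmogorov-Smirnov test. With no m6A genes (or no non-m6A genes) among
#' the events the comparison is skipped with a warning.
#'
#' @param events Event data.frame; SE rows are used. Overlap flags need
#'   columns `exon_tx_start`, `exon_tx_end` (transcript coordinates of the
#'   alternative exon; `NA` where unresolvable).
#' @param peaks Control-condition peak data.frame (with `gene_id` or
#'   `transcript_id`).
#' @return List with `events` (SE rows plus `m6a_gene`, `peak_overlap`)
#'   and `ks` (from [cdf_compare()], or `NULL`).
#' @export
m6a_dependence_of_SE <- function(events, peaks) {
  se <- events[events$event_type == "SE", , drop = FALSE]
  peak_gene <- if ("gene_id" %in% names(peaks)) peaks$gene_id
               else peaks$transcript_id
  se$m6a_gene <- se$gene_id %in% peak_gene
  has_coord <- all(c("exon_tx_start", "exon_tx_end") %in% names(se))
  se$peak_overlap <- vapply(seq_len(nrow(se)), function(i) {
    if (!has_coord || is.na(se$exon_tx_start[i])) return(NA)
    j <- which(peak_gene == se$gene_id[i] &
                 peaks$start < se$exon_tx_end[i] &
                 peaks$end > se$exon_tx_start[i])
    length(j) > 0L
  }, logical(1))
  a <- se$IncLevelDifference[se$m6a_gene]
  b <- se$IncLevelDifference[!se$m6a_gene]
  ks <- if (length(a) >= 3L && length(b) >= 3L) cdf_compare(a, b)
        else {
          warning("too few m6A or non-m6A SE events: comparison skipped")
          NULL
        }
  list(events = se, ks = ks)
}

#' Read an rMATS JC output table
#'
#' Reads one rMATS `*.MATS.JC.txt` file, sums replicate counts and
#' averages replicate inclusion levels, returning the column layout used
#' by [filter_events()].
#'
#' @param path Path to an rMATS JC table.
#' @param event_type Event type label to assign (e.g. `"SE"`).
#' @return data.frame with `event_type`, `gene_id`, `IJC_1`, `SJC_1`,
#'   `IJC_2`, `SJC_2`, `IncLevel1`, `IncLevel2`, `IncLevelDifference`,
#'   `FDR`.
#' @export
read_rmats <- function(path, event_type) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  sum_reps <- function(x) vapply(strsplit(as.character(x), ","),
                                 function(v) sum(as.numeric(v)), numeric(1))
  mean_reps <- function(x) vapply(strsplit(as.character(x), ","),
                                  function(v) mean(as.numeric(v),
                                                   na.rm = TRUE),
                                  numeric(1))
  data.frame(event_type = event_type,
             gene_id = if ("GeneID" %in% names(df)) df$GeneID else df$geneSymbol,
             IJC_1 = sum_reps(df$IJC_SAMPLE_1),
             SJC_1 = sum_reps(df$SJC_SAMPLE_1),
             IJC_2 = sum_reps(df$IJC_SAMPLE_2),
             SJC_2 = sum_reps(df$SJC_SAMPLE_2),
             IncLevel1 = mean_reps(df$IncLevel1),
             IncLevel2 = mean_reps(df$IncLevel2),
             IncLevelDifference = df$IncLevelDifference,
             FDR = df$FDR)
}
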