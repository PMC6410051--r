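#' Compare peak sets between conditions
#'
#' Classifies every peak of the control condition against the silenced
#' condition (and vice versa) on shared transcript coordinates. Overlap is
#' at least one shared nucleotide on the same transcript. A control peak
#' with no overlapping silenced peak is `lost`; an overlapping pair whose
#' enrichment score drops by at least `reduction_threshold` log2 units is
#' `reduced`; a drop or gain below the threshold is `common`; a gain of at
#' least the threshold, or a silenced-only peak, is `independent` (peaks
#' not depending on the silenced methyltransferase).
#'
#' The gene-level class is the strongest class among a gene's peaks, in the
#' priority order lost > reduced > common > independent.
#'
#' @param peaks_control,peaks_silenced Peak data.frames from
#'   [call_peaks()] (columns `transcript_id`, `start`, `end`,
#'   `enrichment_score`; `gene_id` optional, defaulting to
#'   `transcript_id`).
#' @param reduction_threshold Minimum log2 score drop to call a peak
#'   `reduced` (default 1).
#' @return List with `peaks` (per-peak table with `condition` and
#'   `peak_class`) and `genes` (data.frame `gene_id`, `peak_class`).
#' @export
compare_peak_sets <- function(peaks_control, peaks_silenced,
                              reduction_threshold = 1) {
  gene_of <- function(p) {
    if ("gene_id" %in% names(p)) p$gene_id else p$transcript_id
  }
  overlap_score <- function(p, i, other) {
    j <- which(other$transcript_id == p$transcript_id[i] &
                 other$start < p$end[i] & other$end > p$start[i])
    if (length(j) == 0L) NA_real_ else max(other$enrichment_score[j])
  }
  nc <- nrow(peaks_control); ns <- nrow(peaks_silenced)
  ctrl_class <- character(nc)
  for (i in seq_len(nc)) {
    os <- overlap_score(peaks_control, i, peaks_silenced)
    ctrl_class[i] <-
      if (is.na(os)) "lost"
      else {
        d <- peaks_control$enrichment_score[i] - os
        if (d >= reduction_threshold) "reduced"
        else if (d <= -reduction_threshold) "independent"
        else "common"
      }
  }
  sil_class <- character(ns)
  for (i in seq_len(ns)) {
    os <- overlap_score(peaks_silenced, i, peaks_control)
    sil_class[i] <-
      if (is.na(os)) "independent"
      else {
        d <- os - peaks_silenced$enrichment_score[i]
        if (d >= reduction_threshold) "reduced"
        else if (d <= -reduction_threshold) "independent"
        else "common"
      }
  }
  per_peak <- rbind(
    data.frame(condition = rep("control", nc),
               gene_id = gene_of(peaks_control),
               transcript_id = peaks_control$transcript_id,
               start = peaks_control$start, end = peaks_control$end,
               enrichment_score = peaks_control$enrichment_score,
               peak_class = ctrl_class),
    data.frame(condition = rep("silenced", ns),
               gene_id = gene_of(peaks_silenced),
               transcript_id = peaks_silenced$transcript_id,
               start = peaks_silenced$start, end = peaks_silenced$end,
               enrichment_score = peaks_silenced$enrichment_score,
               peak_class = sil_class))
  prio <- c(lost = 1L, reduced = 2L, common = 3L, independent = 4L)
  genes <- do.call(rbind, lapply(split(per_peak, per_peak$gene_id),
    function(g) data.frame(gene_id = g$gene_id[1L],
                           peak_class = names(prio)[min(prio[g$peak_class])])))
  if (is.null(genes))
    genes <- data.frame(gene_id = character(), peak_class = character())
  rownames(genes) <- NULL
  list(peaks = per_peak, genes = genes)
}

#' Apply differential-expression thresholds
#'
#' A gene is regulated iff its adjusted p-value is below 0.05 and its
#' absolute fold change exceeds 1.5 (both strict inequalities); direction
#' follows the sign of the log2 fold change.
#'
#' @param de data.frame with columns `gene_id`, `log2_fold_change`
#'   (condition minus control) and `p_adjusted`.
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param fold_change Fold-change cutoff on the linear scale (default 1.5).
#' @return The input with added columns `regulated` (logical) and
#'   `direction` (`"up"`, `"down"`, `"none"`).
#' @export
apply_de_thresholds <- function(de, alpha = 0.05, fold_change = 1.5) {
  stopifnot(all(c("gene_id", "log2_fold_change", "p_adjusted") %in%
                  names(de)))
  de$regulated <- de$p_adjusted < alpha &
    abs(de$log2_fold_change) > log2(fold_change)
  de$direction <- ifelse(!de$regulated, "none",
                         ifelse(de$log2_fold_change > 0, "up", "down"))
  de
}

#' Classify genes into direct and indirect target classes
#'
#' Genes whose m6A peak is lost or reduced upon methyltransferase silencing
#' are direct targets, split into `direct_regulated` and
#' `direct_unregulated` by the differential-expression flag. Genes
#' regulated at the RNA level without a dependent peak (no peak,
#' silencing-independent peak, or unchanged peak) are `indirect_regulated`;
#' the remainder are `unaffected`. The classes partition the gene universe
#' (the union of peak-bearing and expression-tested genes).
#'
#' @param gene_classes data.frame `gene_id`, `peak_class` from
#'   [compare_peak_sets()]; genes absent get peak class `"none"`.
#' @param de Differential-expression table processed by
#'   [apply_de_thresholds()] (columns `gene_id`, `regulated`, `direction`;
#'   `biotype` carried through if present).
#' @return data.frame with one row per gene: `gene_id`, `peak_class`,
#'   `regulated`, `direction`, `target_class`, and `biotype` when
#'   available.
#' @export
classify_targets <- function(gene_classes, de) {
  universe <- union(gene_classes$gene_id, de$gene_id)
  pc <- stats::setNames(gene_classes$peak_class, gene_classes$gene_id)
  peak_class <- ifelse(universe %in% names(pc), pc[universe], "none")
  i <- match(universe, de$gene_id)
  regulated <- ifelse(is.na(i), FALSE, de$regulated[i])
  direction <- ifelse(is.na(i), "none", de$direction[i])
  out <- data.frame(gene_id = universe, peak_class = unname(peak_class),
                    regulated = regulated, direction = direction)
  if ("biotype" %in% names(de))
    out$biotype <- ifelse(is.na(i), "other", de$biotype[i])
  direct <- out$peak_class %in% c("lost", "reduced")
  out$target_class <- ifelse(
    direct & out$regulated, "direct_regulated",
    ifelse(direct, "direct_unregulated",
           ifelse(out$regulated, "indirect_regulated", "unaffected")))
  rownames(out) <- NULL
  out
}

pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den

#' Summarise target classification
#'
#' Bookkeeping counts and percentages for a target-record table: how many
#' direct targets are regulated, how many of those are downregulated, the
#' indirect share of the regulated transcriptome and its up/down split,
#' overall and for protein-coding genes only. Percentages are returned
#' unrounded; zero denominators yield `NA`.
#'
#' @param records data.frame from [classify_targets()].
#' @return List with `counts` (named integer vector) and `percentages`
#'   (named numeric vector).
#' @export
summarize_targets <- function(records) {
  tc <- records$target_class
  n_direct <- sum(tc %in% c("direct_regulated", "direct_unregulated"))
  n_dir_reg <- sum(tc == "direct_regulated")
  n_dir_unreg <- sum(tc == "direct_unregulated")
  n_dir_down <- sum(tc == "direct_regulated" & records$direction == "down")
  n_ind <- sum(tc == "indirect_regulated")
  n_reg <- n_dir_reg + n_ind
  n_ind_up <- sum(tc == "indirect_regulated" & records$direction == "up")
  n_ind_down <- sum(tc == "indirect_regulated" &
                      records$direction == "down")
  has_bio <- "biotype" %in% names(records)
  pc_ind <- if (has_bio) tc == "indirect_regulated" &
    records$biotype == "protein_coding" else rep(FALSE, nrow(records))
  n_pc_ind <- sum(pc_ind)
  n_pc_ind_up <- sum(pc_ind & records$direction == "up")
  n_pc_ind_down <- sum(pc_ind & records$direction == "down")
  list(
    counts = c(total_genes = nrow(records), direct = n_direct,
               direct_regulated = n_dir_reg,
               direct_unregulated = n_dir_unreg,
               direct_regulated_down = n_dir_down,
               regulated = n_reg, indirect_regulated = n_ind,
               indirect_up = n_ind_up, indirect_down = n_ind_down,
               pc_indirect = n_pc_ind, pc_indirect_up = n_pc_ind_up,
               pc_indirect_down = n_pc_ind_down,
               unaffected = sum(tc == "unaffected")),
    percentages = c(
      direct_regulated = pct(n_dir_reg, n_direct),
      direct_regulated_down = pct(n_dir_down, n_dir_reg),
      direct_unregulated = pct(n_dir_unreg, n_direct),
      indirect_of_regulated = pct(n_ind, n_reg),
      indirect_up = pct(n_ind_up, n_ind),
      indirect_down = pct(n_ind_down, n_ind),
      pc_indirect_up = pct(n_pc_ind_up, n_pc_ind),
      pc_indirect_down = pct(n_pc_ind_down, n_pc_ind)))
}

#' Compare two samples by cumulative distribution
#'
#' Two-sample Kolmogorov-Smirnov test (asymptotic p) plus the median shift
#' `median(a) - median(b)`.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return List with `D`, `p_value`, `median_shift`.
#' @export
cdf_compare <- function(sample_a, sample_b) {
  if (length(sample_a) == 0L || length(sample_b) == 0L)
    stop("both samples must be non-empty")
  ks <- suppressWarnings(stats::ks.test(sample_a, sample_b, exact = FALSE))
  list(D = unname(ks$statistic), p_value = ks$p.value,
       median_shift = stats::median(sample_a) - stats::median(sample_b))
}

#' Classify an RBP by its cooperation with m6A
#'
#' Compares the differential expression (silenced minus control) of
#' m6A-modified transcripts carrying the RBP's binding site against
#' m6A-modified transcripts without a site. A significant shift
#' (Kolmogorov-Smirnov p below `alpha`) with a lower with-site median
#' means the RBP stabilises its m6A targets (`stabilizer`); a higher
#' with-site median means `destabilizer`; otherwise `neutral`.
#'
#' @param with_site_deltas,without_site_deltas Numeric vectors of per-gene
#'   expression differences.
#' @param alpha Significance cutoff (default 0.05).
#' @return List with `class`, `p_value`, `median_shift`.
#' @export
classify_rbp <- function(with_site_deltas, without_site_deltas,
                         alpha = 0.05) {
  cmp <- cdf_compare(with_site_deltas, without_site_deltas)
  cls <- if (cmp$p_value >= alpha || cmp$median_shift == 0) "neutral"
         else if (cmp$median_shift < 0) "stabilizer" else "destabilizer"
  list(class = cls, p_value = cmp$p_value, median_shift = cmp$median_shift)
}

#' Abundance distributions by m6A status and biotype
#'
#' Builds per-group empirical CDF tables of expression (FPKM-like) split
#' by m6A modification status within each biotype, with a
#' Kolmogorov-Smirnov comparison of m6A vs non-m6A where both groups are
#' present.
#'
#' @param expression data.frame with columns `gene_id`, `fpkm`, `m6a`
#'   (logical) and `biotype`.
#' @param biotypes Biotypes to analyse (default protein-coding and
#'   lincRNA).
#' @return Named list per biotype with `cdf` (data.frame `fpkm`, `m6a`,
#'   `ecdf`) and `test` (from [cdf_compare()], or `NULL` with one group).
#' @export
abundance_by_group <- function(expression,
                               biotypes = c("protein_coding", "lincRNA")) {
  stopifnot(all(c("fpkm", "m6a", "biotype") %in% names(expression)))
  out <- list()
  for (bt in biotypes) {
    sub <- expression[expression$biotype == bt, , drop = FALSE]
    if (nrow(sub) == 0L) stop("no genes of biotype ", bt)
    cdf <- do.call(rbind, lapply(split(sub, sub$m6a), function(g) {
      o <- order(g$fpkm)
      data.frame(fpkm = g$fpkm[o], m6a = g$m6a[o],
                 ecdf = seq_along(o) / length(o))
    }))
    rownames(cdf) <- NULL
    test <- if (length(unique(sub$m6a)) == 2L)
      cdf_compare(sub$fpkm[sub$m6a], sub$fpkm[!sub$m6a]) else NULL
    out[[bt]] <- list(cdf = cdf, test = test)
  }
  out
}
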