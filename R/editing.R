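#' Homopolymer check for an editing site
#'
#' A site is flagged when the reference run of identical bases covering the
#' site position has length at least `min_run` (default 5). Runs adjacent
#' to but not covering the site do not flag it.
#'
#' @param context Reference context string with the site at position
#'   `center` (1-based within the string).
#' @param center 1-based index of the site within `context`.
#' @param min_run Minimum run length (default 5).
#' @return Logical.
#' @export
homopolymer_check <- function(context, center = (nchar(context) + 1L) %/% 2L,
                              min_run = 5L) {
  ch <- strsplit(context, "")[[1]]
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  idx <- which(ends >= center)[1L]
  r$lengths[idx] >= min_run
}

#' High-confidence editing flag
#'
#' An editing event is high confidence when 10 or more reads cover it and
#' the editing ratio is at least 0.2 (both bounds inclusive).
#'
#' @param total_reads Total read depth at the site.
#' @param editing_ratio Fraction of reads carrying the altered base.
#' @param min_reads,min_ratio Thresholds (defaults 10 and 0.2).
#' @return Logical (vectorised).
#' @export
high_confidence <- function(total_reads, editing_ratio, min_reads = 10L,
                            min_ratio = 0.2) {
  total_reads >= min_reads & editing_ratio >= min_ratio
}

#' Classify an editing event type
#'
#' A-to-I editing appears as A-to-G on the plus strand or T-to-C on the
#' minus strand; C-to-U editing as C-to-T on the plus strand or G-to-A on
#' the minus strand. Strandless sites (`strand = "."`) are typed by the
#' genomic change in either orientation. Everything else is `other`.
#'
#' @param ref,alt Reference and alternative bases (genomic).
#' @param strand `"+"`, `"-"` or `"."` (vectorised).
#' @return Character vector: `"A_to_I"`, `"C_to_U"` or `"other"`.
#' @export
classify_edit_type <- function(ref, alt, strand) {
  n <- max(length(ref), length(alt), length(strand))
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  strand <- rep_len(strand, n)
  chg <- paste0(ref, alt)
  a2i_plus <- chg == "AG"; a2i_minus <- chg == "TC"
  c2u_plus <- chg == "CT"; c2u_minus <- chg == "GA"
  ifelse(
    (strand == "+" & a2i_plus) | (strand == "-" & a2i_minus) |
      (strand == "." & (a2i_plus | a2i_minus)), "A_to_I",
    ifelse(
      (strand == "+" & c2u_plus) | (strand == "-" & c2u_minus) |
        (strand == "." & (c2u_plus | c2u_minus)), "C_to_U", "other"))
}

#' Run the editing-detection filter cascade
#'
#' Applies, in order, the filters that separate genuine editing events
#' from artefacts:
#'
#' 1. `snp`: sites overlapping the known-polymorphism mask are removed
#'    (all sites).
#' 2. Read-start discount: supporting reads whose mismatch lies in the
#'    first six read bases (offsets 0-5, a random-hexamer priming
#'    artefact) are discounted before counting `alt_reads`.
#' 3. For non-Alu sites only (Alu elements host the bulk of genuine A-to-I
#'    editing; pass `strict_all = TRUE` to filter Alu sites too):
#'    `support` / `read_start` (fewer than `min_alt` supporting reads or
#'    frequency below `min_freq` after the discount; labelled
#'    `read_start` when all support lay in the first read bases and the
#'    raw, undiscounted support would have passed),
#'    `simple_repeat` (mask overlap), `splice_junction` (within
#'    `junction_dist` nt of a junction), `homopolymer` (inside a reference
#'    run of `min_run`+ identical bases), `similarity` (overlap with the
#'    high-similarity mask).
#'
#' `filter_status` records the first failing filter, or `"pass"`.
#'
#' @param sites data.frame with columns `chrom`, `pos` (0-based), `ref`,
#'   `alt`, `strand`, `total_reads`, `alt_read_offsets` (list column of
#'   0-based per-read mismatch offsets) and `context` (reference context
#'   string centred on the site).
#' @param masks Named list of [interval_mask()] objects: `snp`,
#'   `simple_repeat`, `splice_junction`, `similarity` required, `alu`
#'   optional (without it no site is Alu).
#' @param min_alt Minimum supporting reads after discount (default 3).
#' @param min_freq Minimum altered-base frequency after discount
#'   (default 0.1).
#' @param junction_dist Splice-junction exclusion distance in nt
#'   (default 4).
#' @param min_run Homopolymer run threshold (default 5).
#' @param read_start_len Number of leading read bases discounted
#'   (default 6).
#' @param strict_all Apply the non-Alu filters to Alu sites as well.
#' @return The input with added columns `in_alu`, `alt_reads` (after
#'   discount), `alt_reads_raw`, `editing_ratio`, `filter_status`,
#'   `high_confidence`, `edit_type`.
#' @export
filter_cascade <- function(sites, masks, min_alt = 3L, min_freq = 0.1,
                           junction_dist = 4L, min_run = 5L,
                           read_start_len = 6L, strict_all = FALSE) {
  for (m in c("snp", "simple_repeat", "splice_junction", "similarity"))
    if (is.null(masks[[m]])) stop("missing mask: ", m)
  n <- nrow(sites)
  offs <- sites$alt_read_offsets
  stopifnot(is.list(offs))
  raw <- lengths(offs)
  kept <- vapply(offs, function(o) sum(o >= read_start_len), integer(1))
  sites$alt_reads_raw <- raw
  sites$alt_reads <- kept
  sites$editing_ratio <- ifelse(sites$total_reads > 0,
                                kept / sites$total_reads, 0)
  sites$in_alu <- if (!is.null(masks$alu))
    mask_overlaps(masks$alu, sites$chrom, sites$pos) else rep(FALSE, n)

  status <- rep("pass", n)
  fail <- function(cond, label) {
    hit <- status == "pass" & cond
    status[hit] <<- label
  }
  fail(mask_overlaps(masks$snp, sites$chrom, sites$pos), "snp")

  sel <- if (strict_all) rep(TRUE, n) else !sites$in_alu
  low <- kept < min_alt |
    ifelse(sites$total_reads > 0, kept / sites$total_reads, 0) < min_freq
  raw_ok <- raw >= min_alt &
    ifelse(sites$total_reads > 0, raw / sites$total_reads, 0) >= min_freq
  # a site whose support lies entirely in the first read bases is the
  # random-hexamer priming artefact, not ordinary low support
  fail(sel & low & kept == 0L & raw_ok, "read_start")
  fail(sel & low, "support")
  fail(sel & mask_overlaps(masks$simple_repeat, sites$chrom, sites$pos),
       "simple_repeat")
  fail(sel & mask_within(masks$splice_junction, sites$chrom, sites$pos,
                         junction_dist), "splice_junction")
  homo <- vapply(sites$context, homopolymer_check, logical(1),
                 min_run = min_run, USE.NAMES = FALSE)
  fail(sel & homo, "homopolymer")
  fail(sel & mask_overlaps(masks$similarity, sites$chrom, sites$pos),
       "similarity")

  sites$filter_status <- status
  sites$high_confidence <- status == "pass" &
    high_confidence(sites$total_reads, sites$editing_ratio)
  sites$edit_type <- classify_edit_type(sites$ref, sites$alt, sites$strand)
  sites
}

#' Annotate editing sites with gene region and codon effect
#'
#' Assigns each site the strongest region among the gene models covering
#' it, with precedence CDS (exonic) > UTR > intronic > intergenic. For CDS
#' sites with reference sequence available, substitutes the altered base
#' into the reference codon and reports `synonymous` or `nonsynonymous`
#' under the standard genetic code.
#'
#' @param sites Editing-site data.frame (columns `chrom`, `pos`, `alt`).
#' @param models Named list of [gene_model()] objects.
#' @param genome Optional named character vector (or `DNAStringSet`) of
#'   chromosome sequences; required for codon effects.
#' @return The input with added columns `region` (`exonic`, `5'UTR`,
#'   `3'UTR`, `intronic`, `intergenic`) and `codon_effect` (`synonymous`,
#'   `nonsynonymous`, `none`).
#' @export
annotate_region <- function(sites, models, genome = NULL) {
  rank <- c(exonic = 1L, "5'UTR" = 2L, "3'UTR" = 2L, intronic = 3L,
            intergenic = 4L)
  region <- character(nrow(sites))
  effect <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    best <- "intergenic"; best_model <- NULL; best_tpos <- NA_integer_
    for (m in models) {
      if (m$chrom != sites$chrom[i]) next
      span <- range(m$exons)
      if (sites$pos[i] < span[1L] || sites$pos[i] >= span[2L]) next
      tpos <- genome_to_transcript(m, sites$pos[i])
      cand <- if (is.na(tpos)) "intronic"
              else if (!is_coding(m)) "exonic"
              else {
                r <- region_of_tpos(m, tpos)
                if (r == "CDS") "exonic" else r
              }
      if (rank[cand] < rank[best]) {
        best <- cand
        best_model <- m
        best_tpos <- tpos
      }
    }
    region[i] <- best
    effect[i] <-
      if (best == "exonic" && !is.null(best_model) &&
          is_coding(best_model) && !is.null(genome))
        codon_effect(best_model, best_tpos, sites$alt[i], genome)
      else "none"
  }
  sites$region <- region
  sites$codon_effect <- effect
  sites
}

codon_effect <- function(model, tpos, alt, genome) {
  chrom_seq <- as.character(genome[[model$chrom]])
  off <- tpos - model$cds_start_tx
  codon_tx <- model$cds_start_tx + 3L * (off %/% 3L) + 0:2
  if (any(codon_tx >= model$cds_end_tx)) return("none")  # partial codon
  gpos <- transcript_to_genome(model, codon_tx)
  base_at <- function(p) substr(chrom_seq, p + 1L, p + 1L)
  genome_bases <- vapply(gpos, base_at, "")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  tx_base <- function(b) if (model$strand == "+") b else unname(comp[b])
  ref_codon <- paste0(vapply(genome_bases, tx_base, ""), collapse = "")
  alt_codon_bases <- genome_bases
  alt_codon_bases[off %% 3L + 1L] <- toupper(alt)
  alt_codon <- paste0(vapply(alt_codon_bases, tx_base, ""), collapse = "")
  aa <- Biostrings::GENETIC_CODE[c(ref_codon, alt_codon)]
  if (anyNA(aa)) return("none")
  if (aa[1L] == aa[2L]) "synonymous" else "nonsynonymous"
}

#' Compare editing between two conditions
#'
#' Counts high-confidence events (passing sites at or above
#' `ratio_threshold` with sufficient depth) in each condition, the
#' percentage change, per-type proportions, and Kolmogorov-Smirnov
#' comparisons of the editing-ratio distributions overall and per event
#' type.
#'
#' @param sites_a,sites_b Site tables from [filter_cascade()] (conditions
#'   a = control, b = silenced).
#' @param ratio_threshold Editing-ratio threshold for counting events
#'   (default 0.2).
#' @return List with `n_a`, `n_b`, `pct_change` (percentage reduction from
#'   a to b), `type_proportions` (per condition), `ks_overall` and
#'   `ks_by_type`.
#' @export
compare_editing <- function(sites_a, sites_b, ratio_threshold = 0.2) {
  conf <- function(s) s[s$filter_status == "pass" &
                          high_confidence(s$total_reads, s$editing_ratio,
                                          min_ratio = ratio_threshold), ,
                        drop = FALSE]
  a <- conf(sites_a); b <- conf(sites_b)
  n_a <- nrow(a); n_b <- nrow(b)
  props <- function(s) if (nrow(s) == 0L) table(character()) else
    prop.table(table(s$edit_type))
  ks_by_type <- list()
  for (ty in intersect(unique(a$edit_type), unique(b$edit_type))) {
    ra <- a$editing_ratio[a$edit_type == ty]
    rb <- b$editing_ratio[b$edit_type == ty]
    if (length(ra) >= 3L && length(rb) >= 3L)
      ks_by_type[[ty]] <- cdf_compare(ra, rb)
  }
  list(n_a = n_a, n_b = n_b,
       pct_change = if (n_a == 0L) NA_real_ else 100 * (n_a - n_b) / n_a,
       type_proportions = list(a = props(a), b = props(b)),
       ks_overall = if (n_a >= 3L && n_b >= 3L)
         cdf_compare(a$editing_ratio, b$editing_ratio) else NULL,
       ks_by_type = ks_by_type)
}
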