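#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. Defaults emulate the study
#' conditions the pipeline was designed for: a few hundred transcripts
#' with realistic 5'UTR/CDS/3'UTR architectures, negative-binomial
#' background coverage at 30x depth with 50-base single-end reads, peaks of
#' 100-200 nt planted at 4-fold IP enrichment in a fifth of the genes, a
#' -1.5 log2 knockdown effect on peak-bearing genes, editing decoys
#' targeting each cascade filter, a 37% loss of true editing events in the
#' silenced condition, and unit log2 RBP stabilisation effects.
#'
#' @param n_genes Number of genes (one transcript each).
#' @param utr5_len,cds_len,utr3_len Length ranges (nt) sampled uniformly;
#'   CDS lengths are rounded to codon multiples.
#' @param n_exons Range of exon counts per transcript.
#' @param intron_len Intron length range (nt).
#' @param background_mean Mean background coverage per nt (reads).
#' @param dispersion Negative-binomial size parameter (larger = less
#'   overdispersed).
#' @param peak_fraction Fraction of genes carrying a planted peak.
#' @param peak_fold IP mean multiplier inside planted peaks (1 = null
#'   data).
#' @param peak_width Planted peak width range (nt).
#' @param read_length Read length (nt) for coverage-to-count conversion.
#' @param de_direct_effect Log2 fold change applied to peak-bearing genes
#'   in the silenced condition.
#' @param de_noise_sd Per-gene log2 fold-change noise.
#' @param editing List: `n_true` true sites, `n_decoy` per decoy class,
#'   `ratio_range`, `depth_range`, `alu_fraction` of true sites inside Alu
#'   elements, `removed_fraction` of true events absent from the silenced
#'   condition.
#' @param rbp_effect Log2 expression shift of site-bearing m6A transcripts
#'   for a stabilising RBP (destabilisers get the opposite sign).
#' @param rbp_n Genes per group in RBP simulations.
#' @param rbp_noise_sd Per-gene noise of the RBP expression deltas.
#' @param splice List: `n_null_per_type` background events per type,
#'   `n_sig_se` planted significant skipped-exon events, `n_sig_other`
#'   planted significant events per remaining type, `dpsi` planted
#'   inclusion-difference magnitude.
#' @param seed Integer seed; a fixed seed makes every generator
#'   deterministic.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200L,
                       utr5_len = c(100L, 300L),
                       cds_len = c(300L, 1500L),
                       utr3_len = c(200L, 800L),
                       n_exons = c(1L, 4L),
                       intron_len = c(200L, 2000L),
                       background_mean = 30,
                       dispersion = 10,
                       peak_fraction = 0.2,
                       peak_fold = 4,
                       peak_width = c(100L, 200L),
                       read_length = 50L,
                       de_direct_effect = -1.5,
                       de_noise_sd = 0.3,
                       editing = list(n_true = 50L, n_decoy = 10L,
                                      ratio_range = c(0.2, 0.6),
                                      depth_range = c(15L, 60L),
                                      alu_fraction = 0.5,
                                      removed_fraction = 0.37),
                       rbp_effect = -1,
                       rbp_n = 200L,
                       rbp_noise_sd = 0.5,
                       splice = list(n_null_per_type = 40L,
                                     n_sig_se = 30L, n_sig_other = 5L,
                                     dpsi = 0.3),
                       seed = 1L) {
  stopifnot(n_genes >= 1L, background_mean > 0, dispersion > 0,
            peak_fraction >= 0, peak_fraction <= 1, peak_fold >= 1,
            peak_width[1L] <= peak_width[2L], read_length >= 1L,
            seed == as.integer(seed))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate gene models
#'
#' Draws transcript architectures (5'UTR, CDS, 3'UTR lengths; 1-4 exons
#' with random introns) laid out head-to-tail on a single synthetic
#' chromosome with random strands.
#'
#' @param config A [sim_config()].
#' @return Named list of [gene_model()] objects keyed by gene id
#'   (`G0001`... with transcripts `T0001`...).
#' @export
simulate_gene_models <- function(config) {
  set.seed(config$seed)
  out <- list()
  gstart <- 0L
  for (i in seq_len(config$n_genes)) {
    utr5 <- sample(config$utr5_len[1L]:config$utr5_len[2L], 1L)
    cds <- 3L * sample((config$cds_len[1L] %/% 3L):(config$cds_len[2L] %/% 3L),
                       1L)
    utr3 <- sample(config$utr3_len[1L]:config$utr3_len[2L], 1L)
    len <- utr5 + cds + utr3
    nex <- sample(config$n_exons[1L]:config$n_exons[2L], 1L)
    cuts <- if (nex > 1L) sort(sample(seq_len(len - 1L), nex - 1L)) else
      integer()
    widths <- diff(c(0L, cuts, len))
    introns <- if (nex > 1L)
      sample(config$intron_len[1L]:config$intron_len[2L], nex - 1L,
             replace = TRUE) else integer()
    starts <- gstart + cumsum(c(0L, widths[-nex] + introns))
    strand <- sample(c("+", "-"), 1L)
    gid <- sprintf("G%04d", i)
    tid <- sprintf("T%04d", i)
    # transcript-coordinate CDS bounds are strand-independent
    out[[gid]] <- gene_model(gid, tid, "chrS", strand,
                             cbind(starts, starts + widths),
                             cds_start_tx = utr5, cds_end_tx = utr5 + cds)
    gstart <- max(starts + widths) + 5000L
  }
  out
}

#' Simulate MeRIP IP and input coverage with planted peaks
#'
#' Background coverage at every transcript nucleotide is drawn
#' negative-binomially with the configured mean and dispersion in both
#' libraries; inside each planted peak the IP mean is multiplied by
#' `peak_fold`. With `peak_fold = 1` the IP and input tracks are drawn
#' from identical distributions (null data).
#'
#' @param config A [sim_config()].
#' @param models Optional pre-built gene models (defaults to
#'   [simulate_gene_models()] under the same seed).
#' @return List with `models`, `ip` and `input` ([coverage_set()]s) and
#'   `truth` (data.frame `gene_id`, `transcript_id`, `peak_start`,
#'   `peak_end` of planted peaks).
#' @export
simulate_rip <- function(config, models = NULL) {
  if (is.null(models)) models <- simulate_gene_models(config)
  set.seed(config$seed + 1L)
  lens <- vapply(models, `[[`, integer(1), "transcript_length")
  if (config$peak_width[2L] > min(lens))
    stop("peak_width exceeds the shortest transcript length")
  n_peak <- round(config$peak_fraction * length(models))
  peak_genes <- sample(names(models), n_peak)
  ip <- list(); input <- list()
  truth <- data.frame(gene_id = character(), transcript_id = character(),
                      peak_start = integer(), peak_end = integer())
  for (gid in names(models)) {
    m <- models[[gid]]
    L <- m$transcript_length
    mu_ip <- rep(config$background_mean, L)
    if (gid %in% peak_genes) {
      # plant on the 50-nt scan grid: the caller resolves boundaries in
      # grid units, so recovery then measures detection, not quantisation
      w_opts <- seq.int(config$peak_width[1L], config$peak_width[2L],
                        by = 50L)
      w <- w_opts[sample.int(length(w_opts), 1L)]
      s <- 50L * (sample.int((L - w) %/% 50L + 1L, 1L) - 1L)
      mu_ip[(s + 1L):(s + w)] <- config$background_mean * config$peak_fold
      truth <- rbind(truth, data.frame(gene_id = gid,
                                       transcript_id = m$transcript_id,
                                       peak_start = s, peak_end = s + w))
    }
    ip[[m$transcript_id]] <- stats::rnbinom(L, mu = mu_ip,
                                            size = config$dispersion)
    input[[m$transcript_id]] <- stats::rnbinom(
      L, mu = config$background_mean, size = config$dispersion)
  }
  list(models = models,
       ip = coverage_set(ip, read_length = config$read_length),
       input = coverage_set(input, read_length = config$read_length),
       truth = truth)
}

#' Fraction of planted peaks recovered by a peak call
#'
#' A planted peak is recovered when a called peak on the same transcript
#' has both boundaries within `tol` nt of the planted ones.
#'
#' @param peaks Peak data.frame from [call_peaks()].
#' @param truth Truth table from [simulate_rip()].
#' @param tol Boundary tolerance in nt (default 50).
#' @return Fraction in `[0, 1]` (`NA` with empty truth).
#' @export
peak_recovery <- function(peaks, truth, tol = 50L) {
  if (nrow(truth) == 0L) return(NA_real_)
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    j <- which(peaks$transcript_id == truth$transcript_id[i] &
                 abs(peaks$start - truth$peak_start[i]) <= tol &
                 abs(peaks$end - truth$peak_end[i]) <= tol)
    length(j) > 0L
  }, logical(1))
  mean(hit)
}

#' Simulate a differential-expression table
#'
#' Peak-bearing genes receive a log2 fold change centred on
#' `de_direct_effect`; all other genes are centred on zero, with common
#' per-gene noise. P-values come from the implied two-sided z-test of the
#' observed fold change against its noise scale, BH-adjusted, so with a
#' zero effect planted and non-planted genes are indistinguishable.
#' Biotypes and FPKM-like abundances are drawn with m6A (peak-bearing)
#' genes more abundant and lincRNAs less abundant.
#'
#' @param config A [sim_config()].
#' @param truth Truth table from [simulate_rip()] identifying peak-bearing
#'   genes.
#' @return data.frame with `gene_id`, `log2_fold_change`, `p_adjusted`,
#'   `biotype`, `fpkm`, `m6a`.
#' @export
simulate_de <- function(config, truth) {
  set.seed(config$seed + 2L)
  ids <- sprintf("G%04d", seq_len(config$n_genes))
  m6a <- ids %in% truth$gene_id
  lfc <- ifelse(m6a, config$de_direct_effect, 0) +
    stats::rnorm(config$n_genes, 0, config$de_noise_sd)
  p <- 2 * stats::pnorm(-abs(lfc) / config$de_noise_sd)
  biotype <- sample(c("protein_coding", "lincRNA", "antisense", "other"),
                    config$n_genes, replace = TRUE,
                    prob = c(0.8, 0.1, 0.05, 0.05))
  fpkm <- stats::rlnorm(config$n_genes,
                        meanlog = 2 + m6a - (biotype == "lincRNA"),
                        sdlog = 1)
  data.frame(gene_id = ids, log2_fold_change = lfc,
             p_adjusted = stats::p.adjust(p, method = "BH"),
             biotype = biotype, fpkm = fpkm, m6a = m6a)
}

random_base <- function(n, exclude = NULL) {
  pool <- setdiff(c("A", "C", "G", "T"), exclude)
  sample(pool, n, replace = TRUE)
}

edit_site_bases <- function(type, strand) {
  if (type == "A_to_I") {
    if (strand == "-") c("T", "C") else c("A", "G")
  } else {
    if (strand == "-") c("G", "A") else c("C", "T")
  }
}

make_context <- function(ref, width = 21L) {
  center <- (width + 1L) %/% 2L
  ctx <- random_base(width)
  ctx[center] <- ref
  # keep the reference run covering the site at length 1
  ctx[center - 1L] <- random_base(1L, exclude = ref)
  ctx[center + 1L] <- random_base(1L, exclude = ref)
  paste(ctx, collapse = "")
}

#' Simulate editing-site candidates with per-filter decoys
#'
#' Emits `n_true` genuine editing sites that pass every cascade filter
#' plus, for each of the seven decoy classes, `n_decoy` sites violating
#' exactly that filter: `snp` (polymorphism overlap), `support` (fewer
#' than 3 clean supporting reads), `read_start` (support only within the
#' first six read bases), `simple_repeat`, `splice_junction` (within 4 nt
#' of a junction), `homopolymer` (inside a reference run of 5+), and
#' `similarity`. A configured fraction of true sites lies in Alu elements.
#' The silenced condition drops `removed_fraction` of the true events.
#'
#' @param config A [sim_config()].
#' @return List with `sites` (control condition), `sites_silenced`,
#'   `masks` (named [interval_mask()] list) and `truth` (data.frame
#'   `site_id`, `class`, `expected_status`).
#' @export
simulate_editing <- function(config) {
  set.seed(config$seed + 3L)
  ed <- config$editing
  rl <- config$read_length
  classes <- c(rep("true", ed$n_true),
               rep(c("snp", "support", "read_start", "simple_repeat",
                     "splice_junction", "homopolymer", "similarity"),
                   each = ed$n_decoy))
  n <- length(classes)
  pos <- 1000L * seq_len(n)
  strand <- sample(c("+", "-", "."), n, replace = TRUE,
                   prob = c(0.45, 0.45, 0.1))
  type <- sample(c("A_to_I", "C_to_U"), n, replace = TRUE,
                 prob = c(0.8, 0.2))
  depth <- sample(ed$depth_range[1L]:ed$depth_range[2L], n, replace = TRUE)
  ratio <- stats::runif(n, ed$ratio_range[1L], ed$ratio_range[2L])
  alt_n <- pmin(depth, ceiling(ratio * depth))

  ref <- character(n); alt <- character(n)
  offsets <- vector("list", n)
  context <- character(n)
  mask_rows <- list(snp = NULL, simple_repeat = NULL,
                    splice_junction = NULL, similarity = NULL, alu = NULL)
  add_mask <- function(name, start, end) {
    mask_rows[[name]] <<- rbind(mask_rows[[name]],
                                data.frame(chrom = "chrE", start = start,
                                           end = end))
  }
  n_alu <- round(ed$alu_fraction * ed$n_true)
  alu_true <- sample(which(classes == "true"), n_alu)
  for (i in seq_len(n)) {
    ra <- edit_site_bases(type[i], strand[i])
    ref[i] <- ra[1L]; alt[i] <- ra[2L]
    context[i] <- make_context(ref[i])
    offsets[[i]] <- sample(6L:(rl - 1L), alt_n[i], replace = TRUE)
    cls <- classes[i]
    if (cls == "snp") add_mask("snp", pos[i], pos[i] + 1L)
    if (cls == "support") {
      alt_n[i] <- sample(0:2, 1L)
      offsets[[i]] <- if (alt_n[i] > 0L)
        sample(6L:(rl - 1L), alt_n[i], replace = TRUE) else integer()
    }
    if (cls == "read_start")
      offsets[[i]] <- sample(0:5, alt_n[i], replace = TRUE)
    if (cls == "simple_repeat") add_mask("simple_repeat", pos[i] - 5L,
                                         pos[i] + 6L)
    if (cls == "splice_junction") {
      d <- sample(c(-4:-1, 1:4), 1L)
      add_mask("splice_junction", pos[i] + d, pos[i] + d + 1L)
    }
    if (cls == "homopolymer") {
      ctx <- strsplit(context[i], "")[[1]]
      ctx[9:13] <- ref[i]
      context[i] <- paste(ctx, collapse = "")
    }
    if (cls == "similarity") add_mask("similarity", pos[i] - 10L,
                                      pos[i] + 10L)
    if (i %in% alu_true) add_mask("alu", pos[i] - 50L, pos[i] + 50L)
  }
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer())
  masks <- lapply(names(mask_rows), function(nm)
    interval_mask(nm, if (is.null(mask_rows[[nm]])) empty else
      mask_rows[[nm]]))
  names(masks) <- names(mask_rows)

  sites <- data.frame(site_id = sprintf("E%04d", seq_len(n)),
                      chrom = "chrE", pos = pos, ref = ref, alt = alt,
                      strand = strand, total_reads = depth)
  sites$alt_read_offsets <- offsets
  sites$context <- context

  truth <- data.frame(site_id = sites$site_id, class = classes,
                      expected_status = ifelse(classes == "true", "pass",
                                               classes))
  n_rm <- round(ed$removed_fraction * ed$n_true)
  removed <- sample(which(classes == "true"), n_rm)
  list(sites = sites,
       sites_silenced = sites[-removed, , drop = FALSE],
       masks = masks, truth = truth)
}

#' Simulate an rMATS-format splicing event table
#'
#' Background events of all five types (SE, RI, A5SS, A3SS, MXE) fail the
#' retention filters (high FDR, small inclusion difference, or low
#' counts); planted significant events carry FDR < 0.05, inclusion
#' differences of the configured magnitude and counts of at least 10 in
#' both conditions. When RIP truth is supplied, planted skipped-exon
#' events fall on m6A (peak-bearing) genes with the alternative exon
#' overlapping the planted peak, emulating m6A-dependent exon skipping;
#' background SE events fall on non-peak genes.
#'
#' @param config A [sim_config()].
#' @param truth Optional truth table from [simulate_rip()].
#' @return List with `events` (data.frame in the [filter_events()] layout
#'   plus `exon_tx_start`, `exon_tx_end`, `planted`) and `n_planted`.
#' @export
simulate_splice_table <- function(config, truth = NULL) {
  set.seed(config$seed + 4L)
  sp <- config$splice
  types <- c("SE", "RI", "A5SS", "A3SS", "MXE")
  rows <- list()
  m6a_genes <- if (!is.null(truth)) truth$gene_id else character()
  other_genes <- setdiff(sprintf("G%04d", seq_len(config$n_genes)),
                         m6a_genes)
  mk <- function(type, gene, fdr, dpsi, counts_lo, exon = c(NA, NA),
                 planted = FALSE) {
    psi1 <- stats::runif(1L, 0.25, 0.75)
    psi2 <- min(max(psi1 - dpsi, 0), 1)
    data.frame(event_type = type, gene_id = gene,
               IJC_1 = sample(counts_lo:100L, 1L),
               SJC_1 = sample(counts_lo:100L, 1L),
               IJC_2 = sample(counts_lo:100L, 1L),
               SJC_2 = sample(counts_lo:100L, 1L),
               IncLevel1 = psi1, IncLevel2 = psi2,
               IncLevelDifference = psi1 - psi2, FDR = fdr,
               exon_tx_start = exon[1L], exon_tx_end = exon[2L],
               planted = planted)
  }
  for (ty in types) {
    n_sig <- if (ty == "SE") sp$n_sig_se else sp$n_sig_other
    for (k in seq_len(n_sig)) {
      dpsi <- sp$dpsi * sample(c(-1, 1), 1L) *
        stats::runif(1L, 0.8, 1.2)
      if (ty == "SE" && length(m6a_genes) > 0L) {
        i <- sample(seq_len(nrow(truth)), 1L)
        exon <- c(truth$peak_start[i] + 10L, truth$peak_start[i] + 110L)
        rows[[length(rows) + 1L]] <-
          mk(ty, truth$gene_id[i], stats::runif(1L, 0, 0.01), dpsi, 20L,
             exon, planted = TRUE)
      } else {
        rows[[length(rows) + 1L]] <-
          mk(ty, sample(other_genes, 1L), stats::runif(1L, 0, 0.01), dpsi,
             20L, planted = TRUE)
      }
    }
    for (k in seq_len(sp$n_null_per_type)) {
      fail_mode <- sample(c("fdr", "dpsi", "counts"), 1L,
                          prob = c(0.6, 0.2, 0.2))
      gene <- sample(other_genes, 1L)
      rows[[length(rows) + 1L]] <- switch(
        fail_mode,
        fdr = mk(ty, gene, stats::runif(1L, 0.2, 1),
                 stats::runif(1L, -0.3, 0.3), 20L),
        dpsi = mk(ty, gene, stats::runif(1L, 0, 0.01),
                  stats::runif(1L, -0.04, 0.04), 20L),
        counts = {
          r <- mk(ty, gene, stats::runif(1L, 0, 0.01),
                  sp$dpsi * sample(c(-1, 1), 1L), 20L)
          r$SJC_1 <- sample(0:9, 1L)
          r
        })
    }
  }
  events <- do.call(rbind, rows)
  rownames(events) <- NULL
  list(events = events, n_planted = sum(events$planted))
}

#' Simulate RBP-site expression effects
#'
#' For each simulated RBP, draws the per-gene differential expression
#' (silenced minus control) of m6A transcripts with and without the RBP's
#' binding site. Stabilisers shift the with-site group by `rbp_effect`
#' (negative: silencing destabilises their targets), destabilisers by the
#' opposite sign, neutral RBPs not at all.
#'
#' @param config A [sim_config()].
#' @param n_rbp Number of RBPs.
#' @param composition Named counts of true classes; must sum to `n_rbp`.
#' @return List with `rbps` (per-RBP list of `with`/`without` delta
#'   vectors) and `truth` (data.frame `rbp`, `class`).
#' @export
simulate_rbp_sites <- function(config, n_rbp = 100L,
                               composition = c(stabilizer = 40L,
                                               destabilizer = 40L,
                                               neutral = 20L)) {
  stopifnot(sum(composition) == n_rbp)
  set.seed(config$seed + 5L)
  shift_of <- c(stabilizer = -abs(config$rbp_effect),
                destabilizer = abs(config$rbp_effect), neutral = 0)
  cls <- sample(rep(names(composition), composition))
  rbps <- lapply(seq_len(n_rbp), function(i) {
    list(with = stats::rnorm(config$rbp_n, shift_of[cls[i]],
                             config$rbp_noise_sd),
         without = stats::rnorm(config$rbp_n, 0, config$rbp_noise_sd))
  })
  names(rbps) <- sprintf("RBP%03d", seq_len(n_rbp))
  list(rbps = rbps,
       truth = data.frame(rbp = names(rbps), class = cls))
}
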