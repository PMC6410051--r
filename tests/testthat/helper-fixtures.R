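# Shared fixtures built in code.

# Two-exon plus-strand model: exons [100,200)+[300,400), 200 nt transcript,
# CDS occupying transcript [50,170).
toy_model_plus <- function() {
  gene_model("gP", "tP", "chr1", "+", cbind(c(100L, 300L), c(200L, 400L)),
             cds_start_tx = 50L, cds_end_tx = 170L)
}

toy_model_minus <- function() {
  gene_model("gM", "tM", "chr1", "-", cbind(c(100L, 300L), c(200L, 400L)),
             cds_start_tx = 50L, cds_end_tx = 170L)
}

# Coding model with segment lengths utr5/cds/utr3 = 100/300/200 on one exon.
toy_model_segments <- function() {
  gene_model("gS", "tS", "chr1", "+", cbind(0L, 600L),
             cds_start_tx = 100L, cds_end_tx = 400L)
}

random_model <- function(i, n_exons = 3L) {
  widths <- sample(50:300, n_exons, replace = TRUE)
  gaps <- sample(100:500, n_exons, replace = TRUE)
  starts <- cumsum(gaps) + cumsum(c(0L, widths[-n_exons]))
  gene_model(paste0("g", i), paste0("t", i), "chr1",
             sample(c("+", "-"), 1L), cbind(starts, starts + widths))
}

toy_peaks <- function(tx, start, end, score, gene = tx) {
  data.frame(gene_id = gene, transcript_id = tx, start = start, end = end,
             enrichment_score = score)
}

# Brute-force one-sided Fisher p: tail sum of exact hypergeometric terms.
fisher_oracle <- function(read_ip, gene_ip, read_ctrl, gene_ctrl) {
  k <- read_ip + read_ctrl
  xs <- max(0, k - gene_ctrl):min(gene_ip, k)
  terms <- exp(lchoose(gene_ip, xs) + lchoose(gene_ctrl, k - xs) -
                 lchoose(gene_ip + gene_ctrl, k))
  sum(terms[xs >= read_ip])
}

# Quadratic-time BH reference: adj_i = min over {j : p_j >= p_i} of
# min(1, p_j * n / rank_j).
bh_oracle <- function(p) {
  n <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(n), function(i) {
    cand <- vapply(seq_len(n), function(j)
      if (p[j] >= p[i]) min(1, p[j] * n / r[j]) else Inf, numeric(1))
    min(cand)
  }, numeric(1))
}

# Regex-free brute-force IUPAC motif scan.
motif_oracle <- function(sequence, motif = "RRAC") {
  iupac <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                Y = c("C", "T"))
  s <- strsplit(sequence, "")[[1]]
  m <- strsplit(motif, "")[[1]]
  hits <- 0L
  for (i in seq_len(length(s) - length(m) + 1L)) {
    ok <- TRUE
    for (j in seq_along(m))
      if (!s[i + j - 1L] %in% iupac[[m[j]]]) { ok <- FALSE; break }
    if (ok) hits <- hits + 1L
  }
  hits
}

# Gene universe reconstructed from published per-class component counts,
# run through the real DE-threshold and classification path.
bookkeeping_fixture <- function() {
  n_dir_down <- 1461L; n_dir_up <- 6L; n_dir_unreg <- 234L
  n_ind_down <- 7261L; n_ind_up <- 8011L
  n_pc_ind_down <- 6128L; n_pc_ind_up <- 3702L
  n_unaffected <- 500L
  n <- n_dir_down + n_dir_up + n_dir_unreg + n_ind_down + n_ind_up +
    n_unaffected
  ids <- sprintf("g%05d", seq_len(n))
  lfc <- c(rep(-1, n_dir_down), rep(1, n_dir_up), rep(0, n_dir_unreg),
           rep(-1, n_ind_down), rep(1, n_ind_up), rep(0, n_unaffected))
  padj <- ifelse(lfc == 0, 0.9, 0.001)
  biotype <- c(rep("protein_coding", n_dir_down + n_dir_up + n_dir_unreg),
               rep(c("protein_coding", "lincRNA"),
                   c(n_pc_ind_down, n_ind_down - n_pc_ind_down)),
               rep(c("protein_coding", "lincRNA"),
                   c(n_pc_ind_up, n_ind_up - n_pc_ind_up)),
               rep("protein_coding", n_unaffected))
  de <- data.frame(gene_id = ids, log2_fold_change = lfc,
                   p_adjusted = padj, biotype = biotype)
  n_direct <- n_dir_down + n_dir_up + n_dir_unreg
  gene_classes <- data.frame(gene_id = ids[seq_len(n_direct)],
                             peak_class = "lost")
  classify_targets(gene_classes, apply_de_thresholds(de))
}
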