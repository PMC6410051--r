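test_that("peak-set comparison classifies lost, reduced, common, independent", {
  ctrl <- toy_peaks(c("t1", "t2", "t3", "t4"),
                    c(100L, 100L, 100L, 100L), c(200L, 200L, 200L, 200L),
                    c(3, 3, 3, 3))
  sil <- toy_peaks(c("t2", "t3", "t4", "t5"),
                   c(150L, 150L, 150L, 0L), c(250L, 250L, 250L, 100L),
                   c(2.9, 1.5, 4.5, 2))
  cmp <- compare_peak_sets(ctrl, sil, reduction_threshold = 1)
  ctrl_cls <- cmp$peaks$peak_class[cmp$peaks$condition == "control"]
  expect_equal(ctrl_cls, c("lost", "common", "reduced", "independent"))
  sil_cls <- cmp$peaks$peak_class[cmp$peaks$condition == "silenced"]
  expect_equal(sil_cls, c("common", "reduced", "independent", "independent"))
  # gene-level priority lost > reduced > common > independent
  gc <- stats::setNames(cmp$genes$peak_class, cmp$genes$gene_id)
  expect_equal(unname(gc[c("t1", "t2", "t3", "t5")]),
               c("lost", "common", "reduced", "independent"))
})

test_that("peak-set comparison is label-symmetric under input swap", {
  set.seed(21)
  a <- toy_peaks(paste0("t", 1:15), 50L * sample(0:8, 15, TRUE),
                 0L, stats::runif(15, 1, 5))
  a$end <- a$start + 100L
  b <- toy_peaks(paste0("t", sample(1:20, 12)),
                 50L * sample(0:8, 12, TRUE), 0L, stats::runif(12, 1, 5))
  b$end <- b$start + 100L
  ab <- compare_peak_sets(a, b)
  ba <- compare_peak_sets(b, a)
  cls_a_in_ab <- ab$peaks$peak_class[ab$peaks$condition == "control"]
  cls_a_in_ba <- ba$peaks$peak_class[ba$peaks$condition == "silenced"]
  # lost <-> independent for non-overlapping peaks; common preserved;
  # a score drop seen one way is a gain seen the other way
  expect_equal(cls_a_in_ba[cls_a_in_ab == "lost"],
               rep("independent", sum(cls_a_in_ab == "lost")))
  expect_equal(cls_a_in_ba[cls_a_in_ab == "common"],
               rep("common", sum(cls_a_in_ab == "common")))
  expect_equal(cls_a_in_ba[cls_a_in_ab == "reduced"],
               rep("independent", sum(cls_a_in_ab == "reduced")))
  expect_true(all(cls_a_in_ba[cls_a_in_ab == "independent"] %in%
                    c("lost", "reduced")))
})

test_that("DE thresholds are strict on both fold change and adjusted p", {
  de <- data.frame(gene_id = c("a", "b", "c", "d"),
                   log2_fold_change = c(-1, -0.5, -2, 1),
                   p_adjusted = c(0.001, 0.001, 0.05, 0.01))
  out <- apply_de_thresholds(de)
  expect_equal(out$regulated, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(out$direction, c("down", "none", "none", "up"))
})

test_that("target classes follow the direct/indirect rules and partition genes", {
  gene_classes <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                             peak_class = c("lost", "reduced", "common",
                                            "independent"))
  de <- apply_de_thresholds(data.frame(
    gene_id = c("g1", "g2", "g3", "g5", "g6"),
    log2_fold_change = c(-2, 0, 2, 1.5, 0.1),
    p_adjusted = c(0.001, 0.9, 0.001, 0.001, 0.9)))
  rec <- classify_targets(gene_classes, de)
  cls <- stats::setNames(rec$target_class, rec$gene_id)
  expect_equal(unname(cls[c("g1", "g2", "g3", "g4", "g5", "g6")]),
               c("direct_regulated", "direct_unregulated",
                 "indirect_regulated", "unaffected", "indirect_regulated",
                 "unaffected"))
  expect_equal(nrow(rec), 6L)  # universe = union of both inputs
  expect_false(any(is.na(cls)))
})

test_that("target summary percentages match a hand-computed oracle", {
  rec <- data.frame(
    gene_id = sprintf("g%02d", 1:10),
    peak_class = c("lost", "lost", "reduced", "none", "none", "none",
                   "none", "none", "common", "independent"),
    regulated = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE,
                  TRUE, FALSE),
    direction = c("down", "up", "none", "down", "down", "up", "none",
                  "none", "up", "none"),
    biotype = c(rep("protein_coding", 8), "lincRNA", "protein_coding"))
  rec$target_class <- ifelse(
    rec$peak_class %in% c("lost", "reduced"),
    ifelse(rec$regulated, "direct_regulated", "direct_unregulated"),
    ifelse(rec$regulated, "indirect_regulated", "unaffected"))
  s <- summarize_targets(rec)
  expect_equal(unname(s$counts[c("direct", "direct_regulated",
                                 "indirect_regulated")]), c(3, 2, 4))
  expect_equal(s$percentages[["direct_regulated"]], 100 * 2 / 3)
  expect_equal(s$percentages[["direct_regulated_down"]], 50)
  expect_equal(s$percentages[["indirect_of_regulated"]], 100 * 4 / 6)
  expect_equal(s$percentages[["indirect_down"]], 50)
  expect_equal(s$percentages[["pc_indirect_up"]], 100 / 3)
  # degenerate: all unaffected
  rec0 <- rec
  rec0$target_class <- "unaffected"
  s0 <- summarize_targets(rec0)
  expect_true(all(is.na(s0$percentages)))
})

test_that("CDF comparison reports KS distance, p and median shift", {
  x <- c(1, 2, 3, 4, 5)
  same <- cdf_compare(x, x)
  expect_equal(same$D, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$median_shift, 0)
  disj <- cdf_compare(rep(0, 4), rep(1, 4))
  expect_equal(disj$D, 1)
  set.seed(11)
  shift <- cdf_compare(stats::rnorm(500, 1), stats::rnorm(500, 0))
  expect_lt(shift$p_value, 1e-6)
  expect_gt(shift$median_shift, 0.5)
  expect_error(cdf_compare(numeric(0), x), "non-empty")
})

test_that("RBP classification separates stabilizers, destabilizers, neutrals", {
  set.seed(7)
  stab <- classify_rbp(stats::rnorm(200, -1, 0.5), stats::rnorm(200, 0, 0.5))
  expect_equal(stab$class, "stabilizer")
  dest <- classify_rbp(stats::rnorm(200, 1, 0.5), stats::rnorm(200, 0, 0.5))
  expect_equal(dest$class, "destabilizer")
  x <- stats::rnorm(200, 0, 0.5)
  expect_equal(classify_rbp(x, x)$class, "neutral")
})

test_that("abundance CDFs split by m6A status within biotype", {
  set.seed(23)
  expr <- data.frame(
    gene_id = sprintf("g%03d", 1:300),
    fpkm = c(stats::rlnorm(100, 3), stats::rlnorm(100, 2),
             stats::rlnorm(50, 1.5), stats::rlnorm(50, 1)),
    m6a = rep(c(TRUE, FALSE, TRUE, FALSE), c(100, 100, 50, 50)),
    biotype = rep(c("protein_coding", "lincRNA"), c(200, 100)))
  res <- abundance_by_group(expr)
  expect_named(res, c("protein_coding", "lincRNA"))
  expect_lt(res$protein_coding$test$p_value, 0.01)
  expect_gt(res$protein_coding$test$median_shift, 0)
  expect_true(all(res$lincRNA$cdf$ecdf > 0 & res$lincRNA$cdf$ecdf <= 1))
  # single group: CDF only, no test
  one <- abundance_by_group(expr[expr$m6a & expr$biotype == "lincRNA", ],
                            biotypes = "lincRNA")
  expect_null(one$lincRNA$test)
  expect_error(abundance_by_group(expr, biotypes = "snoRNA"), "snoRNA")
})
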