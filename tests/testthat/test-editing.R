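empty_masks <- function() {
  e <- data.frame(chrom = character(), start = integer(), end = integer())
  list(snp = interval_mask("snp", e),
       simple_repeat = interval_mask("simple_repeat", e),
       splice_junction = interval_mask("splice_junction", e),
       similarity = interval_mask("similarity", e))
}

site_row <- function(pos, offsets, total = 30L, ref = "A", alt = "G",
                     strand = "+", context = "CTCTCTCTCTATCTCTCTCTC") {
  df <- data.frame(chrom = "chrE", pos = pos, ref = ref, alt = alt,
                   strand = strand, total_reads = total)
  df$alt_read_offsets <- list(offsets)
  df$context <- context
  df
}

test_that("filter cascade removes each decoy for exactly its own reason", {
  sim <- sim_config(seed = 3)
  ed <- simulate_editing(sim)
  expect_equal(nrow(ed$sites),
               sim$editing$n_true + 7L * sim$editing$n_decoy)
  out <- filter_cascade(ed$sites, ed$masks)
  expect_identical(out$filter_status, ed$truth$expected_status)
  expect_equal(sum(out$filter_status == "pass"), sim$editing$n_true)
  # the low-support decoys have at most 2 supporting reads by construction
  low <- out[ed$truth$class == "support", ]
  expect_true(all(low$alt_reads_raw <= 2L))
})

test_that("filter order is stable under input shuffling", {
  sim <- sim_config(seed = 5)
  ed <- simulate_editing(sim)
  out <- filter_cascade(ed$sites, ed$masks)
  set.seed(99)
  perm <- sample(nrow(ed$sites))
  out_perm <- filter_cascade(ed$sites[perm, ], ed$masks)
  expect_identical(out_perm$filter_status[order(perm)], out$filter_status)
})

test_that("read-start discount is applied before the support filter", {
  masks <- empty_masks()
  # offsets [2,3,4,60]: three supports fall in the first six read bases
  s <- filter_cascade(site_row(100L, c(2L, 3L, 4L, 60L), total = 30L),
                      masks)
  expect_equal(s$alt_reads, 1L)
  expect_equal(s$filter_status, "support")
  # support entirely within the first six bases: the priming artefact
  s2 <- filter_cascade(site_row(100L, c(0L, 1L, 2L, 3L, 4L), total = 20L),
                       masks)
  expect_equal(s2$filter_status, "read_start")
  # clean supports pass
  s3 <- filter_cascade(site_row(100L, c(10L, 20L, 30L, 40L), total = 20L),
                       masks)
  expect_equal(s3$filter_status, "pass")
})

test_that("Alu sites bypass the non-Alu filters unless strict_all", {
  masks <- empty_masks()
  masks$alu <- interval_mask("alu", data.frame(chrom = "chrE", start = 50L,
                                               end = 150L))
  weak <- site_row(100L, c(10L, 20L), total = 30L)  # only 2 supports
  expect_equal(filter_cascade(weak, masks)$filter_status, "pass")
  expect_equal(filter_cascade(weak, masks,
                              strict_all = TRUE)$filter_status, "support")
  # the SNP filter applies to Alu sites regardless
  masks$snp <- interval_mask("snp", data.frame(chrom = "chrE", start = 100L,
                                               end = 101L))
  expect_equal(filter_cascade(weak, masks)$filter_status, "snp")
})

test_that("junction proximity boundary is 4 nt inside, 5 nt outside", {
  masks <- empty_masks()
  masks$splice_junction <- interval_mask(
    "splice_junction", data.frame(chrom = "chrE", start = 104L, end = 105L))
  near <- site_row(100L, c(10L, 20L, 30L, 40L))
  expect_equal(filter_cascade(near, masks)$filter_status,
               "splice_junction")
  masks$splice_junction <- interval_mask(
    "splice_junction", data.frame(chrom = "chrE", start = 105L, end = 106L))
  expect_equal(filter_cascade(near, masks)$filter_status, "pass")
})

test_that("missing masks are reported by name", {
  masks <- empty_masks()
  masks$similarity <- NULL
  expect_error(filter_cascade(site_row(1L, c(10L, 20L, 30L)), masks),
               "similarity")
})

test_that("homopolymer flag requires a run of five covering the site", {
  expect_true(homopolymer_check("CTCTAAAAACTCT", 7L))   # inside AAAAA
  expect_false(homopolymer_check("CTCTAAAACTCTC", 7L))  # run of 4
  # adjacent to a 6-run but not inside it
  expect_false(homopolymer_check("AAAAAAGTCTCTC", 7L))
  expect_true(homopolymer_check("AAAAAAGTCTCTC", 3L))
})

test_that("high-confidence bounds are inclusive", {
  expect_true(high_confidence(10, 0.2))
  expect_false(high_confidence(9, 0.5))
  expect_false(high_confidence(100, 0.19))
})

test_that("edit typing follows strand and is complement-consistent", {
  expect_equal(classify_edit_type("A", "G", "+"), "A_to_I")
  expect_equal(classify_edit_type("T", "C", "-"), "A_to_I")
  expect_equal(classify_edit_type("G", "A", "."), "C_to_U")
  expect_equal(classify_edit_type("A", "G", "-"), "other")
  expect_equal(classify_edit_type("G", "C", "+"), "other")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- c("+" = "-", "-" = "+")
  set.seed(31)
  for (i in 1:40) {
    ref <- sample(names(comp), 1); alt <- sample(setdiff(names(comp), ref), 1)
    st <- sample(c("+", "-"), 1)
    expect_equal(classify_edit_type(comp[[ref]], comp[[alt]], flip[[st]]),
                 classify_edit_type(ref, alt, st))
  }
})

test_that("region annotation ranks CDS > UTR > intronic > intergenic and calls codon effects", {
  # 600-nt single-exon gene at [1000,1600), CDS tx [100,400)
  m <- gene_model("g1", "t1", "chrQ", "+", cbind(1000L, 1600L),
                  cds_start_tx = 100L, cds_end_tx = 400L)
  m2 <- gene_model("g2", "t2", "chrQ", "+", cbind(c(3000L, 3500L),
                                                  c(3200L, 3700L)))
  chrom <- paste(rep("T", 4000), collapse = "")
  # codon 1 of the CDS at tx [100,103) = genomic [1100,1103): GGA (Gly)
  substr(chrom, 1101, 1103) <- "GGA"
  # codon at tx [103,106): AAA (Lys)
  substr(chrom, 1104, 1106) <- "AAA"
  genome <- list(chrQ = chrom)
  sites <- data.frame(chrom = "chrQ",
                      pos = c(1102L, 1104L, 1050L, 1500L, 3300L, 500L),
                      alt = c("G", "G", "G", "G", "A", "A"))
  out <- annotate_region(sites, list(g1 = m, g2 = m2), genome)
  expect_equal(out$region, c("exonic", "exonic", "5'UTR", "3'UTR",
                             "intronic", "intergenic"))
  # GGA -> GGG stays Gly; AAA -> AGA is Lys -> Arg
  expect_equal(out$codon_effect[1:2], c("synonymous", "nonsynonymous"))
  expect_equal(out$codon_effect[3:6], rep("none", 4))
})

test_that("editing comparison counts events and detects ratio shifts", {
  sim <- sim_config(seed = 9)
  ed <- simulate_editing(sim)
  a <- filter_cascade(ed$sites, ed$masks)
  same <- compare_editing(a, a)
  expect_equal(same$pct_change, 0)
  expect_equal(same$ks_overall$p_value, 1)
  b <- filter_cascade(ed$sites_silenced, ed$masks)
  cmp <- compare_editing(a, b)
  expect_equal(cmp$n_a, sim$editing$n_true)
  expect_equal(cmp$pct_change,
               100 * round(0.37 * sim$editing$n_true) / sim$editing$n_true)
  # a genuine ratio shift is detected
  shifted <- a[a$filter_status == "pass", ]
  shifted$editing_ratio <- pmin(shifted$editing_ratio + 0.25, 1)
  ks <- compare_editing(a, shifted)$ks_overall
  expect_lt(ks$p_value, 0.01)
})
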