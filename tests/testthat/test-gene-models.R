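test_that("genome/transcript projection follows exon structure and strand", {
  m <- toy_model_plus()
  expect_equal(genome_to_transcript(m, 150), 50L)
  expect_true(is.na(genome_to_transcript(m, 250)))
  expect_true(is.na(genome_to_transcript(m, 50)))
  expect_equal(transcript_to_genome(m, 50), 150L)
  expect_equal(transcript_to_genome(m, 0), 100L)

  neg <- toy_model_minus()
  expect_equal(genome_to_transcript(neg, 399), 0L)
  expect_equal(transcript_to_genome(neg, 0), 399L)
  expect_equal(genome_to_transcript(neg, 100), neg$transcript_length - 1L)

  expect_error(transcript_to_genome(m, 200), "out of range")
  expect_error(transcript_to_genome(m, -1), "out of range")
})

test_that("projection round trip is the identity on random models", {
  set.seed(42)
  for (i in 1:20) {
    m <- random_model(i, n_exons = sample(1:5, 1))
    tpos <- 0:(m$transcript_length - 1L)
    expect_identical(genome_to_transcript(m, transcript_to_genome(m, tpos)),
                     tpos)
    # genomic positions off the exons project to NA
    introns <- setdiff(min(m$exons):max(m$exons),
                       unlist(apply(m$exons, 1, function(e)
                         e[1]:(e[2] - 1L))))
    if (length(introns) > 0)
      expect_true(all(is.na(genome_to_transcript(m, introns))))
  }
})

test_that("segment lengths partition coding transcripts", {
  m <- toy_model_segments()
  expect_equal(unname(sum(tx_segments(m))), m$transcript_length)
  expect_equal(region_of_tpos(m, c(0, 99, 100, 399, 400, 599)),
               c("5'UTR", "5'UTR", "CDS", "CDS", "3'UTR", "3'UTR"))
  nc <- gene_model("g", "t", "chr1", "+", cbind(0L, 500L))
  expect_true(all(is.na(tx_segments(nc))))
  expect_equal(region_of_tpos(nc, 10), "noncoding")
})

test_that("longest isoform selection uses summed exon length with id tie-break", {
  gtf <- rbind(
    data.frame(chrom = "chr1", start = 0L, end = 900L, strand = "+",
               type = "exon", gene_id = "gA", transcript_id = "short"),
    data.frame(chrom = "chr1", start = 0L, end = 1200L, strand = "+",
               type = "exon", gene_id = "gA", transcript_id = "long"),
    # gB: two isoforms both 1000 nt; ENST1 must win the tie
    data.frame(chrom = "chr1", start = 5000L, end = 6000L, strand = "+",
               type = "exon", gene_id = "gB", transcript_id = "ENST2"),
    data.frame(chrom = "chr1", start = 5000L, end = 6000L, strand = "+",
               type = "exon", gene_id = "gB", transcript_id = "ENST1"),
    # gC: single isoform, spliced, with CDS
    data.frame(chrom = "chr1", start = c(10000L, 10500L),
               end = c(10200L, 10800L), strand = "+", type = "exon",
               gene_id = "gC", transcript_id = "tC"),
    data.frame(chrom = "chr1", start = 10100L, end = 10600L, strand = "+",
               type = "CDS", gene_id = "gC", transcript_id = "tC"))
  models <- select_longest_isoform(gtf)
  expect_named(models, c("gA", "gB", "gC"))
  expect_equal(models$gA$transcript_id, "long")
  expect_equal(models$gB$transcript_id, "ENST1")
  expect_equal(models$gC$transcript_id, "tC")
  # CDS genomic [10100,10600) -> transcript [100, 300) across the intron
  expect_equal(models$gC$cds_start_tx, 100L)
  expect_equal(models$gC$cds_end_tx, 300L)
})

test_that("GTF round trip preserves models", {
  set.seed(7)
  models <- lapply(1:5, random_model)
  names(models) <- vapply(models, `[[`, "", "gene_id")
  models$g1$cds_start_tx <- 10L
  models$g1$cds_end_tx <- 40L
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(models, path)
  back <- read_gtf_models(path)
  for (g in names(models)) {
    expect_equal(back[[g]]$exons, models[[g]]$exons)
    expect_equal(back[[g]]$strand, models[[g]]$strand)
    expect_equal(back[[g]]$cds_start_tx, models[[g]]$cds_start_tx)
    expect_equal(back[[g]]$cds_end_tx, models[[g]]$cds_end_tx)
  }
})

test_that("interval masks agree with a brute-force linear scan", {
  set.seed(11)
  for (rep in 1:5) {
    starts <- sort(sample(0:2000, 20))
    iv <- data.frame(chrom = "chr1", start = starts,
                     end = starts + sample(1:30, 20, replace = TRUE))
    mask <- interval_mask("m", iv)
    pos <- sample(0:2100, 300, replace = TRUE)
    brute <- vapply(pos, function(p)
      any(p >= iv$start & p < iv$end), logical(1))
    expect_identical(mask_overlaps(mask, "chr1", pos), brute)
    brute_near <- vapply(pos, function(p)
      any(pmax(iv$start - p, p - (iv$end - 1L), 0L) <= 4L), logical(1))
    expect_identical(mask_within(mask, "chr1", pos, 4L), brute_near)
  }
})

test_that("junction proximity uses coordinate distance with inclusive bound", {
  jn <- interval_mask("splice_junction",
                      data.frame(chrom = "chr1", start = 100L, end = 101L))
  expect_true(mask_within(jn, "chr1", 104L, 4L))   # 4 nt away: flagged
  expect_false(mask_within(jn, "chr1", 105L, 4L))  # 5 nt away: kept
  expect_true(mask_within(jn, "chr1", 96L, 4L))
  expect_true(mask_within(jn, "chr1", 100L, 4L))
})
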