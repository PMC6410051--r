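# meriptools

Windowed m6A peak calling and epitranscriptome integration for
MeRIP/RIP-seq experiments paired with RNA-seq.

N6-methyladenosine (m6A) is the most common internal mRNA modification,
written chiefly by the methyltransferase METTL3. Knockdown experiments
(control vs METTL3-silenced cells) combined with m6A
RNA-immunoprecipitation sequencing let one map which transcripts carry
the mark, which peaks depend on the writer, and how losing the mark
propagates to transcript abundance, RNA editing and alternative
splicing. `meriptools` implements that analysis for people working from
per-nucleotide coverage on transcript coordinates: epitranscriptomics
groups re-analysing MeRIP data, and method developers who need a
peak caller with a fully specified, testable statistic.

## The statistic at its core

Each transcript is scanned with 100-nt windows stepping 50 nt. A window
is scored by the gene-median-normalised log2 enrichment of IP over
input,

    WinScore = log2( (MeanWin_IP / MedianGene_IP) /
                     (MeanWin_ctrl / MedianGene_ctrl) )

which cancels both sequencing depth and transcript abundance. Windows at
or above a 2-fold cutoff are tested with a one-sided Fisher exact test
(window vs rest-of-gene read counts, IP vs input), all tested windows
are Benjamini–Hochberg corrected in one transcriptome-wide batch, and
overlapping or adjacent windows with adjusted p < 0.05 are merged into
peaks with summits at the maximum of depth-normalised IP coverage.

Downstream, peaks feed a metagene profile over rescaled
5'UTR/CDS/3'UTR segments, and the two conditions' peak sets are
compared (lost / reduced / common / independent) and integrated with
differential expression (padj < 0.05, |fold change| > 1.5) to classify
genes as direct targets (dependent peak), indirect targets (regulated
without a peak) or unaffected. Companion modules implement an
RNA-editing detection filter cascade (SNP, read-start, support,
simple-repeat, splice-junction, homopolymer and similarity filters),
rMATS splicing post-filters with an m6A-dependence test for exon
skipping, and RBP stabilizer/destabilizer classification from
cumulative expression-shift distributions. A seed-reproducible
synthetic-data generator with known ground truth exercises every stage.

## Worked example

Simulate a 50-gene experiment (30x background, 4-fold peaks in a fifth
of the genes), call peaks and inspect them:

```r
library(meriptools)

sim   <- sim_config(n_genes = 50, seed = 1)
rip   <- simulate_rip(sim)
peaks <- call_peaks(rip$ip, rip$input, rip$models)
head(peaks[, c("transcript_id", "start", "end", "enrichment_score",
               "p_adjusted", "summit", "region_class")], 4)
#>   transcript_id start end enrichment_score   p_adjusted summit region_class
#> 1         T0006   200 500         1.942933 4.485163e-17    253          CDS
#> 2         T0008   100 300         1.961558 3.371024e-23    236        5'UTR
#> 3         T0012   200 450         1.990871 1.276078e-21    336          CDS
#> 4         T0015   400 650         1.940057 6.607110e-21    470          CDS

peak_recovery(peaks, rip$truth)
#> [1] 1
```

Every called peak carries the merged window span, its best window score
(log2 units, here ~2 as planted), the minimum adjusted p and the summit.
All ten planted peaks are recovered with boundaries on the 50-nt scan
grid. Comparing against a silenced condition and integrating with
differential expression:

```r
sil       <- simulate_rip(within.list(sim, {peak_fold <- 1; seed <- 101L}),
                          models = rip$models)
peaks_sil <- call_peaks(sil$ip, sil$input, rip$models)
cmp       <- compare_peak_sets(peaks, peaks_sil)
de        <- apply_de_thresholds(simulate_de(sim, rip$truth))
summ      <- summarize_targets(classify_targets(cmp$genes, de))
round(summ$percentages, 2)
#>      direct_regulated direct_regulated_down    direct_unregulated
#>                   100                   100                     0
#> indirect_of_regulated           indirect_up         indirect_down
#>                     0                    NA                    NA
#> ...
```

All ten peak-bearing genes lose their peak upon silencing and are
downregulated, so 100% of direct targets are regulated and all of them
down — the planted knockdown effect. `run_demo(pipeline_config(seed = 1))`
runs the whole chain (peaks, metagene, targets, editing, splicing, RBPs)
and returns these numbers as one report.

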