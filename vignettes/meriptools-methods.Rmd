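---
title: "Methods: windowed m6A peak calling and epitranscriptome integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed m6A peak calling and epitranscriptome integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meriptools)
```

## Scope and model

`meriptools` analyses m6A MeRIP/RIP-seq experiments paired with total
RNA-seq in a knockdown design: a control condition (e.g. cells carrying a
non-targeting shRNA) and a condition in which the m6A writer
methyltransferase METTL3 has been silenced. The package starts from
per-nucleotide coverage on **transcript coordinates** — peak calling on
spliced transcripts avoids intronic interference, so aligned reads are
assumed to have been projected from genome to isoform coordinates
upstream. Only the longest isoform per gene is used (summed exon length;
equal lengths broken by the lexicographically smallest transcript id, a
package decision since no convention exists).

All internal coordinates are 0-based half-open; GTF input (1-based
inclusive) is converted on read and BED is passed through unchanged. This
makes interval arithmetic uniform across modules.

## The window-scan peak caller

For each transcript shared by the IP and input libraries, 100-nt windows
are tiled every 50 nt. Trailing windows clipped to 50 nt or less add no
new coverage beyond their predecessor and are dropped; transcripts
shorter than 50 nt yield no windows. Each window is scored by

$$\mathrm{WinScore} = \log_2\!\left(
  \frac{\mathrm{MeanWin}_{IP}/\mathrm{MedianGene}_{IP}}
       {\mathrm{MeanWin}_{ctrl}/\mathrm{MedianGene}_{ctrl}}\right),$$

the log2 ratio of window coverage over gene-median coverage between
libraries. Normalising by the per-gene median makes the score insensitive
to both sequencing depth and transcript abundance, so it measures local
IP enrichment rather than expression.

Windows at or above the enrichment cutoff (default 1.0, i.e. 2-fold;
`enrichment_cutoff`) are tested with a one-sided Fisher exact test on the
2x2 table of window vs rest-of-gene read counts in IP vs input, the same
direction the score measures. Coverage is converted to read units by
dividing coverage sums by the read length (default 50 nt, the library's
single-end read length); the exact conversion used upstream of published
analyses of this type is typically unstated, so it is exposed as
`read_length`. All tested windows across the transcriptome form one
Benjamini-Hochberg batch; windows with adjusted p below `alpha` (default
0.05) are kept, and overlapping or adjacent significant windows are
merged into peaks. A peak's enrichment score is the maximum window score,
its adjusted p the minimum, and its summit the position of maximum
depth-normalised IP coverage (leftmost on ties — deterministic).

Numerical choices:

* **Pseudocount.** One unit is added to the four score inputs and one
  read-unit to the four Fisher totals, keeping the score finite and the
  table cells positive. Transcripts whose raw median coverage is zero in
  either library are excluded from calling (their median normalisation
  would be meaningless) with a message.
* **Testing only enriched windows.** Only windows that clear the
  enrichment cutoff enter the Fisher/BH stage. This follows the described
  procedure of testing "windows with detected enrichment"; it shrinks the
  BH family relative to testing everything, which is anti-conservative
  for the family but conservative per window. The cutoff itself is
  unquantified in the source procedure; 2-fold is the package default and
  configurable.
* **Region classes.** A peak is assigned 5'UTR/CDS/3'UTR by its midpoint
  (the summit is available as an option); peaks on transcripts without a
  CDS are `noncoding`.

Coverage tracks for visualisation are normalised to one million reads
per library (`normalize_track`), a positive rescaling that cannot move
summit positions. Summit-flanking sequence extraction (±50 nt, clipped at
transcript ends) feeds external motif tools.

## Metagene profiling

Peak positions on coding transcripts are rescaled onto a three-segment
axis: 5'UTR to [0,1), CDS to [1,2), 3'UTR to [2,3), each segment
stretched to unit length. Noncoding transcripts are excluded from the
metagene (the three-segment model applies to mRNA only) but participate
fully in peak calling. The signed distance of the summit from the stop
codon (`stop_offset`, negative upstream) resolves the stop-codon
enrichment at nucleotide resolution. Consensus-site counting uses IUPAC
matching (default motif `RRAC`, the canonical m6A core; `GACYC`-style
alternatives are configurable) with overlapping matches counted, and the
peak-score association uses Spearman rank correlation, reported as `NA`
with a warning when ranks are degenerate.

## Differential integration

Peak sets from the two conditions are compared by overlap (at least one
shared nucleotide on the same transcript; a minimum-overlap fraction is
deliberately not imposed — merged windows are already coarse). A control
peak with no silenced counterpart is **lost**; an overlapping pair whose
score drops by at least `reduction_threshold` (default 1 log2 unit,
symmetric with the caller's enrichment cutoff, since "reduced intensity"
has no established quantitative definition) is **reduced**; smaller
changes are **common**; gains of at least the threshold and
silenced-only peaks are **independent**. A gene's class is the strongest
among its peaks (lost > reduced > common > independent) — a package
decision for the genuinely open case of genes with peaks in several
classes.

Differential expression is thresholded strictly: regulated iff adjusted
p < 0.05 **and** |fold change| > 1.5 (|log2 FC| > log2 1.5 ≈ 0.585).
Genes with lost or reduced peaks are **direct** targets
(`direct_regulated` / `direct_unregulated` by the DE flag); regulated
genes without a dependent peak are **indirect**; the remainder
unaffected. The classes partition the union of peak-bearing and
expression-tested genes, and `summarize_targets` reports the bookkeeping
percentages (share of direct targets regulated, their down split, the
indirect share and its up/down split overall and for protein-coding
genes) unrounded, with zero denominators as `NA`.

Cumulative-distribution comparisons (transcript abundance by m6A status
and biotype, fold-change distributions, RBP site effects) use the
two-sample Kolmogorov-Smirnov test with asymptotic p-values plus the
median shift; the Wilcoxon rank-sum test is used where distributions of
inclusion levels are compared per splicing event type. An RBP is called a
**stabilizer** when m6A transcripts carrying its site are significantly
more downregulated after silencing than m6A transcripts without the site
(KS p < 0.05 and negative median shift), a **destabilizer** for the
opposite shift, **neutral** otherwise.

## RNA-editing filter cascade

Candidate mismatch sites (from any upstream variant caller; the
alignment and calling itself is out of scope) pass through, in order:
known-SNP removal (all sites); discounting of supporting reads whose
mismatch lies in the first six read bases (random-hexamer priming
artefacts); then, for non-Alu sites only: at least 3 clean supporting
reads at frequency ≥ 0.1 (both evaluated **after** the discount; the
pre/post choice is unstated in the source procedure and post-discount is
the stricter, adopted here), simple-repeat overlap, proximity within
4 nt of a splice junction, homopolymer runs of ≥ 5 reference bases
covering the site, and a high-similarity mask (supplied as a BED
interval mask; running an aligner to find near-duplicate regions is out
of scope, the contract is preserved). `filter_status` records the first
failing filter; a site whose support lies entirely in the first six read
bases is labelled `read_start` rather than `support`, so the two failure
modes remain distinguishable. A passing site is high confidence with
≥ 10 reads and editing ratio ≥ 0.2 (inclusive bounds).

Event typing follows strand: A→G on plus or T→C on minus is A-to-I;
C→T on plus or G→A on minus is C-to-U; strandless sites accept either
orientation. (Published figure legends occasionally group C–G changes
with A-to-I; this is inconsistent with A-to-I chemistry and the standard
convention is used here.) Region annotation ranks CDS > UTR > intronic >
intergenic across all overlapping gene models, and CDS sites get a
synonymous/nonsynonymous call by substituting the altered base into the
reference codon under the standard genetic code.

## Splicing post-filters

rMATS-format tables are filtered to FDR < 0.05, |ΔPSI| ≥ 0.05 and
inclusion **and** skipping counts ≥ 10 in each condition (replicate
counts are summed per condition). The "inclusion-level difference ≥ 5"
convention is read as five percentage points — the only reading
consistent with PSI's [0,1] range — and exposed as `psi_threshold`.
Skipped-exon events are flagged for overlap between the alternative
exon's transcript interval and any control-condition peak (for MXE-style
events with two alternative exons the first is used), and the ΔPSI
distributions of m6A-gene vs non-m6A-gene events are compared by KS.

## The synthetic-data generator

Every stage is exercised against seed-reproducible synthetic data with
known truth. Background coverage is drawn i.i.d. negative-binomially per
nucleotide (mean 30 reads/nt, size 10) in both libraries — the standard
overdispersion model for sequencing coverage; the source procedure
states none. Planted peaks multiply the IP mean by `peak_fold` (default
4) over 100-200 nt intervals. Planted intervals sit on the caller's
50-nt scan grid: merged 100-nt windows stepping 50 nt resolve boundaries
in grid units, so off-grid planting would measure grid quantisation
(worst case ~66 nt) rather than detection, and the ±50 nt recovery
tolerance used in the tests equals one grid step. With `peak_fold = 1`
the IP and input tracks are exchangeable, which feeds the caller's
type-I-error check.

The DE table gives peak-bearing genes a log2 fold change centred on
-1.5 with per-gene noise of sd 0.3, and p-values from the implied
z-test, so a zero planted effect makes peak and non-peak genes
statistically indistinguishable. Editing decoys violate exactly one
filter each, which makes every cascade step individually assertable;
true sites clear the high-confidence bounds by construction and a 37%
subset of them is absent from the silenced condition. RBP simulations
shift the with-site group by ±1 log2 unit with per-gene noise of sd 0.5
(a typical replicate-level log2 fold-change spread for a strong
knockdown) over 200 genes per group.

What the generator does **not** emulate: read-level properties (fragment
lengths, positional autocorrelation of coverage, sequence-content bias),
multi-isoform expression, and correlated peak/expression noise. Passing
tests therefore demonstrate correctness of the statistics and
bookkeeping under the stated model, not robustness to alignment
artefacts in real libraries.

## Problem sizes and determinism

The default demonstration scale is 200 genes (about 0.3 Mnt of
transcriptome per library), 50 true editing sites plus 70 decoys, 250
splicing events and 100 RBPs; the full demonstration pipeline
(`run_demo`) completes in a few seconds at this scale and is
byte-identical for a fixed seed, as all randomness flows through seeds
derived from the single configured one.

```{r demo, eval = FALSE}
report <- run_demo(pipeline_config(seed = 1))
str(report, max.level = 1)
```

## Known limitations

* The caller reports peaks at 50-nt boundary resolution; sub-window
  boundary refinement is not attempted.
* The Fisher read-unit conversion treats coverage/read-length as a read
  count, which is exact only for non-overlapping reads.
* Editing region annotation assigns each site to the strongest region
  across isoform models of the longest-isoform set only.
* The similarity filter is delegated to a user-supplied mask; no
  alignment-based duplicate detection is performed.
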