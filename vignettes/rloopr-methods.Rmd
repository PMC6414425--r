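---
title: "Methods: quantifying R-loops at Polycomb target genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying R-loops at Polycomb target genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rloopr)
```

## The analysis

In mouse embryonic stem cells, developmental regulator genes are silenced
by the Polycomb complexes PRC1 (RING1B, depositing H2AK119ub1) and PRC2
(EZH2, depositing H3K27me3) while retaining poised Ser5P RNA polymerase II
and low-level nascent transcription. R-loops — co-transcriptional RNA-DNA
hybrids with a displaced single strand — form at a subset of these genes,
and removing them (RNase H1 overexpression) reduces Polycomb occupancy.
`rloopr` implements the quantitative layer of that analysis:

1. **R-loop gene classification.** A gene's window is the genomic region
   from 1 kb upstream of the TSS to 1 kb downstream of the TES (because the
   flank is symmetric, this is the gene body ± 1 kb on either strand,
   clipped at the chromosome start). A gene is *positive* when at least one
   DRIP-seq peak shares ≥ 1 base with its window. Positive genes whose
   windows overlap another positive gene's window are reassigned
   *uncertain_proximity*: the peak cannot be attributed unambiguously
   between neighbours. All other genes are *negative*.
2. **Duplicate thresholding and spike-in normalization.** Reads with an
   identical signature (chromosome, start, end, strand) beyond a
   per-dataset threshold — the nearest-rank 95th percentile of the
   signature-frequency distribution — are removed. Signal is made
   comparable between samples by the exogenous spike-in library: each
   target-genome read carries a weight of $10^6 / N_{\mathrm{spike}}$, so a
   sample's normalized depth is
   $N_{\mathrm{target}} / N_{\mathrm{spike}} \times 10^6$.
3. **Nascent transcription.** Sense-strand run-on (GRO-seq) coverage is
   integrated from TSS to TES and expressed as
   $\mathrm{RPKM} = \dfrac{\text{sense reads}}
   {\text{length}_{\mathrm{kb}} \times \text{library}_{\mathrm{millions}}}$,
   with genes called nascent-positive when RPKM is *strictly* greater than
   0.1. Rank classes (most/least active 15%) are built among eligible genes
   with a deterministic gene-id tie-break.
4. **Profiles and statistics.** Meta-profiles average coverage in
   non-overlapping 10-bp bins across windows centred on the TSS or TES,
   with minus-strand genes orientation-flipped; group comparisons use the
   Wilcoxon rank-sum test (the transcription comparison) or the two-tailed
   unpaired pooled-variance t test (qPCR), starred at p < 0.05 / 0.01 /
   0.001.
5. **qPCR quantification.** Enrichment is percent of input with the
   adjusted-input ΔCt method:
   $\%\,\mathrm{input} = 100 \times
   2^{\,(Ct_{\mathrm{input}} - \log_2(1/f)) - Ct_{\mathrm{IP}}}$, where
   $f$ is the input fraction.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `flank_bp` | 1000 | gene-window flank on both sides (bases) |
| `tss_window_bp` | 1000 | TSS-centred window for normalized ChIP signal |
| `bin_bp` | 10 | meta-profile bin width |
| `rpkm_threshold` | 0.1 | strict nascent-positivity cutoff (RPKM) |
| `fraction` | 0.15 | top/bottom expression rank fraction |
| `percentile` | 0.95 | duplicate-threshold percentile |
| stars | 0.05/0.01/0.001 | significance annotation thresholds |

All are overridable per call; the defaults are the values the analysis is
defined with.

## What the synthetic generator emulates

`simulation_config()` plants a genome whose ground truth every downstream
stage must recover:

* **Gene classes.** Equal-sized Polycomb-repressed, active and inactive
  cohorts placed non-nested with ≥ 3 kb body spacing (so 1-kb windows of
  distinct genes are disjoint), gene lengths uniform on 2–10 kb. A
  configurable `overlap_fraction` of genes is instead placed in pairs with
  body gaps of 200–1500 bp, making exactly those window pairs overlap —
  the planted exercise of the proximity rule. Pair members are forced
  R-loop positive so each planted pair must come out
  `uncertain_proximity`.
* **R-loop peaks.** Per-class Bernoulli planting with defaults 0.25
  (Polycomb), 0.76 (active), 0.05 (inactive) — the proportion structure of
  a mESC DRIP-seq landscape where about three quarters of active genes and
  a quarter of Polycomb targets carry R-loops. One peak of 300–1500 bp is
  placed inside the positive gene's window.
* **Nascent transcription.** A gene is transcribed with per-class
  probability `p_nascent` (0.42 / 1 / 0.05) independently of its R-loop
  status; transcribed genes emit sense-strand reads at
  Poisson(`nascent_rate` × length in kb) with rates 2 / 60 / 0.5 reads per
  kb. The independence is deliberate: it encodes the null hypothesis that
  R-loop-positive and R-loop-negative Polycomb genes are transcribed at
  similar levels, which the Wilcoxon comparison must *not* reject.
* **ChIP reads.** A genome-wide Poisson background of 5 reads/kb (the
  per-kb depth of a typical mammalian ChIP-seq library) plus per-gene
  enrichment at the 2-kb TSS-centred window at 50× (Polycomb), 5×
  (active) and 1× (inactive) background. The `rnaseh1` condition
  multiplies enrichment at R-loop-positive Polycomb genes by 0.5. The
  fragment library is built as a set of *distinct* signatures (positions
  sampled without replacement), after which PCR amplification gives each
  fragment `1 + Geometric(duplication_rate)` copies — so a duplication
  rate of zero really does mean all-unique signatures, and the heavy tail
  mimics PCR jackpots. Spike-in reads live on a reserved `spike_1`
  chromosome and are appended so their expected library share is
  `spikein_fraction` (default 5%).
* **qPCR.** The undiluted input has baseline Ct 25; the measured input Ct
  is shifted by $\log_2(1/f)$ for a diluted aliquot, and the IP Ct is
  $25 - \log_2(\%/100)$ plus Gaussian noise on both measurements. With
  zero noise, `percent_input()` inverts the generator exactly at any
  dilution.

What it does **not** emulate: sequence content (no FASTQ, no GC or
mappability bias), fragment-length variation, strand-specific R-loop
structure (DRIPc), isoform structure, or the tendency of run-on assays to
miss very low-level nascent RNA at poised genes. Passing recovery tests
therefore demonstrates the correctness of the computational rules, not
robustness to every artefact of real libraries.

## Numerical and design choices

* **Coordinates** are 0-based half-open everywhere; GTF input is converted
  on read. The minus-strand TSS is the gene's end bound (the biological 5'
  boundary in half-open coordinates). Overlap means ≥ 1 shared base.
* **Duplicate removal caps** each over-threshold signature at the
  threshold rather than deleting the whole group: deleting would erase the
  strongest true-signal positions. `deduplicate(mode = "drop")` provides
  the other reading. The threshold is computed once per dataset on target
  and spike-in reads combined; the nearest-rank definition
  (⌈0.95 n⌉-th order statistic) is exact on a discrete multiset and never
  interpolates.
* **Proximity rule** is window-versus-window between positive genes and is
  applied in a single pass over the initial positive set — reassignment
  cannot create new overlaps, so no fixpoint iteration is needed. A
  peak-mediated variant (`proximity = "peak"`) is available: it marks only
  positive genes sharing an actual peak with another positive gene's
  window.
* **RPKM denominator** counts mapped reads on both strands ("per million
  mapped" is strand-agnostic); bedGraph input has no read boundaries, so
  reads are recovered as coverage integral / read length, which matches
  true counts exactly when reads fall fully inside the gene.
  `uncertain_proximity` genes are excluded from both sides of the
  R-loop × nascent intersection by default.
* **Wilcoxon** uses exact enumeration of all $\binom{n+m}{n}$ rank
  assignments when $n+m \le 12$ with no ties, else the normal
  approximation with midranks, tie-corrected variance and a 0.5 continuity
  correction. The t test pools variances (Student) by default with Welch
  behind a flag; a zero pooled variance is an error rather than an
  infinite statistic.
* **Rank classes** break expression ties by ascending gene id, so the
  top/bottom 15% sets are deterministic and disjoint
  (size ⌊0.15 n⌋ each).
* **Determinism.** Every generator draws inside `withr::with_seed()` with
  a fixed offset per stage, so a configuration seed fixes all outputs
  byte-for-byte, and stages can be re-run in isolation.

## Problem sizes

The recovery suite runs at 3,000 genes for exact classification recovery,
2,000 genes per class for planted-fraction recovery (3 binomial SE), 100
seeded cohorts of 60 Polycomb genes for the transcription null (≥ 90%
non-significant at α = 0.05), 500 genes per class for the RNase H1
depletion recovery (median TSS-window reduction 50% ± 15% at
R-loop-positive Polycomb genes, < 10% at active genes), and 1,000 random
read multisets for the deduplication oracle. These sizes keep each
statistical check well-powered while the full suite stays fast on a
laptop.

## Known limitations

* Peaks are consumed, never called; alignment is upstream of the package
  (inputs are aligned read intervals and coverage tracks).
* The classifier treats peaks as unstranded, as DRIP-seq peaks are.
* With extremely shallow ChIP libraries the median TSS-window count at
  weakly enriched classes moves in coarse discrete steps; condition ratios
  at such classes are then unstable (the generator's default depth avoids
  this regime).
* Whether the original duplicate filter removed excess copies or whole
  signature groups, and whether its threshold used target reads only, is
  not derivable from the data; both choices are implemented, with cap +
  combined as defaults.
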