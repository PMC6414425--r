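# rloopr

Quantitative analysis of R-loops at Polycomb-repressed genes.

In mouse embryonic stem cells, CpG-rich developmental regulator genes are
silenced by the Polycomb complexes PRC1 (RING1B) and PRC2 (EZH2) while
retaining poised Ser5P RNA polymerase II. R-loops — co-transcriptional
RNA-DNA hybrids — form at a subset of these genes, and their removal
changes Polycomb occupancy and transcription. `rloopr` is a tidyverse-style
R package for the computations behind that kind of study:

* **R-loop gene classification** from DRIP-seq peaks: a gene is *positive*
  when a peak overlaps its window (TSS − 1 kb to TES + 1 kb, ≥ 1 shared
  base), *uncertain_proximity* when its window also overlaps another
  positive gene's window, *negative* otherwise — plus per-class proportion
  summaries.
* **Spike-in-normalized ChIP-seq quantification**: duplicate reads beyond
  the nearest-rank 95th percentile of the signature-frequency distribution
  are removed, and target signal is scaled by the exogenous library,
  `normalized depth = N_target / N_spike × 10⁶`, with per-gene signal in
  1-kb TSS-centred windows.
* **Nascent transcription** from stranded run-on coverage:
  `RPKM = sense reads / (length_kb × library_millions)`, nascent-positive
  strictly above 0.1, top/bottom 15% expression classes, and the
  R-loop × nascent-RNA intersection table for Polycomb targets.
* **Meta-profiles and statistics**: 10-bp-bin average profiles around
  TSS/TES, Wilcoxon rank-sum (exact by enumeration for n + m ≤ 12 without
  ties), two-tailed unpaired t tests, and `*`/`**`/`***` annotation at
  0.05 / 0.01 / 0.001.
* **qPCR percent-of-input**:
  `% input = 100 × 2^((Ct_input − log2(1/f)) − Ct_IP)` for input fraction
  `f`, replicate summaries (mean, SD, n) and condition comparisons.
* A **seeded synthetic-data generator** that plants gene classes, R-loop
  peaks, stranded coverage, duplicated spike-in-mixed reads and Ct tables
  with known ground truth, so that every stage is verified by parameter
  recovery.

Functions take data frames first and return tibbles; results have
`tidy()` / `glance()` methods and `autoplot()` / `plot_*()` figures.

## Worked example

Simulate a study at reference conditions (R-loops at 25% of Polycomb,
76% of active, 5% of inactive genes; 42% of Polycomb genes transcribed;
RNase H1 halving ChIP enrichment at R-loop-positive Polycomb genes) and
run the complete pipeline:

```r
library(rloopr)

cfg <- simulation_config(
  n_genes = c(pcg_repressed = 500, active_top = 500, inactive_bottom = 500),
  genome_size = 2e7, seed = 42
)
result <- run_pipeline(cfg)
result
#> rloop_pipeline: 1500 genes, seed 42
#>
#> R-loop status proportions by class:
#>      class_label n_genes prop_positive prop_uncertain prop_negative
#>    pcg_repressed     500         0.228              0         0.772
#>       active_top     500         0.740              0         0.260
#>  inactive_bottom     500         0.058              0         0.942
#>
#> Polycomb-repressed intersection (R-loop x nascent RNA):
#>    class_label n_both n_nascent_only n_rloop_only n_neither n_genes pct_nascent
#>  pcg_repressed     53            165           61       221     500        43.6
#>  pct_rloop_of_nascent
#>              24.31193
#>
#> RPKM, R-loop+ vs R-loop- Polycomb genes: p = 0.4771
#> RNase H1 / control median TSS signal at R-loop+ Polycomb genes: 0.5542
```

Reading the output: the classifier recovers the planted per-class R-loop
fractions (22.8% / 74.0% / 5.8% against planted 25% / 76% / 5%); 43.6% of
Polycomb genes yield nascent RNA and 24.3% of those also form R-loops; the
Wilcoxon p of 0.48 correctly fails to separate the transcription of
R-loop-positive and -negative Polycomb genes (they are simulated
identically); and the spike-in-normalized median TSS signal at
R-loop-positive Polycomb genes drops to 0.55 of control under RNase H1,
recovering the planted 0.5 depletion.

qPCR quantification works the same way on Ct tables:

```r
drip <- dplyr::bind_rows(
  simulate_qpcr(6,   ct_noise_sd = 0.15, input_dilution = 0.1, n_replicates = 3,
                target_id = "Nkx2-9_P", condition = "mock",    seed = 11),
  simulate_qpcr(1.5, ct_noise_sd = 0.15, input_dilution = 0.1, n_replicates = 3,
                target_id = "Nkx2-9_P", condition = "RNaseH1", seed = 12)
)
condition_compare(percent_input(drip), "mock", "RNaseH1")
#> # A tibble: 1 × 9
#>   target_id mean_reference mean_treatment fold_change     t  p_value stars
#>   <chr>              <dbl>          <dbl>       <dbl> <dbl>    <dbl> <chr>
#> 1 Nkx2-9_P            6.23           1.41       0.227 -11.8 0.000295 ***
```

`plot_rloop_proportions()`, `plot_tss_signal()`, `plot_percent_input()`
and `autoplot()` on a `profile_matrix` give the corresponding figures.

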