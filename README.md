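# phosflow

Analysis toolkit for SILAC-style quantitative phosphoproteomics of kinase
signalling, with companion kinetic fitting for the imaging-based binding
assays used to follow up discovered phospho-switches. It is aimed at
proteomics bioinformaticians who have a MaxQuant-style phosphosite table
(or want to simulate one with known ground truth) and need the standard
downstream chain as tested, scriptable R functions:

* **Differential phosphorylation** — per-site linear models of log2 ratios
  with treatment effects and isotope-label (labeling-bias) covariates;
  residual variances regularized by averaging with the median variance,
  `s²_mod = (s² + median s²)/2`; calibrated p values for the moderated
  statistic; Benjamini–Hochberg FDR; regulation calls at a fold-change and
  significance gate; localization filtering at probability ≥ 0.75.
* **Motif discovery** — iterative position-specific enrichment (motif-X
  style) with exact binomial tails, plus rule-based annotation of the
  classical (`RxRxx[S/T]`) and extended (`RxRxx[S/T]xxpS`) basophilic
  motifs.
* **Kinase-substrate enrichment** — the z-score-type statistic
  `(s̄ − p̄)√m / σ` over PhosphoSitePlus-like annotations, with isoform
  grouping and a minimum-substrate floor.
* **Imputation & clustering** — downshifted-normal imputation (2σ
  downshift, 0.3σ width), Pearson-distance/Ward hierarchical clustering,
  and k-means enrichment classification for proximity-labeling (BioID)
  screens against two controls.
* **Kinetics** — biphasic FRAP recovery fits
  (`F(t) = F∞ − A_f e^(−k_f t) − A_s e^(−k_s t)`, slow-phase halftime and
  mobile fraction), one-component FCS autocorrelation fits with
  focal-volume calibration, and competition-titration Kd estimation
  (`b(c) = b₀/(1 + c/K_d)` under the trace-probe assumption).
* **Synthetic data** — generators for every input (proteome FASTA, site
  tables with label swaps and missing-at-low-abundance values, FRAP traces,
  FCS curves, titrations) with ground truth, so each stage is testable
  offline.

Everything takes and returns tibbles (or small S3 fit objects with
`tidy()`/`glance()`/`autoplot()` methods), so calls chain with the pipe.

## Worked example

```r
library(phosflow)

spec     <- phospho_sim_spec(n_proteins = 600, n_sites = 4000, seed = 7)
proteome <- simulate_proteome(spec)
sim      <- simulate_phospho_experiment(spec, proteome)

summarize_dataset(sim$table)
#> # A tibble: 1 × 5
#>   n_identified n_localized pct_localized n_quant_min2 pct_quant_min2
#> 1         4000        2747            69         2648             96

loc  <- filter_localized(sim$table)$localized
fits <- loc |> fit_ratio_model() |> call_regulated()
dplyr::count(fits, contrast, regulation)
#>   contrast regulation     n
#> 1 IGF      up           140
#> 2 IGF      down           5
#> 3 IGF      none        1995
#> 4 IGF      untestable   607
#> ...

reg    <- dplyr::filter(fits, contrast == "IGF", regulation == "up")
motifx_enrich(reg$window, loc$window)
#>   pattern fg_matches fg_size bg_matches bg_size fold_enrichment
#> 1  R.R..S         63     140        139    2747        8.893165

table(annotate_basophilic(reg$window))
#> classical      none
#>        63        77
```

Of 4,000 simulated sites, 69% pass the localization filter; 140
phosphopeptides come up at the fold-change/FDR gate under stimulation, the
planted basophilic motif `R.R..S` is recovered as 8.9-fold enriched over
the localized background, and 63 of the regulated windows carry the
classical arginine signature.

Kinetics, on synthetic wild-type FRAP traces (halftime 33 s, mobile
fraction 0.86, 2% noise):

```r
wt <- kinetic_sim_spec(halftime = 33, mobile_fraction = 0.86, seed = 1)
summarize_frap(lapply(simulate_frap(wt), fit_frap))
#>       n t_half_median t_half_iqr mobile_mean_pct mobile_sd_pct
#> 1    20          34.2       6.19            87.0          3.31
```

The median fitted halftime (34.2 s) and mean mobile fraction (87%) recover
the generating values within sampling error.

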