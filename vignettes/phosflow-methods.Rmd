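---
title: "Models and methods in phosflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in phosflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosflow)
```

phosflow implements the computational chain of a SILAC-style quantitative
phosphoproteomics study of kinase signalling — moderated differential
statistics on multiplexed log2 ratios, basophilic phosphorylation-motif
discovery, kinase-substrate enrichment, imputation and clustering — together
with the kinetic fits used to characterise a discovered phospho-regulated
protein interaction (FRAP recovery, FCS diffusion, competition-binding
titrations). Every stage can be exercised on synthetic data with known
ground truth, so the whole pipeline is testable without any deposited raw
data. This vignette records the models, the tunable parameters, and the
design decisions that were genuinely open.

## The ratio linear model

Each phosphosite contributes a vector of log2 SILAC ratios, one per sample,
where a sample is one treatment channel of one replicate measured in one
isotope label. The per-site model is ordinary least squares on

* one indicator column per treatment effect (e.g. growth-factor stimulation
  and pathway inhibition, each measured against the common control channel),
* one indicator per isotope-label configuration beyond the first, absorbing
  the labeling bias that a label switch between replicates makes estimable.

Ratios are stored internally as log2(treatment/control). Volcano plots of
this kind of data are often drawn as control/treatment; `plot_volcano()`
offers `flip_sign` for that, so there is exactly one internal convention.

Sites are fitted on their available (non-missing) observations. A site whose
surviving design submatrix is rank deficient, or which has no residual
degrees of freedom, is reported as `untestable` rather than silently given a
p value — no row is ever dropped.

### Variance moderation and p values

Residual variances are regularized by averaging with the median variance
across all fitted sites,

$$s^2_\mathrm{mod} = \tfrac{1}{2}\left(s^2 + \mathrm{median}(s^2)\right),$$

and the contrast statistic is $t = \hat\beta / \sqrt{s^2_\mathrm{mod}\,c_{jj}}$
with $c_{jj}$ the contrast's diagonal element of $(X^\top X)^{-1}$. The
moderated denominator is *not* a scaled chi-square, so referring $t$ to a
t distribution on the OLS residual df is badly miscalibrated at low
replication: in simulations with three replicates the null rejection rate at
$\alpha = 0.05$ is about 0.001, and the "moderated" test is then *less*
powerful than the plain per-site t test — the opposite of what moderation is
for. phosflow therefore computes p values from the exact null law of the
moderated statistic under a common-variance null,

$$t \;\sim\; \frac{Z}{\sqrt{\tfrac{1}{2}\!\left(\chi^2_d/d + m^*\right)}},$$

where $m^*$ is the median of the $\chi^2_d/d$ mixture implied by the
observed per-site df (estimable because the median pools thousands of
sites). The tail probability is a one-dimensional integral evaluated by
midpoint quadrature on the chi-square quantile scale (400 nodes). This
calibrates essentially exactly (simulated null rates 0.0497/0.0498/0.0500 at
d = 2/4/8) and is uniformly more powerful than the unmoderated t test. The
t-reference variant remains available as `fit_ratio_model(p_method = "t")`.
The exactness argument assumes a common residual variance across sites —
the same assumption that motivates moderation toward a global median in the
first place; under strong heteroscedasticity the p values are approximate.

Multiple testing uses the Benjamini–Hochberg step-up procedure per contrast
across testable sites. Regulation calls combine a fold-change gate on the
model-adjusted estimate (default |log2 FC| ≥ log2 1.5) with a significance
gate (default adjusted p < 0.05; both the raw-p and adjusted-p variants are
exposed because studies of this design have used each). Sites with
localization probability ≥ 0.75 are "localized", below that (or missing)
"putative".

## Motif discovery

`motifx_enrich()` implements the iterative greedy motif search: windows are
±7-residue contexts (15-mers, site centred at position 8, `_` past the
termini). For each not-yet-fixed (offset, residue) pair the exact binomial
tail probability of the foreground count given the background frequency at
that offset is computed (frequencies over non-`_` characters only); the most
significant pair is fixed if it passes the p cutoff (default 1e-6) and the
minimum-occurrence support (default 10); non-matching windows are removed
from both sets, and the loop repeats. On completion the motif's foreground
matches are removed and the search restarts. Central S and T windows are
analysed separately and merged in the report.

Open choices made here:

* **Tie-breaks.** When two pairs share the minimal p: smaller |offset|, then
  lower offset, then alphabetical residue. This makes the search fully
  deterministic.
* **Zero background cells.** After a few fixing steps the background can
  shrink until a residue is unseen at some offset; the raw binomial tail
  would then be an artificial 0. A half pseudo-count is used for zero cells
  so significance always reflects evidence, never emptiness.
* **Background choice.** The background is caller-supplied; the natural
  default in this pipeline is the set of all localized site windows. Whether
  the foreground should be restricted to localized sites is likewise left to
  the caller.

Rule-based annotation (`annotate_basophilic()`) classifies marked windows:
the classical basophilic motif requires arginine at −5 and −3 of the
phosphorylated central S/T; the extended motif additionally requires a
*phosphorylated* S/T at +3, and takes precedence.

## Kinase-substrate enrichment

For each kinase group with at least 5 mapped substrate peptides, the score
is $(\bar s - \bar p)\sqrt{m}/\sigma$: mean substrate log2 fold-change
versus the mean over all quantified peptides, scaled by $\sqrt{m}$ and the
standard deviation of all fold-changes. Two wording ambiguities are resolved
as: $\bar p$ is the *mean* of all quantified fold-changes, and $\sigma$ is
the sample standard deviation (n − 1), the convention of the method this
score follows. Peptides enter at the peptide level (not collapsed per
protein); a peptide annotated to several isoforms of one group counts once.

## Imputation, clustering, proximity labeling

Missing profile entries are drawn per column from a downshifted normal,
$N(\mu_c - 2\sigma_c, (0.3\sigma_c)^2)$ by default — the standard model for
intensities missing because they fell below detection. Observed entries are
untouched and the draw is deterministic given a seed.

Hierarchical clustering uses the distance $1 - r$ (Pearson) between row
profiles with Ward's criterion. The named tools in this field implement
Ward on squared dissimilarities (the Ward.D2 form of the Lance–Williams
update); that variant is used here, and the agglomeration is verified in the
tests against an independent O(n³) implementation. Trees are cut at a
requested k (cluster counts, not heights, are what studies of this design
report). A row-z-scored matrix accompanies every result for heatmap-style
display. Merge ties break toward the lower row-index pair; with continuous
data ties have probability zero.

Proximity-labeling (BioID-style) enrichment takes per-protein SILAC ratios
against *two* negative controls. Proteins lacking three quantified ratios in
any replicate-control cell are filtered; mean log10 ratios per control
dimension are partitioned with seeded k-means (squared-Euclidean criterion,
best of 25 restarts), and the enriched group is the one whose centroid is
maximal against both controls. The phrase "Euclidean average k-means
cluster analysis" in descriptions of this procedure is internally
contradictory (it names both an agglomerative linkage and a partitional
criterion); it is implemented as seeded k-means, which matches the reported
scatter-plot groupings, and the hierarchical route is available by
clustering the same two-column matrix with `hier_cluster()`.

## Kinetic models

**FRAP.** Recovery follows the biphasic model
$F(t) = F_\infty - A_f e^{-k_f t} - A_s e^{-k_s t}$ with
$A_f + A_s = F_\infty - F_0$. The imaging protocol this emulates samples
only 5, 20, 60 and 120 s plus a full-recovery image — six points cannot
constrain a free biphasic fit, so on sparse grids (≤ 6 post-bleach points)
the fast:slow rate ratio is held fixed (default 10; the synthetic generator
uses the same ratio). The reported halftime is that of the slow exchange
phase, $t_{1/2} = \ln 2 / k_s$, matching the interpretation that the slow
phase reflects exchange of bound protein with the soluble pool. The mobile
fraction is $(F_\infty - F_0)/(F_\mathrm{pre} - F_0)$, by default with the
fitted plateau (an observed full-recovery intensity can be substituted via
`use_fmax`); values outside [0, 1] are clipped and flagged. Fits use
Levenberg–Marquardt with 12 multistarts (log-spaced slow rates × two
amplitude splits) and a relative SSE tolerance of 1e-10; halftime and
mobile-fraction sets are summarised as median/IQR and mean/SD (percent).

**FCS.** The one-component 3D diffusion autocorrelation
$G(\tau) = 1 + \frac{1}{N}(1 + \tau/\tau_D)^{-1}(1 + \tau/(S^2\tau_D))^{-1/2}$
is fitted over $(N, \tau_D)$ with the structure parameter fixed (default 5)
or free. Calibrating with a dye of known diffusion coefficient
($D = 4.0\times10^{-10}\,\mathrm{m^2\,s^{-1}}$ for the green calibration
dye used here) gives the beam waist $\omega = \sqrt{4 D \tau_D}$ and hence
$D = \omega^2/(4\tau_D)$ for any subsequent fit.

**Competition titrations.** The bound probe fraction at competitor
concentration $c$ is $b(c) = b_0 (1 + L/K_p) / (1 + L/K_p + c/K_d)$; under
the trace-probe default ($L \ll K_p$) this is $b_0/(1 + c/K_d)$. Free
parameters are $(b_0, K_d)$, fitted by Levenberg–Marquardt with seven
log-spaced $K_d$ starts spanning the titrated range; the fit warns when the
bound fractions span less than two-fold (the titration then does not
bracket the inflection and $K_d$ is weakly constrained). How the bound
fraction is derived from raw autocorrelation amplitudes upstream is
instrument-specific and is deliberately outside the module boundary: the
titration table is the input.

## What the synthetic data does and does not emulate

`phospho_sim_spec()` defaults describe a three-replicate triple-label
experiment with a label switch (treatments rotate over the isotope labels
between replicates), 10% regulated sites with ±1 log2-unit effects, 0.3
log2-units residual noise (typical for SILAC ratios), localization
probabilities drawn so 31% of sites fall below the 0.75 threshold (matching
a localized fraction of about 69%), and missingness that is logistic in a
latent abundance — low-abundance sites lose observations preferentially,
which is exactly the assumption behind downshifted-normal imputation. Among
regulated sites, 30% carry the planted classical motif (R at −5/−3) and 15%
the extended motif (additionally S at +3); regulated sites without a planted
motif are rejection-sampled away from accidental classical matches so the
planted enrichment is interpretable, while unregulated sites follow the
background frequencies untouched (and therefore match the classical pattern
at the closed-form background rate, which the tests verify).

The kinetic generator's defaults are the study conditions of the FRAP and
FCS experiments it emulates: the 5/20/60/120 s imaging grid plus a
full-recovery point, 2% Gaussian readout noise, 20 traces per condition,
wild-type halftime 33 s and mobile fraction 0.86; titrations of 12 points
spanning 0.021–44 µM with 3% noise. The fast-phase amplitude fraction
(0.3) is a free parameter — reports of this design quantify the slow phase
only — and is stated here once and not revisited.

Deliberately not emulated: peptide-to-site aggregation, protein-level
normalization, heteroscedastic per-site variances, correlated noise across
samples, instrument artefacts (triplet states, afterpulsing, photobleaching
during FCS acquisition). Passing tests on this generator therefore
demonstrate correctness of the statistical machinery under its stated
assumptions, not robustness to every pathology of real spectra.

## Numerical choices and problem sizes

Quadrature for the exact moderated p uses 400 midpoint nodes (error well
below the p values of interest). All nonlinear fits use multistart
Levenberg–Marquardt with `ftol = ptol = 1e-10`. The test suite runs null
calibration on 2,000 simulated sites, motif recovery on 200/500-window
foregrounds/backgrounds, Ward agglomeration oracles on 6×4 matrices, FRAP
recovery on 20-trace batches and titration recovery as the median of 50
simulated replicates — sizes chosen to make sampling error small relative
to the tolerances being checked while keeping the suite fast on a laptop.

One further interface note: this package is driven from R like its
exemplars (limma, DESeq2); the exported functions plus `run_config()` files
are the scripting surface, and no shell entry point is shipped.

## Known limitations

* The exact moderated p assumes homoscedastic sites; with strong
  variance heterogeneity it is approximate (the empirical-Bayes route with
  estimated prior df is intentionally out of scope — the simpler
  median-averaging rule is the method implemented here).
* Collapsing of non-localized multiplicity variants is left to the caller;
  the reader keeps rows as given.
* On sparse FRAP grids the fast:slow ratio is an assumption, not an
  estimate; halftimes are robust to it, the fast amplitude split is not.
* k-means enrichment classification assumes the enriched group is maximal
  in both control dimensions; when no group is, the enriched set is empty
  and a warning is raised rather than guessing.
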