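---
title: "Copy number burden, ancestry screens and immune content from methylation-array copy ratios: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{scnapipe methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnapipe)
```

# What the package models

`scnapipe` analyzes somatic copy number alterations (sCNA) inferred from
log2 copy ratio data, such as the gene- and segment-level copy number
that methylation arrays yield after normalization against a pooled
normal reference. Its stages mirror a complete immunogenomic study of a
two-group tumor cohort with genetic ancestry estimates and censored
clinical outcomes:

1. **Segmentation** (`segment_bins`): bin-level log2 ratios are cut into
   piecewise-constant segments by recursive binary segmentation.
2. **Mixture calling** (`fit_mixture`, `call_segments`): the pooled,
   cohort-wide distribution of segment means is modeled as a mixture of
   three normal components — lost, copy-neutral and gained — fitted by
   expectation-maximization (EM); each segment is assigned its
   maximum-posterior state.
3. **Percent genome altered** (`compute_pga`): per sample, the summed
   length of gained and lost segments divided by the genome size, in
   percent. PGA is the standard global burden measure of genomic
   instability in prostate cancer.
4. **Locus screens** (`screen_group`, `screen_ancestry`): per-locus
   linear models of continuous gene-level copy number on a group label
   or on the continuous African-ancestry fraction, adjusted for age,
   preoperative PSA and binary Gleason Grade Group (GG1–2 vs GG3–5),
   with Benjamini–Hochberg FDR across loci.
5. **Germline filtering** (`derive_germline_set`, `filter_germline`):
   loci whose copy number differs between groups *in normal tissue* are
   germline copy number variants (gCNV), not tumor-acquired events; they
   are removed from tumor hit lists by locus id, with the overlap
   arithmetic reported.
6. **Outcome screens** (`cox_screen`, `km_logrank`): per-locus Cox
   proportional hazards models of biochemical recurrence and metastasis
   adjusted for ancestry, age, PSA and grade; Kaplan–Meier and log-rank
   for categorical gain calls at a candidate locus.
7. **Immune deconvolution** (`deconvolve`, `correlate_with_pga`):
   cell-type fractions from methylation beta values by constrained least
   squares against a signature matrix, and Spearman correlation of an
   immune fraction (typically Tregs) with PGA.
8. **Concordance** (`per_locus_correlation`, `cat_curve`): per-locus
   rank correlations between two copy number matrices and
   correspondence-at-the-top curves for cross-platform agreement.

A synthetic cohort generator (`simulate_cohort`) plants ground truth for
every one of these stages, so the whole pipeline is testable end to end.

# The three-component mixture and PGA

Segment means $x_i$ (log2 copy ratio, optionally weighted by supporting
bin count $w_i$) are modeled cohort-wide as

$$x_i \sim \pi_L \, \mathcal N(\mu_L, \sigma_L^2) +
          \pi_N \, \mathcal N(\mu_N, \sigma_N^2) +
          \pi_G \, \mathcal N(\mu_G, \sigma_G^2),$$

with components relabeled after fitting so $\mu_L < \mu_N < \mu_G$.

Numerical choices, all of which matter on real data:

* **Initialization** is deterministic: means at the 10th/50th/90th
  percentiles of the data, standard deviations at half the pooled SD,
  weights $(0.15, 0.70, 0.15)$. Quantile starts keep the labels stable
  and avoid the label-switching churn of random initialization.
* **Weighting** defaults to `by_bins`: the precision of a segment mean
  scales with the number of bins that support it. `by_length` and
  `none` are available for sensitivity analysis.
* **Convergence** at relative log-likelihood change below `tol = 1e-8`,
  capped at 500 iterations. The log-likelihood trace is retained and is
  non-decreasing — a property the test suite asserts on every fit.
* **Degeneracy**: component SDs are floored at $10^{-3}$ log2 units so
  that near-constant data cannot blow up the likelihood. A fit whose
  component means collapse is flagged `degenerate` but still usable;
  numerically failed fits are restarted from jittered quantile starts
  and only raise after repeated failure.
* **Ties** in the hard call are broken toward neutral: a segment exactly
  equidistant between neutral and gain is conservative, not a call.

PGA is then plain arithmetic: per sample,
$\mathrm{PGA}_{\text{gain}} = 100 \sum_{\text{gain segs}} \ell_s / G$
with $G$ the total genome size, similarly for losses, and
$\mathrm{PGA} = \mathrm{PGA}_{\text{gain}} + \mathrm{PGA}_{\text{loss}}$.
Samples with *no* altered segment are reported with PGA 0 and flagged
`excluded`; downstream PGA correlations drop them, which mirrors the
usual practice of excluding samples without any called segmental sCNA.
We use pure posterior argmax as the calling cutoff; a minimum-posterior
threshold would be easy to add but is not part of the default contract.

# Segmentation

Methylation-array copy number workflows usually delegate segmentation to
array-specific tooling; here it is a self-contained recursive binary
segmentation with
a Welch-type two-sample statistic at every candidate split and a
normal-theory p-value, accepting a split when $p < \alpha$ (default
0.01) and both sides keep at least `min_bins = 5` bins. This is not a
full circular binary segmentation: there is no permutation null and no
circularization. It is deterministic, fast at desk scale, and the
downstream mixture/PGA contract only requires reasonable
piecewise-constant fits — the recovery tests show breakpoints within
±2 bins of truth in over 95% of noisy replicates at a step of one log2
unit over noise SD 0.1.

A perfectly clean break (zero within-side variance, materially different
means) is always accepted; constant stretches are never split.

# Locus screens and their adjustment sets

Gene-level values are the overlap-length-weighted mean of segment means
across each annotation interval (`summarize_loci`), `NA` where nothing
overlaps. Loci missing in more than 10% of samples are dropped before
screening; remaining missing values are mean-imputed per locus to keep
design matrices full rank. The group screen uses limma's empirical-Bayes
variance moderation by default; the ancestry screen defaults to plain
per-locus least squares ("GLM" style) — both paths share the same
coefficients and differ only in the variance estimate. PSA enters
untransformed by default (`log_psa = TRUE` is available); grade enters
as the binary low (GG1–2) vs high (GG3–5) contrast throughout. Both
screens adjust for age, PSA and grade by default; where a study's two
descriptions of the adjustment set disagree, the `covariates` argument
makes either choice explicit.

Germline derivation runs the same group screen on the normal-tissue
cohort with *no* clinical covariates by default (normal-tissue donors
typically lack tumor covariates) at a deliberately stringent FDR of
0.001, so that only strongly supported loci are subtracted from tumor
lists. Matching between cohorts is by locus id within a shared
annotation; coordinate fuzz-matching is out of scope. Overlap
percentages are rounded to the nearest integer, matching how such
numbers are conventionally reported.

# Survival models

`cox_screen` fits one Cox model per locus with Efron tie handling via
the survival package, records per-locus failures as `NA` rows rather
than aborting a genome-wide screen, requires at least 10 events, and
BH-adjusts the Wald p-values. The Kaplan–Meier validation path
(`call_loci` + `km_logrank`) stratifies by the mixture's categorical
gain call at a candidate locus. A figure-legend notion like
"gains (>2 copies)" is mapped to the gain mixture component rather than
an absolute copy threshold, because log2-ratio data carry no absolute
copy count without purity/ploidy modeling; `call_loci(gain_cutoff =)`
offers a fixed log2 cutoff instead. PGA-based survival models reuse
`cox_screen` with the PGA vector as a one-column matrix
(`pga_survival`), continuous or in cohort quartiles.

# Deconvolution

`deconvolve` solves, per sample, $\min_f \|S f - b\|_2$ subject to
$f \ge 0$ and $\sum_k f_k = 1$, where $S$ is the signature matrix over
the shared CpGs and $b$ the sample's beta vector. The solver is
Lawson–Hanson non-negative least squares on a system augmented with a
heavily weighted sum-to-one row, followed by exact renormalization;
it is deterministic and recovers noiseless mixtures to machine
precision. This is a constrained-least-squares stand-in for
support-vector-regression deconvolution tools (e.g. the
methylCIBERSORT family): it satisfies the same input/output contract
and is exactly testable by round-trip, but it is not a reimplementation
of those tools, and absolute fraction values from real signatures are
not expected to match them numerically — only the correlation structure
downstream is comparable. Spearman correlations use average ranks for
ties.

# The synthetic cohort generator

`simulate_cohort` is first-class, tested code, and its defaults *are*
the study conditions the rest of the package is validated under:

* **Cohort**: 145 + 145 tumors in two groups, 88 + 40 normal-tissue
  samples, on a toy genome of five 50 Mb chromosomes — large enough to
  exercise multi-chromosome bookkeeping while keeping a full pipeline
  run under half a minute.
* **Ancestry** is drawn from a two-component Beta mixture (shapes (8,2)
  for one group, (1.2,20) for the other), putting one mode near 0.8 and
  one near 0, so group label and continuous ancestry are strongly but
  not perfectly correlated — both kinds of screens are exercised on one
  cohort. The within-group distribution of ancestry fractions is our
  choice; real cohorts vary.
* **Segments**: each chromosome is cut at Poisson(7) uniform
  breakpoints; planted loci are carved out as dedicated segments.
  Background segment states are drawn from the configured mixture with
  default weights (0.025, 0.95, 0.025) and component means (−0.5, 0,
  +0.5) at SD 0.08. These defaults put the simulated median PGA near 4%
  with roughly a tenth of samples having no altered segment, the regime
  reported for surgically treated primary prostate cancer. Normal
  tissue is copy-neutral outside germline loci.
* **Planted loci**: alteration indicators are Bernoulli with logistic
  probability in ancestry,
  $\mathrm{logit}\, p = \mathrm{logit}(p_0) + \beta \cdot \text{ancestry}$.
  Germline-flagged loci follow the same law in the normal cohort;
  somatic loci never alter normal tissue. The default hazard locus is
  gained with probability 0.19 — the ballpark frequency of clinically
  consequential 8q/MYC gains in primary prostate cancer.
* **Outcomes**: exponential event times with log hazard 0.8 per gain at
  the hazard locus plus modest covariate effects (grade 0.7, age
  0.02/yr, PSA 0.01/(ng/mL)), under independent uniform administrative
  censoring on [0, 15] years — the simplest censoring satisfying the
  Cox model's assumptions. Baseline rates (BCR 0.06/yr, metastasis
  0.025/yr) give roughly 100 BCR and 60 metastasis events per 290
  samples.
* **Treg–PGA coupling** uses a Gaussian copula on ranks with target
  Spearman rho 0.4, which controls the rank correlation directly
  without distorting either margin.
* **Noise** (`noise_sd = 0.1` log2 units) is added both to
  planted-locus segment means and to locus-level measurements,
  emulating probe-level variability on top of segmentation noise.

What the generator does *not* emulate: probe chemistry and raw
two-channel intensities, GC/wave artifacts, tumor purity and subclonal
fractions, correlated noise along the genome, and tissue-specific
germline effects. Tests passing on this generator therefore demonstrate
the correctness and calibration of the statistical machinery under its
stated model, not robustness to every artifact of real arrays.

# Problem sizes used in validation

The shipped test suite validates at these scales, chosen as desk-scale
representatives of the study design: mixture recovery on 10,000 pooled
segment means; full-cohort EM/PGA recovery at 290 samples; screen
calibration at 290 samples × 2,000 loci over 50 seeds and power at 20
planted loci; Cox recovery over 20 seeded cohorts of 290 with ~60
metastasis events; deconvolution with 10 cell types over 600 CpGs; and
Treg–PGA recovery at n = 250. With ~60 events and a 19% gain
prevalence, a per-gain log hazard ratio of 0.8 sits near the detection
boundary at FDR 0.1 (Wald z ≈ 2.4), so single-candidate detection
rates around 75–80% are the analytic expectation at that design point,
and confidence intervals for the per-gain effect are mildly attenuated
by gain-call misclassification; both behaviors are visible in the
validation suite and are properties of the design point, not of the
implementation.

# Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
res <- run_pipeline(cfg, outdir = "pipeline_out")

res$mixture              # fitted cohort mixture
head(res$pga)            # per-sample percent genome altered
res$ancestry_filtered$summary  # germline filtering arithmetic
res$treg_pga             # Treg fraction vs PGA, overall and per group
```

# Known limitations

* Segmentation is recursive binary segmentation, not CBS; very short
  events below `min_bins` bins are invisible by construction.
* The mixture is cohort-pooled, as the segment-calling design requires;
  per-sample mixtures (useful under variable purity) are out of scope.
* The deconvolution is a linear least-squares method; it will differ
  from SVR-based estimates on real signatures, especially for rare cell
  types.
* Germline filtering by locus id assumes both cohorts were summarized
  against the same annotation, and cannot detect tissue-specific gCNV.
* The exclusion rule for zero-alteration samples reproduces the
  analysis convention; the exact number excluded in any real cohort
  depends on that cohort's data and is not a reproducible constant.
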