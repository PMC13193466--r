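---
title: "Methods: pre-diagnostic circulating miRNA trajectories"
author: "miRtraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pre-diagnostic circulating miRNA trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Nested case-control studies of pancreatic ductal adenocarcinoma collect
plasma years before diagnosis and ask whether circulating miRNAs carry an
early signal. Each case is matched 1:1 to a cancer-free control from the
same cohort on age at draw (±2 years), sex, race/ethnicity and draw date
(±90 days). The central time axis is the **lead time**: years from blood
draw to the case's diagnosis. miRtraj implements the four analysis stages
such a study needs — count normalization, matched association, log-ratio
trajectory modelling, and time-dependent risk prediction — together with a
synthetic cohort generator that makes every stage testable without
restricted data.

```{r, eval = FALSE}
library(miRtraj)
x  <- generateCohort(cohortConfig(seed = 1))   # 1307 matched pairs
xn <- normalizePipeline(x)
assoc <- associationTable(xn)
trend <- trendTable(xn, assoc = assoc)
auc   <- aucCurve(xn, trend$table$probe_id[trend$table$p < 0.05])
```

## Normalization

Digital counting (nCounter-style) panels report one count per probe. The
panel carries 798 endogenous human miRNA probes, eight negative controls
(no target), six positive controls in a titration ladder, and five
non-mammalian spike-in oligos added to plasma at fixed amounts before RNA
extraction. Normalization proceeds in a fixed order:

1. **Background correction** — subtract, per sample, the arithmetic mean
   of the negative-control counts; floor at zero. The floor is our choice;
   negative normalized counts have no interpretation.
2. **Spike-in normalization** — scale each sample by
   `ref / mean(three spike-in counts)`. The spike-ins (ath-miR159a,
   cel-miR248, osa-miR414) calibrate extraction efficiency and input
   volume. The default reference is the geometric mean of the per-sample
   spike means; under that anchoring, multiplying one sample's raw counts
   by `c` multiplies every fully normalized value by exactly `c^(1/S)`
   (`S` = number of samples) while all between-sample ratios are exactly
   invariant. `ref = "nominal"` anchors to the known spike input instead,
   making each sample's normalized values strictly invariant to rescaling
   of that sample alone.
3. **Content normalization** — scale by the geometric mean of a shared
   content set: the 50 endogenous probes with the highest mean count,
   *excluding* hsa-miR-320e, hsa-miR-16-5p and hsa-miR-451a. These three
   are red-blood-cell miRNAs: hemolysis inflates them by close to an order
   of magnitude, and if they sat in the content set a hemolysed sample
   would scale itself down by its own contamination. The content set is
   global (not per-sample) so that factors are comparable across samples.
   Zeros are replaced by 0.5 inside the geometric mean only.
4. **Quantile normalization** (optional, on by default) — classic
   rank-mean normalization over endogenous probes across the whole sample
   set; within-sample ties receive the mean of the target values they
   span. With ties present the "identical sorted vectors" property holds
   in its tie-averaged form; on continuous (tie-free) values it is exact.

Swapping steps 2 and 3 changes the output; the pipeline enforces the
order above and records it in an append-only stage tag. Per-sample
factors are kept in `normFactors()`; on simulated data their log product
correlates with the true log extraction efficiency at r < −0.9.

Sample QC (`qcSample`) follows vendor conventions where the count matrix
allows: positive-control linearity (R² of log counts against the log
titration ladder, default minimum 0.9), a limit-of-detection check
(second-lowest positive control above the negative mean + 2 SD), and a
binding-density *proxy* (total counts / 160,000, kept within
[0.1, 2.25]). True binding density and field-of-view counts are imaging
quantities not derivable from counts; FOV is checked only when a
`fov_ratio` column is supplied. A failed sample removes its whole pair —
a matched design cannot use singletons.

## Matched association

Expression is recoded per probe to deciles 1–10 using the pooled
case+control percentiles *within each lead-time window* ((0,5], (5,10],
>10 years by the case's lead time; 5.0 falls in the first window). Decile
coding makes odds ratios comparable across miRNAs and invariant to any
monotone renormalization. Cutpoint ties share the lower decile; a
constant probe is flagged degenerate.

For each probe we maximize the 1:1 matched conditional likelihood
`L(β) = Π_i σ(βᵀΔx_i)` over case-minus-control differences Δx (decile
score plus adjustment covariates: age, BMI, smoking as former/current
indicators with never as reference, diabetes, family history) by
Newton–Raphson with analytic gradient and Hessian (score-norm tolerance
1e-8, 50 iterations max). Matching variables difference out. Wald 95%
intervals and p-values are reported per one-decile increase; |β| > 15 or
a singular Hessian is treated as separation and flagged non-converged.
For a single binary exposure this estimator reduces to the discordant
pair ratio a/b, which the tests exploit as a closed-form oracle, along
with a grid-search maximizer and `survival::clogit`.

Benjamini–Hochberg adjustment is applied across probes within each
window with an explicit family size `m_total` (default: the full panel,
798) so that probes filtered before testing still count toward the
family.

## Log-ratio trajectories

For each matched pair the statistic is `log(case / control)` of the
normalized value (natural log; a 0.5 pseudocount is added to both terms
only when either is zero, so the bulk of ratios is unbiased). Restricted
to pairs with lead time ≤ 10 years (inclusive), ordinary least squares of
log-ratio on lead time gives a slope per year with a t-test. The expected
pattern is a "scissors": miRNAs elevated in cases near diagnosis drift
back toward parity as lead time grows (negative slope read against lead
time), while depressed miRNAs do the reverse.

Participants with 2–3 repeated pre-diagnostic draws are modelled with a
participant-level random intercept (`lme4::lmer`, REML), Wald z-test on
the lead-time slope. Two or three points per participant cannot identify
a slope variance, so no random slopes are fitted. If the mixed fit errors
out, a pooled OLS fit with CR1 cluster-robust standard errors is the
fallback and is labelled as such.

## Time-dependent risk prediction

Four nested models are compared: Model 1 = age, BMI, smoking, diabetes,
family history; Model 2 = Model 1 + log CA19-9; Model 3 = Model 1 + the
slope-significant miRNAs (log2 of normalized value, standardized);
Model 4 = everything. Coefficients come from the same conditional
(matched) likelihood — faithful to the design — while discrimination is
summarized unconditionally: `AUC(t)` restricts to pairs whose case lead
time is at most `t` (a cumulative reading, consistent with reporting
"5-year AUCs" in the same series) and computes the Mann–Whitney
probability that a case score exceeds a control score over all
case × control combinations in the restricted set, ties counting one
half. Apparent AUC of a larger ML-fitted model is *not* guaranteed to
dominate a nested one (ML maximizes likelihood, not AUC); the guaranteed
monotonicity is in the in-sample conditional log-likelihood, which is
what the tests assert exactly.

Internal validation resamples *pairs* with replacement, refits all
models in-bag, and evaluates AUC(t) out-of-bag; the mean and 2.5/97.5
percentiles across B = 500 replicates (seeded, reproducible) are
reported. The share of Model 4 discrimination attributable to CA19-9 is
operationalized as `(AUC₄ − AUC₄₋CA199) / (AUC₄ − 0.5)` — an
above-chance share, one of several possible decompositions; the output
carries its definition. Sensitivity filters restrict to early-stage
(TNM I/IIA) cases or to pairs with lead time strictly above one year,
always removing whole pairs.

## The synthetic cohort generator

`generateCohort()` emulates the structure of a five-cohort study of 1307
matched pairs (290/395/154/468 across four cohort groups). Its defaults
are the study conditions, fixed once:

* **Lead time** — per-cohort gamma laws truncated to [0.03, 19.61] years
  with truncated medians 3.7, 9.4, 6.5 and 8.2 years (shape/scale
  1.33/3.67, 3.39/3.27, 2.35/3.28, 1.98/5.64), matching the cohort-level
  medians and approximating the IQRs.
* **Counts** — probe `k`, sample `s` is Poisson around
  `background + e_s · exp(μ_k + Δ_ks + ε_ks)`: background rate 10,
  extraction efficiency `e_s = exp(N(0, 0.35))`, measurement noise
  `ε ~ N(0, 0.4)`, baselines `μ_k ~ N(4, 1.2)` for filler probes and
  `N(5.5, 0.5)` for the signal panel (detected miRNAs are well
  expressed); the hemolysis trio sits at μ ≈ 6.8–7.6, real plasma's most
  abundant species. Spike-ins scale with `e_s` around nominal levels;
  positive controls follow a fixed 4-fold ladder with tighter noise
  (SD 0.15) since they bypass extraction; negatives are pure background.
* **Trajectories** — case samples of signal probes get
  `Δ = a_k + b_k · min(leadtime, 10)`; beyond 10 years the difference is
  held at its 10-year value (the trend analysis fits only the first
  decade). The default "scissors" panel has 2 oncogenic miRNAs
  (a > 0, b < 0) and 11 suppressors (a < 0, b > 0) with slopes 0.03–0.10
  per year, the magnitude scale reported for pre-diagnostic plasma
  panels; intercepts are set so the window-mean log-ratios have the
  reported sign pattern.
* **Hemolysis** — sample-level Bernoulli (p = 0.05) with a log-normal
  factor (median 8) multiplying exactly the three red-blood-cell marker
  miRNAs: the artifact the content-set exclusion exists to absorb.
* **Covariates** — drawn per cohort from Table-1-like prevalences; cases
  are enriched for current smoking (constant OR 2) and diabetes with an
  odds multiplier ramping from 3 at diagnosis to 1 at 10 years of lead
  time (prodromal new-onset diabetes), so the risk-factor model has
  modest, fading discrimination.
* **CA19-9** — a stand-in: log-normal baseline with case log-shift
  `γ · max(0, 1 − leadtime/τ)` (γ = 1.5, τ = 3 years). The emulated
  study names no assay, units or timing for CA19-9, so this model and
  its U/mL calibration are synthetic plumbing, labelled as such.

What the generator does *not* emulate: between-person biological
variability at the scale real plasma shows (observed log-ratio SDs in
published panels are several-fold larger than the generator's ~0.9, so
real-data power is lower than synthetic power at equal n); storage-
duration degradation; cartridge/batch effects (matched pairs are run in
the same batch by design, so pair differences are batch-free either
way); sequencing-style count distributions. Passing tests therefore
demonstrate correctness of the machinery and calibration of its
inferential claims under the stated model — not effect sizes in any real
population.

## Numerical choices and degenerate inputs

* Newton–Raphson from β = 0; separation flagged at |β| > 15 or singular
  information; non-converged probes carry NA statistics and are excluded
  from the FDR ranking.
* OLS trend by closed-form normal equations (matches `lm` to 1e-10);
  a perfect fit reports SE 0 with p = 0 (or p = 1 when the slope is 0);
  fewer than 3 in-window pairs is an error, as is a constant lead time.
* Decile cutpoints from `quantile()` type 7; ties share the lower
  decile; degenerate (constant) probes score 1 everywhere and are
  flagged.
* Zero-containing pairs get the 0.5 pseudocount; both-zero pairs return
  log-ratio 0 and a degenerate flag.
* Bootstrap replicates with an empty out-of-bag set for a horizon are
  skipped and counted.
* All generator and bootstrap randomness is seeded; equal seeds give
  byte-identical outputs, and `runPipeline()` hashes every stage output
  into its run manifest.

## Problem sizes used in the shipped validation

The test suite and `scripts/acceptance.R` run the generator at the sizes
the validation questions need: the full 1307-pair, 798-probe
configuration for the nested-model AUC pattern; 1000 pairs for slope
sign recovery; 100 replicates of 300 pairs for interval coverage; 2000
replicates of 400 pairs (20-probe all-null panel) for the trend test's
type-I error; 20 replicates of 450 pairs for false-discovery counts; and
a 200-pair, 150-probe double run for end-to-end byte reproducibility.

## Known limitations

* The conditional logistic engine handles 1:1 matching only.
* The CA19-9 decomposition is definition-dependent; alternative
  decompositions (e.g. likelihood- or variance-based) would give
  different shares.
* Window-specific decile cutpoints (cases+controls pooled) are one of
  several defensible conventions; they are configurable but the default
  is fixed and documented rather than asserted to be the only choice.
* The mixed model assumes exchangeable residuals within participant;
  with 2–3 draws that assumption is untestable.
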