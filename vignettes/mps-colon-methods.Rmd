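---
title: "Deriving and applying a median-dichotomized prognostic score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and applying a median-dichotomized prognostic score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpscolon)
```

## The problem and the model

Patients with colorectal or gastric cancer at the same TNM stage show very
different outcomes, and transcriptome profiles carry part of that missing
prognostic information. The obstacle to using expression directly is that
absolute expression values are not comparable across platforms: an RNA-seq
count and a microarray intensity for the same gene live on different
scales, and even two arrays disagree after normalization. `mpscolon`
implements a scoring system built to be *platform-independent* by
construction: every quantity that enters the score is a within-cohort
**median dichotomization** — is this patient's expression of gene *g*
above or at-or-below the median of the cohort being scored? Any strictly
monotone transform of one gene's measurements (a platform change, a
log-transform, a rescaling) preserves every patient's median status, so it
provably cannot change the score. That claim is checked literally in the
test suite.

The score itself, mPS (molecular Prognostic Score), is a weighted sum of
binary gene scores over a small signature. For each signature gene the
patient's status (HIGH = strictly above the cohort median, LOW otherwise;
ties count as LOW so the HIGH group is strictly above the cutoff) is
mapped through a step function against the gene's pooled ("integrated")
hazard ratio from a multi-cohort meta-analysis:

* Gene_Score = 1 if status is LOW and the integrated HR < 1 (a protective
  gene that this patient under-expresses), or if status is HIGH and the
  integrated HR > 1 (a harmful gene over-expressed);
* Gene_Score = 0 otherwise. An HR of exactly 1 falls outside the step
  function's cases; it scores 0 with a warning.

The mPS is `sum(weight_g * gene_score_g)`, with positive weights that sum
to the score maximum (50), so the score ranges over [0, 50]: 0 means every
gene sits at its favourable status, 50 every gene at its unfavourable one.
Patients are stratified into four published risk groups at cuts 10, 25 and
40. The package ships the published 16-gene colon-cancer signature
(`mps_colon_signature()`: 6 HIGH-direction and 10 LOW-direction genes,
weights summing to exactly 50.000) and can also learn new signatures from
data.

## The derivation pipeline

Deriving a signature runs two consecutive filters followed by a sparse
regression; each stage is an exported function and `run_derivation()`
chains them.

**Filter 1 — differential expression (`call_degs`).** Candidate genes must
differ between tumor and adjacent normal tissue. Counts are normalized by
median-of-ratios size factors, per-gene negative-binomial dispersions are
estimated by a method-of-moments estimator shrunk toward a trended
mean–dispersion fit (floored at 1e-8), and each gene gets a likelihood-
ratio test (one NB mean per arm vs a shared mean, dispersion fixed,
chi-squared on 1 df). A gene is a DEG iff BH-adjusted q < 0.01 **and**
|log2 fold change| > 1, both strict. The dispersion estimator is
deliberately simple; it is validated by simulation (parameter recovery
within 25% at n = 200, null false-discovery control) rather than by
bit-equivalence with any particular DE tool, and the package's error-rate
guarantees are stated at that simulation level.

**Filter 2 — prognostic meta-analysis (`select_prognostic`).** For every
DEG and every survival cohort, expression is dichotomized at the
within-cohort median and the high-vs-low hazard ratio for the cohort's
survival endpoint is estimated by univariate Cox regression
(Newton–Raphson on the Breslow partial likelihood; convergence |Δβ| <
1e-8, at most 50 iterations; monotone-likelihood fits are flagged and
excluded). Per-gene log hazard ratios are pooled across cohorts by
DerSimonian–Laird random effects: fixed-effect weights 1/se², Cochran's Q,
τ² = max(0, (Q − (k−1)) / (Σw − Σw²/Σw)), re-weighting by 1/(se² + τ²),
and a two-sided p-value from the normal approximation. Genes with pooled
p < 0.01 pass; each carries its integrated HR = exp(pooled log HR), which
later fixes the gene's scoring direction. Genes degenerate in one cohort
(constant expression, missing values, non-convergence) are pooled over the
remaining cohorts.

A calibration note: the DL normal-approximation test is conservative at a
small number of cohorts. With k = 4 homogeneous cohorts the estimated τ²
is positive for roughly 40% of null genes purely by chance (whenever
Q > k−1), which inflates the pooled standard error; the realized selection
rate of null genes at nominal p < 0.01 is about 0.7% in this package's
simulations (and ~0.8% even when the pooling is fed exactly normal
inputs). The filter therefore errs on the safe side — it admits *fewer*
null genes than the nominal level suggests.

**Training (`lasso_fit`, `extract_signature`).** Candidate genes are
binarized in the training cohort (Gene_Score against each gene's
integrated HR) and an L1-penalized linear model predicts the truncated
target y = 60 − min(t, 60) months, i.e. the part of a five-year window the
patient did not survive event-free. The objective is fixed as
(1/2n)·‖y − β₀ − Xβ‖² + λ·Σ|β| with an unpenalized intercept and **no**
predictor re-standardization (the design is 0/1 by construction), solved
by cyclic coordinate descent with soft-thresholding to tolerance 1e-7.
λ defaults to 0.5 and can be chosen on a held-out validation half over the
grid (0.01, 0.05, 0.1, 0.5, 1) by validation mean-squared error (ties go
to the smaller λ). Genes with nonzero coefficients form the signature;
weights are |β| rescaled to sum exactly to 50, and each gene's direction
is HIGH if its integrated HR > 1, LOW otherwise.

Two ambiguities in this construction are surfaced rather than hidden.
First, the regression target uses each patient's recorded follow-up time
whether or not the event was observed; censored patients therefore enter
with an optimistic y. This reproduces the score's stated construction; a
stricter analysis can pre-filter to relapsed-or-fully-followed patients
before calling `build_target()`. Second, the published penalty value 0.5
originated in a different optimizer's parameterization; here λ is defined
against the objective above, with 0.5 the default and the grid search the
recommended route.

**Validation (`run_validation`, `evaluate_strata`).** A scored cohort is
assessed with Kaplan–Meier curves per stratum, a k-group log-rank test,
univariate Cox regression on the stratum factor (lowest stratum as
reference), and optionally a multivariate Cox model with clinical
covariates. Breslow tie-handling is the default (Efron available).
External validation can truncate follow-up at 120 months (administrative
censoring). When any populated stratum holds fewer than 10 patients the
four-way split collapses to a two-way split; the published description of
the two-way split does not state its cutoff, so the package splits at the
central published cut, 25.

## Tunable parameters

| Parameter | Default | Units / range | Where |
|---|---|---|---|
| DEG FDR threshold | 0.01 (strict <) | q-value | `call_degs` |
| DEG fold-change threshold | 1 (strict >) | \|log2 FC\| | `call_degs` |
| dispersion shrinkage toward trend | 0.3 | weight in [0,1] | `estimate_dispersion` |
| meta-analysis p threshold | 0.01 (strict <) | two-sided p | `select_prognostic` |
| lasso penalty λ | 0.5 | objective units | `lasso_fit` |
| λ grid | 0.01, 0.05, 0.1, 0.5, 1 | — | `tune_lambda` |
| target truncation | 60 | months | `build_target` |
| score maximum | 50 | score points | `extract_signature` |
| strata cuts | 10, 25, 40 | score points, left-closed | `stratify` |
| two-way fallback trigger | 10 | patients per stratum | `evaluate_strata` |
| validation truncation | 120 | months | `run_config` |

Boundary conventions, chosen once and logged where they fire: median ties
are LOW; strata bins are left-closed (a score of exactly 25 is stratum 3,
and the maximum 50 belongs to stratum 4); an integrated HR of exactly 1
scores 0 with a warning.

## What the synthetic-data generator emulates

`simulate_paired_counts()` draws NB counts for a tumor and a normal arm
sharing log-normal baseline abundances (default 1000 genes, 40 samples per
arm, expected depth 1e5, dispersion 0.2 — a realistic biological CV for
tumor cohorts), with a chosen subset of genes given a multiplicative
fold-change (default 50 genes at log2 FC = 2).

`simulate_survival_cohorts()` builds several cohorts (default 4 × 150) of
log-scale expression with a per-gene, per-cohort N(0, 1) platform shift —
each cohort measures each gene on its own offset scale, which is exactly
the situation median dichotomization is meant to survive. The first
`n_planted_prognostic` genes (default 20) drive an exponential event
hazard through their median status: hazard = 0.02/month ×
exp(Σ β·sign·(status − ½)) with β = 0.7, alternating signs, plus optional
stage (1–4, log HR 0.35 per step) and sex (log HR 0.1) covariate effects.
Censoring is independent exponential with its rate solved numerically so
the expected censored fraction hits the target (default 0.5, typical of
relapse-free-survival cohorts). All randomness flows from one seed.

Two honest limitations of the generator, hence of what passing tests can
show about real data: expression is Gaussian on the log scale with
independent genes (no correlation structure, no library-size or batch
pathology beyond the stated platform shift), and the hazard truly depends
on median *status*, matching the model the filter estimates. Real
cohorts violate both — effects are continuous and correlated — so the
simulations demonstrate correctness of the machinery, not clinical
performance. A `continuous_effect` mode lets the hazard act on the
standardized continuous expression instead, for robustness checks. Note
also that with many planted genes acting multiplicatively on one hazard,
each gene's *marginal* dichotomized hazard ratio is attenuated below its
planted conditional value (omitted-covariate attenuation in proportional
hazards); recovery rates in the tests are floors stated with that
attenuation in effect.

## Numerical choices

* Cox fits: Newton–Raphson with step clamping at ±2, |Δβ| < 1e-8; the
  observed information gives the SE; |β| ≥ 15 or a non-finite SE flags
  monotone likelihood and the estimate is excluded from pooling.
* Dispersion floor 1e-8; all-zero genes are flagged and skipped.
* Coordinate descent: deterministic cyclic order, convergence when the
  largest coefficient change in a sweep falls below 1e-7 (1e-10 where
  tests compare against closed forms); constant-zero columns are dropped
  with a warning.
* Signature weights are written as fixed-precision decimal strings so
  files round-trip byte-stably at the published 3-decimal precision.
* Problem sizes in the test suite (e.g. 50 null replicates of 2000 genes
  for FDR control, 25 replicates of the 500-gene / four-cohort / 400-
  patient recovery study, 10⁴ permutations for the log-rank check) were
  chosen as the smallest sizes at which the Monte-Carlo error is
  comfortably below each criterion's tolerance.

## Design choices where the design was open

* **Medians are recomputed on the cohort being scored**, never frozen from
  training: platform independence is the point of the dichotomization, and
  frozen absolute cutoffs could not transfer across platforms. For
  single-sample use a `medians` override accepts externally fixed cutoffs.
* **Probe-to-gene collapsing is left to the user**: inputs are gene-level
  matrices; how multiple probes were collapsed upstream is documented by
  the user, not guessed here.
* **Expression/clinical sample mismatches** are joined on the intersection
  with a logged count of dropped samples.
* **Genes with missing values in a cohort are excluded from that cohort's
  dichotomization** (a median over partial data would distort the cutoff)
  and pooled over the remaining cohorts.
* **DerSimonian–Laird** is the random-effects estimator (the classic
  default of the meta-analysis ecosystem); the conservatism noted above is
  accepted as the cost of that fidelity.
* The command-line surface is the R API itself: every pipeline stage is an
  exported function and `run_derivation()`/`run_validation()` provide the
  orchestrated one-call versions with a machine-readable run report
  (per-stage gene counts, chosen λ, convergence, seed, config hash).

## Known limitations

Beyond the generator caveats above: no paired-sample design or covariate
adjustment in the DE stage (two-group comparison only); no Cox-lasso
variant (the training target is the linear truncated-survival
construction); no publication-bias diagnostics in the meta-analysis; no
proportional-hazards diagnostics; date arithmetic is out of scope (times
are supplied in months). None of the statistics here should be read as a
clinical claim: the package reproduces and tests a published scoring
*procedure*; applying it to real cohorts requires the usual external
validation.
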