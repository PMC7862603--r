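# mpscolon

Derivation and application of **mPS_colon**, a platform-independent
molecular prognostic score for gastrointestinal tumors.

Patients with colorectal or gastric cancer at the same stage show widely
different outcomes. mPS_colon stratifies relapse risk from the expression
of only 16 genes, and it does so in a way that transfers across RNA-seq
and microarray platforms: every gene contributes only through its binary
**median status** — whether the patient's expression lies above or
at-or-below the median of the cohort being scored — which is invariant
under any monotone rescaling of one gene's measurements.

For each signature gene *g* with scoring direction and weight *w_g*, the
patient's Gene_Score is 1 exactly when the patient sits in the gene's
unfavourable group (HIGH expression of a gene whose pooled hazard ratio
across cohorts exceeds 1, or LOW expression of a protective gene), and

&nbsp;&nbsp;&nbsp;&nbsp;mPS = Σ_g w_g · Gene_Score_g ∈ [0, 50],

with the published weights summing to exactly 50.000. Scores map onto four
risk strata at cuts 10, 25 and 40.

The package implements the full derivation pipeline as well as scoring:

1. **DEG filter** — negative-binomial likelihood-ratio tests between
   tumor and normal counts; a gene passes iff BH-FDR q < 0.01 and
   |log2 fold change| > 1 (`call_degs`);
2. **Prognostic filter** — per-cohort median dichotomization, univariate
   Cox hazard ratios (Breslow ties), DerSimonian–Laird random-effects
   pooling across cohorts, selection at pooled p < 0.01
   (`select_prognostic`);
3. **Training** — Gene_Score binarization, lasso on the truncated target
   60 − min(DFS, 60) months (coordinate descent, λ default 0.5 or tuned on
   a validation half over the grid 0.01–1), weights renormalized to 50
   (`lasso_fit`, `extract_signature`);
4. **Scoring & validation** — mPS computation, four-way stratification,
   Kaplan–Meier / log-rank / Cox validation with optional 10-year
   truncation (`score_cohort`, `evaluate_strata`).

A synthetic-data module (`simulate_paired_counts`,
`simulate_survival_cohorts`) generates count data with planted
fold-changes and multi-cohort survival data with planted median-status
hazard effects, so the whole pipeline is exercised end-to-end without any
external downloads. The published 16-gene signature ships as a plain-text
fixture in TSV and JSON form (`mps_colon_signature()`).

## Worked example

Score two patients with the published signature, then run a full
synthetic derivation:

```r
library(mpscolon)

sig <- mps_colon_signature()
sig
#> <mps_signature> 16 genes (6 HIGH, 10 LOW), max score 50
#>    gene_id entrez_id direction weight
#> 1     PER3      8863      HIGH  5.100
#> ...
#> 16    SIAE     54414       LOW  0.174

# a patient at the unfavourable status for every gene scores the maximum
scores <- matrix(1, 16, 1, dimnames = list(sig$gene_id, "patient1"))
compute_mps(scores, sig)
#>   sample_id mps stratum
#> 1  patient1  50       4
```

End-to-end on synthetic data — 300 genes with 30 planted DEGs and 15
planted prognostic genes, four 150-patient survival cohorts, a 400-patient
training cohort and an independent validation cohort:

```r
cfg <- sim_config(n_genes = 300, n_planted_deg = 30, n_planted_prognostic = 15,
                  n_cohorts = 4, n_per_cohort = 150, n_tumor = 30, n_normal = 30)
pc  <- simulate_paired_counts(cfg, seed = 11)
sv  <- simulate_survival_cohorts(cfg, seed = 12)
tcfg <- cfg; tcfg$n_per_cohort <- 400; tcfg$n_cohorts <- 2
tc  <- simulate_survival_cohorts(tcfg, seed = 13)

run <- run_derivation(pc$tumor, pc$normal, sv$cohorts, tc$cohorts[[1]],
                      run_config(seed = 5))
str(run$report[c("n_genes_tested", "n_deg", "n_prognostic", "n_signature", "lambda")])
#> List of 5
#>  $ n_genes_tested: int 300
#>  $ n_deg         : int 30
#>  $ n_prognostic  : int 13
#>  $ n_signature   : int 13
#>  $ lambda        : num 0.1
```

The run report shows the filters narrowing 300 genes to 30 DEGs, 13
prognostic genes and a 13-gene learned signature (λ = 0.1 chosen on the
internal validation half). Validating that signature on the held-out
cohort:

```r
val <- run_validation(run$signature, tc$cohorts[[2]], run_config(seed = 5))
val$report
#> <strata_report> 400 patients, four-way split
#>   1   2   3   4
#>  15 195 169  21
#> log-rank chi2 = 93.587 (df 3), p = 3.72e-20
head(val$scores, 3)
#>   sample_id      mps stratum
#> 1   C2_s001 14.09756       2
#> 2   C2_s002 22.90219       2
#> 3   C2_s003 30.20335       3
```

The learned score splits the independent cohort into four risk groups
whose relapse-free survival separates at log-rank p ≈ 4e-20 — the planted
prognostic structure is recovered and carried through to patient-level
stratification.

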