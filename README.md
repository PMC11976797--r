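# stk11eval

Benchmarking variant-effect predictors against a functional assay of STK11
(LKB1) kinase activity, and turning the combined evidence into point-based
clinical variant classifications.

STK11 is a tumor-suppressor "master kinase": germline variants cause
Peutz–Jeghers syndrome and somatic variants are common in non-small cell
lung cancer. For 28 coding variants found in NSCLC biopsies, a cell-based
luciferase reporter assay measured each variant's effect on p53-dependent
transcription across many biological and technical replicates. This package
implements the full assessment pipeline around such data:

- **Assay model** — raw per-replicate luminescence is normalized to
  relative-wildtype activity within each (biological, technical) replicate,

  R-WT = (A_var − A_EV) / (A_WT − A_EV),

  so the empty-vector baseline maps to 0 and wildtype to 1; per-variant
  means (with 25th/75th percentiles) are thresholded at **R-WT < 0.6** into
  LoF vs WT-like labels.
- **Predictor evaluation** — Pearson correlation and Kendall tau-b on the
  activity scale, ROC AUC (LoF positive, midrank ties) on the risk scale,
  with declared-orientation transforms (pathogenicity scores ŷ → 1 − ŷ for
  regression; activity scores → −ŷ for AUC) and evaluation-set mean
  imputation of missing predictions. Uncertainty comes from 1000 paired
  bootstrap variant sets — stratified (class-count-preserving) for AUC,
  plain for the regression metrics — summarized as 5th/95th percentile
  intervals. Predictors are ranked by average rank over the three metrics
  (best-per-team first), and compared head-to-head with an exact one-sided
  binomial test on bootstrap win counts.
- **Experimental-Max** — a stochastic pseudo-predictor that, per variant,
  returns the R-WT value of a random technical replicate within a random
  biological replicate; averaged over 1000 resampled realizations it
  quantifies assay self-consistency and upper-bounds achievable predictor
  performance.
- **Difficulty profiling** — per-variant FPR (LoF variants) / FNR (WT-like
  variants) at the variant's own predicted value, across all predictors
  with AUC > 0.8.
- **ACMG/AMP point engine** — PS3/BS3 (one supporting point per assay),
  PM2/BS1 (gnomAD absence / AF > 0.001), PP3/BP4 (calibrated REVEL score
  intervals), PM5 (co-located P/LP variants with 2-decimal REVEL
  qualification); totals map to B … P with the VUS band split into
  low/mid/high.
- **Synthetic generator** — assays with the real design (17 biological
  replicates, 2–3 technical replicates, 3–6 biological replicates per
  variant, controls everywhere) and predictors with tunable noise,
  orientation and missingness, so every stage is testable offline.

The 28-variant assay summary and clinical-evidence tables ship as packaged
fixtures; the raw replicate measurements and real predictor score files are
*not* required (nor included) — supply them as TSVs to reproduce the full
published comparison.

## Worked example: clinical classification of the packaged variants

```r
library(stk11eval)

ann <- stk11_annotations()
build_evaluation_set(ann)
#> Evaluation set: 22 variants retained, 6 excluded
#>   - p.D194Y (ClinVar P/LP)
#>   - p.P179R (HGMD DM)
#>   - p.G163R (ClinVar LP)
#>   - p.A241P (HGMD DM)
#>   - p.R297S (ClinVar P)
#>   - p.F354L (ClinVar B/LB)

acmg <- acmg_classify_all(ann)
attr(acmg, "profiles")[[which(acmg$variant == "p.R297M")]]
#> p.R297M: 9 points -> LP
#>   PM2 (+1): absent from gnomAD
#>   PS3 (+1): luciferase assay: LoF
#>   PS3 (+1): gel-shift assay: LoF
#>   PP3 (+4): REVEL 0.936
#>   PM5 (+2): co-located P/LP: R297S
```

The six excluded variants carry definitive clinical assertions and might
have been used to train predictors, so they never enter the predictor
comparison. p.R297M's 9 points place it in the likely-pathogenic band
[6, 9]: one point for gnomAD absence, two for concordant LoF assay results,
four for a REVEL score in the strong interval [0.932, 1], and two because
its rounded REVEL score matches the co-located pathogenic p.R297S. Across
the 24 variants lacking a prior definitive ClinVar assertion, the engine
moves 16 into actionable categories (6 LP, 10 LB).

## Worked example: evaluating predictors on a synthetic challenge

```r
sim <- generate_assay(synthetic_config(noise_sd = 0.1), seed = 42)
gt  <- build_ground_truth(sim$measurements)
preds <- list(
  generate_predictor(sim$truth, "activity",      noise_sd = 0.20, seed = 1, name = "teamA-1", team = "A"),
  generate_predictor(sim$truth, "activity",      noise_sd = 0.45, seed = 2, name = "teamA-2", team = "A"),
  generate_predictor(sim$truth, "pathogenicity", noise_sd = 0.35, missing_rate = 0.1,
                     seed = 3, name = "teamB-1", team = "B"),
  generate_predictor(sim$truth, "pathogenicity", noise_sd = 0.15, seed = 4,
                     name = "meta-tool", baseline = TRUE))

evaluate_predictors(preds, gt, gt$variant, n_boot = 1000, seed = 42)
#> Predictor evaluation on 28 variants, 1000 bootstrap draws
#>   predictor pearson kendall_tau   auc
#> 1   teamA-1   0.947       0.725 0.947
#> 2   teamA-2   0.731       0.407 0.825
#> 3   teamB-1   0.896       0.705 0.971
#> 4 meta-tool   0.930       0.724 0.994

experimental_max(sim$measurements, gt, gt$variant, n_realizations = 1000, seed = 43)
#> Experimental-Max over 1000 replicate resamplings
#>   pearson = 0.977 [0.968, 0.986]
#>   kendall_tau = 0.825 [0.762, 0.884]
#>   auc = 0.993 [0.977, 1.000]
```

The replicate-resampling bound (Pearson 0.977) sits above every predictor,
as it must: no method can predict the assay better than the assay repeats
itself. `rank_predictors(..., two_stage = TRUE)` picks teamA-1 over teamA-2
within team A before re-ranking representatives, and
`compare_binomial()` on shared bootstrap draws gives the exact win-count
test (here teamA-1 beats teamB-1 on only 287/1000 AUC sets, p ≈ 1 — no
evidence of superiority).

`run_stk11_pipeline()` chains every stage and writes a TSV/JSON report
bundle; `inst/cli/stk11.R` exposes `simulate`, `classify` and `run-all`
subcommands via Rscript.

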