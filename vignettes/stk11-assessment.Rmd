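---
title: "Methods: assessing kinase-activity predictors and classifying STK11 variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assessing kinase-activity predictors and classifying STK11 variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stk11eval)
```

# The problem

STK11 (LKB1) is a serine/threonine "master kinase" and tumor suppressor;
its loss of function causes Peutz–Jeghers syndrome and shapes therapy
response in non-small cell lung cancer. For a set of 28 coding variants
(27 missense, one single-residue deletion) observed in NSCLC biopsies, a
p53-dependent luciferase reporter assay measured each variant's residual
transcriptional activity, alongside a binary gel-shift autophosphorylation
assay. This package evaluates how well computational variant-effect
predictors recover that functional readout, how close they come to the
assay's own reproducibility, and what the combined evidence implies
clinically.

# The assay model

## Normalization

Raw luminescence is normalized *within* each (biological, technical)
replicate using that replicate's own wildtype (WT) and empty-vector (EV)
controls:

$$\mathrm{R\text{-}WT} = \frac{A_{\mathrm{var}} - A_{\mathrm{EV}}}{A_{\mathrm{WT}} - A_{\mathrm{EV}}}.$$

This anchors EV at 0 and WT at 1 regardless of per-replicate scale or
offset (the statistic is invariant to shifting or positively scaling all
three readings), and values above 1 — super-wildtype activity — are
legitimate. A replicate in which WT and EV read identically carries no
information and is rejected with its identity, as is any replicate lacking
a matched control: these are load-time errors, never silent drops. The
kinase-dead p.K78I control (`KD`) is carried through as data but plays no
computational role; it exists as an assay sanity check.

## Aggregation and labels

A variant's ground-truth activity is the mean of its per-replicate R-WT
values over all biological and technical replicates; dispersion is reported
as the 25th/75th percentile of the same values. The percentile convention
is not dictated by the source material, so we default to linear
interpolation between order statistics (R type 7) and expose
`quantile_type`. Because it is also unstated whether the published
dispersion values were computed over all replicate values or over
biological-replicate means, the packaged p25/p75 columns are treated as
informational and are never asserted against recomputation.

The binary label applies a strict threshold: mean R-WT **< 0.6** is LoF,
anything else — including exactly 0.6 — is WT-like. On the packaged table
this yields 15 LoF and 13 WT-like variants, matching the published labels
exactly.

## Evaluation set

Variants with a definitive, non-conflicting clinical assertion (ClinVar
P/LP/B/LB, or HGMD DM unopposed by ClinVar) may have been used to train
predictors and are excluded from the comparison, leaving 22 variants.
A reduced 21-variant set additionally drops the deletion p.K84del, since
many tools only score missense changes. Both sets are derived, not stored.

# Evaluating predictors

## Orientation

Predictors declare their orientation in a manifest; it is never inferred.
Activity-oriented predictions are used unaltered for Pearson correlation
and Kendall tau and negated for AUC (where higher must mean more likely
LoF). Pathogenicity-oriented scores $\hat y \in [0,1]$ are transformed to
$1-\hat y$ for the regression metrics and used unaltered for AUC. Scores
outside $[0,1]$ on the pathogenicity scale are accepted with a warning —
the transform is applied as-is — and submitted scores are never clipped.

## Metrics and ties

Kendall's tau is computed as tau-b: ties are guaranteed by mean imputation
(below), and tau-b is the standard tie-corrected form. AUC uses the
Mann–Whitney formulation with midrank (half-credit) ties. Both choices are
verified in the test suite against brute-force pairwise-enumeration
oracles on all small instances.

## Missing predictions

A missing prediction is replaced by the mean of the predictor's
non-missing scores *on the evaluation set*, on the predictor's native scale
before any orientation transform. Restricting the mean to the evaluation
set (rather than all 28 variants) keeps excluded variants from leaking into
evaluated quantities; imputed variants are flagged in every downstream
output. Note the known artifact this creates: a variant with intermediate
true activity is "predicted" harmlessly by the mean, so imputation can
flatter tools that abstain.

## Uncertainty and pairing

Each metric is recomputed on 1000 bootstrap variant sets. Classification
metrics use stratified resampling — sampling with replacement within the
LoF and WT-like groups separately, so every bootstrap set preserves the
class counts; regression metrics use plain resampling. Intervals are the
5th/95th percentiles of the draws (a Gaussian ±1.96·sd version is kept for
AUC reporting). Crucially, *all predictors share the same index sets* per
metric family: the head-to-head comparison counts, per bootstrap set, which
predictor scored strictly higher, and refers the win count to an exact
Binomial(n, ½) upper tail. Without shared indices that test would be
meaningless. Ties are not wins — reproduced win counts can therefore differ
from published ones by the tie mass, which is one reason those counts are
treated as soft targets only. A bootstrap set on which a metric is
undefined (zero variance, single class) is redrawn up to 100 times and then
fails loudly; NaNs never propagate.

## Ranking

Predictors are ranked 1..n per metric (average ranks on ties) and ordered
by the mean of the three ranks. Participant ranking is two-stage — best
predictor per team first, then representatives against each other — and
baselines always form a separate pool.

# Experimental-Max

The assay's replicates bound what any predictor could achieve. The
Experimental-Max pseudo-predictor draws, per variant, a uniformly random
biological replicate containing it and then a uniformly random technical
R-WT value within that replicate (two-level uniform: a biological replicate
with more technical repeats is *not* more likely). Each of 1000
realizations is scored against the all-replicate mean ground truth — no
leave-one-out correction is applied, since the published procedure
describes none — and the report gives the mean and 5th/95th percentile over
realizations, with no further bootstrap layered on top. Degenerate
realizations are redrawn. As replicate noise goes to zero every realization
reproduces the truth exactly and all three metrics hit 1.0; the test suite
checks both this limit and monotone degradation with rising noise.

# Difficult-to-predict variants

For a LoF variant, difficulty under a predictor is the false positive rate
when the variant's own predicted activity is used as the decision
threshold: the fraction of WT-like variants predicted *strictly* below it.
Symmetrically, a WT-like variant's difficulty is the fraction of LoF
variants predicted strictly above it. Ties count toward neither rate, and
the rates depend only on score ranks, so any strictly increasing transform
of a predictor's output leaves its difficulty column unchanged. The profile
uses all 28 variants — including the six excluded from predictor
comparison — over the competitive subset: best-per-team participants plus
baselines, all filtered at AUC > 0.8. Imputed scores participate and are
flagged.

# Clinical classification

Evidence is combined on the point scale: supporting/moderate/strong/very
strong toward pathogenicity (benignity) is +1/+2/+4/+8 (−1/−2/−4/−8), with
category bands ≥10 (P), [6, 9] (LP), [0, 5] (VUS, subdivided [0,1] low /
[2,3] mid / [4,5] high), [−6, −1] (LB), ≤−7 (B).

* **PS3/BS3** — each assay contributes one supporting point in its label's
  direction, so concordant assays net ±2 and the single discordant variant
  (p.H202R) nets 0.
* **PM2/BS1** — absence from gnomAD gives PM2 at supporting strength (+1,
  per current practice rather than the original moderate level); allele
  frequency above 0.001 gives BS1 (−4), a threshold appropriate to an
  autosomal-dominant disorder; presence below threshold is indeterminate
  and contributes no code.
* **PP3/BP4** — REVEL scores are mapped through calibrated intervals:
  [0.644, 0.773) → +1, [0.773, 0.932) → +2, [0.932, 1] → +4;
  (0.183, 0.290] → −1, (0.016, 0.183] → −2, (0.003, 0.016] → −4. The gap
  (0.290, 0.644), scores ≤ 0.003, and absent scores (the deletion) carry no
  code. Endpoints are implemented exactly as stated — left-closed on the
  pathogenic side, right-closed on the benign side.
* **PM5** — co-located P/LP missense variants at the same residue count
  when the tested variant's REVEL score, rounded to two decimals, is ≥ the
  (equally rounded) score of *at least one* of them; once triggered, points
  accumulate over **all** co-located P/LP variants (+2 first P, +1 first
  LP, +1 each additional). This any-triggers-all reading is an
  interpretation: it is the unique semantics consistent with both a variant
  that scores PM5 = 4 while rounding below two of its three co-located
  scores, and a variant that scores PM5 = 0 while rounding below its only
  one. Both scores are rounded symmetrically (also an interpretation; the
  alternative is not distinguishable on the available data). Co-located
  B/LB entries are accepted and ignored.

Case-level codes (PM6/PS2, PP1) are structurally supported as manual
pass-through items but never applied automatically — no case data exists
for these biopsy-derived variants. The golden test reproduces all 28
published rows — every per-code point value, total and category — and the
headline: of the 24 variants without a prior definitive ClinVar assertion,
6 classify LP and 10 LB.

# The synthetic generator

`generate_assay()` emulates the stated design: 17 biological replicates,
2–3 technical replicates each, every (bio, tech) pair carrying WT/EV/KD,
each variant covered by 3–6 biological replicates. True activities default
to an equal mixture of Normal(0.2, 0.15) and Normal(1.1, 0.25) truncated to
[−0.2, 2.0] — a bimodal LoF/WT-like spread with means, weights and range
chosen once to mirror the observed activity distribution of the real
28-variant panel. Replicate noise (default sd 0.1, roughly the
interquartile spread seen in the real data) is applied on the R-WT scale
*before* mapping to raw units through per-replicate EV/WT baselines drawn
from [0.5, 1.5] and [2.5, 4.5] (arbitrary luminescence units), so the
noise knob is directly interpretable against the 0.6 threshold. A single
noise knob deliberately conflates biological and technical variability —
the real data do not identify the two components separately.

What a green synthetic test establishes: the pipeline's algebra,
invariants, determinism and limiting behavior. What it does not: anything
about real assay artifacts (plate effects, transfection efficiency,
photon statistics) — these are consumed as already corrected, and the
generator does not model them.

`generate_predictor()` adds Gaussian noise on the activity scale (and for
pathogenicity orientation returns 1 − clip(truth + noise, 0, 1));
`noise_for_tau()` inverts tau = (2/π)·asin(ρ) under a bivariate-normal
approximation to target a desired rank correlation. Truncation makes the
target approximate, which suffices for the calibration test (the target
falls inside its own bootstrap 90% interval in ≥ 85% of seeded runs).

# Numerical and reproducibility choices

* One top-level seed fans out to named substreams
  (bootstrap-regression, bootstrap-classification, experimental-max) via a
  deterministic hash kept below 2^31; every estimate is bit-reproducible
  given the seed, and the run manifest records seed and configuration.
* Binomial tail probabilities use the exact distribution function with
  log-space output available, so p-values near 10^−110 are representable.
* Packaged fixture tables are checksummed at load; a mismatch is an
  integrity error, not a warning.
* The boundary R-WT = 0.6 is WT-like ("less than" read strictly); AUC ties
  get half credit; difficulty rates use strict inequalities; PM5 rounds to
  2 decimals before comparing.

# Known limitations

* The published bootstrap interval endpoints and win counts are
  reproducible only approximately: the original RNG, resampling order and
  tie conventions are unstated. The structural claims (pairing, stratified
  counts, exact tail test) are what the suite asserts.
* Real predictor score files and raw replicate measurements are not
  shipped; the published per-predictor numbers are asserted only when a
  user supplies those files. All other results recompute from packaged
  inputs.
* The data providers' own normalization used a wider scale; only the 0–1
  scale defined by the formula above is implemented.
* Mean imputation is the published convention, not a recommendation; its
  flattering effect on abstaining tools is inherited by design.
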