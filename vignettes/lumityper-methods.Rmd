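---
title: "Methods and design of the lumityper pipeline"
author: "lumityper authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the lumityper pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`lumityper` analyses a 72-gene targeted RNA-seq panel measured on
HR+/HER2- early-stage breast tumours: 50 subtype genes used for
intrinsic subtyping and recurrence risk, 17 immune genes summarised into
an immune score, and 5 housekeeping genes used as the reference for all
absolute-scale scores. Alongside the molecular arm it implements the
IHC surrogate rules that pathology services use when expression profiling
is unavailable, and the downstream agreement and survival statistics that
connect the two. The pipeline starts at the count matrix; read mapping is
out of scope.

# Quality control and normalisation

A sample is retained when its fraction of zero-count genes is strictly
below 30% and its total panel reads strictly exceed 10,000. Both bounds
are taken literally ("less than", "larger than") and are arguments of
`qcFilterSamples()`, so a user can relax them; "missing" is defined as a
zero count, because targeted panels report zeros rather than NAs.

Normalisation is counts per million over the panel-wide library size of
each sample, then `log2(CPM + 1)`. The pseudocount of 1 is a convention:
the upstream assay chain specifies a log2 transform without one, and the
pseudocount is what keeps zero counts finite. Transcript-length
correction (counts divided by length in kb before CPM) is available but
off by default, since the panel definition ships no lengths. Each gene is
then median-centred across samples; optional standardisation divides by
the per-gene SD, with zero-variance genes flagged in
`rowData(x)$zero_variance` and left undivided. Scores that need an
absolute scale (RS, immune score) use the *uncentred* log2 CPM referenced
to the housekeeping mean; the centroid classifier and ROR-P use the
centred matrix.

# Intrinsic subtyping and ROR-P

Centroids are within-class means of centred expression over the 50
subtype genes, trained from labelled samples (`trainCentroids()`).
Assignment is the subtype maximising the correlation between sample and
centroid. Spearman is the default metric because rank correlation is
robust to the monotone distortions of targeted sequencing; Pearson is
available. Exact ties are broken by the fixed order
LumA > LumB > HER2E > Basal and flagged, for determinism.

ROR-P is `raw = Σ_k w_k · r_k + w_P · P` with `r_k` the four centroid
correlations and `P` the mean centred expression of an 11-gene
proliferation subset. The shipped subtype weights (−0.34 LumA, +0.23
LumB, +0.12 HER2E, +0.05 Basal) follow the published correlation-weighted
risk score; the proliferation weight (0.54) and the proliferation subset
are package conventions, since the assay publishes neither. Because no
absolute scale is published either, the raw score is min–max rescaled to
0–100 *on the training cohort* and the affine map is stored in the model,
so held-out samples are scored on the same scale. Risk classes default to
low < 40 ≤ medium < 60 ≤ high on that scale. A self-trained alternative
(`trainRORWeights()`) refits the weights by Cox regression of the
correlations and `P` on survival, mirroring how such scores were
originally calibrated.

One ambiguity in the upstream description deserves a note: the phrase
about evaluating expression "using the K-nearest neighbor method" does
not say whether KNN served imputation or classification. This package
implements nearest-centroid assignment as the subtype caller — the
standard for this class of predictor — and does not implement KNN
imputation; missing genes at classification time are mean-imputed with a
warning.

# The 21-gene recurrence score

`oncotypeRS()` reference-normalises each informative gene (log2 value
minus the mean housekeeping log2 value, plus a reference offset), forms
the published group scores — HER2 group `0.9·GRB7 + 0.1·ERBB2` floored at
8, ER group `(0.8·ESR1 + 1.2·PGR + BCL2 + SCUBE2)/4`, proliferation group
mean floored at 6.5, invasion group mean, and the singleton genes CD68,
GSTM1, BAG1 — and combines them with the published coefficients (+0.47,
−0.34, +1.04, +0.10, +0.05, −0.08, −0.07). The scaled score is
`RS = clip(20 · (RSu − 6.7), 0, 100)`, classed low < 18,
medium 18–30, high ≥ 31.

Two deliberate choices:

* **Reference offset.** The original score operates on a qRT-PCR scale
  where reference-normalised expression sits around 0–15 units and the
  floors (8, 6.5) are meaningful. Housekeeping-referenced log2 CPM sits
  near zero, so the package adds a reference offset (default 7) that
  places typical values in the range where the floors and the affine map
  behave as designed. Absolute RS values are therefore internally
  consistent, *not* vendor-exact — reproducing the commercial assay is a
  non-goal.
* **Panel restriction.** Five of the 16 informative genes (SCUBE2, AURKA,
  CTSV, GSTM1, CD68) are not on the default 50-gene subtype panel.
  `panelRSModel()` keeps the group structure, coefficients and floors but
  restricts each group to its measurable members; `rsModel()` carries the
  full 16-gene configuration for panels that measure them. All tests are
  written to be gene-list-agnostic.

# The 17-gene immune score

The score is the mean housekeeping-referenced log2 expression of the
immune genes, min–max rescaled to 0–100 over the cohort; whether the
original score was a rescaled mean or a weighted signature is not
published, so the rescaled mean is a declared convention. Grouping is
`istrong` when score ≥ cutoff — the inequality is inclusive by
specification. The published cutoff 45.5 ships as the default preset;
passing an outcome vector instead derives the cutoff from the cohort by
the Youden index. The identities of the 17 genes live in an unavailable
supplement, so the default list is a documented placeholder of canonical
T-cell, cytotoxicity and chemokine markers; every computation accepts a
custom panel.

# IHC surrogate rules

Marker positivity is strictly greater than 1% staining. The St. Gallen
split assigns luminal B iff PR < 20% or Ki-67 > 30% (so Ki-67 = 30 is
"low"), luminal A otherwise; ER-negative records are outside the cohort
definition and raise an error. The modified rule runs **before** the
luminal split: basal-like iff any of CK5/6, EGFR, CK14 is positive, AND
Ki-67 ≥ 40%, AND ER ≤ 10% (both boundaries inclusive). Rule precedence
reflects the rule's purpose — pulling molecular basal-like tumours out of
the luminal classes; no IHC rule is defined for HER2-enriched, which is
reachable only through expression.

TILs are dichotomised as high iff strictly greater than the cutoff
(default 13.5%). The strict convention is documented rather than
consequential at the default: 13.5 is not an attainable integer reading.
On the shipped 12-case fixture, the printed IHC label of case 7 (LumB)
disagrees with the stated St. Gallen rule (Ki-67 = 30, PR = 90 gives
LumA); the package follows the rule and keeps the printed label in a
separate column. Three fixture rows (cases 4, 8, 9) had ambiguously
concatenated digits in the published layout; the transcription fixed by
the column order is used and flagged `ambiguous_parse`, and none of the
candidate parses changes any rule-based result (all of rows 7–12 stay
below the Ki-67 threshold).

# Downstream statistics

* **Youden cutpoints** scan midpoints of sorted unique values; ties break
  to the smallest threshold, and the rule direction is chosen
  automatically unless fixed. Which survival endpoint feeds a cutoff is
  a user choice; the pipeline's convention is the distant-metastasis
  event, where immune effects are strongest, and it is switchable.
* **Cohen's κ** is unweighted — no weighting scheme is published for the
  three-level risk classes — with the cross-tab and observed agreement
  returned alongside; a constant pair of raters yields a flagged NA.
* **Kaplan–Meier / log-rank** delegate to the survival package, with ties
  handled by the standard aggregated-risk-set variance (the dominant
  convention; nothing upstream specifies one).
* **Cox regression** fits each factor of the published menu univariately
  and the multivariate joint model; monotone-likelihood situations (a
  stratum without events) are flagged per factor via their exploding
  standard errors rather than raised. Reference categories are the first
  factor level, encoded explicitly in the pipeline's covariate
  construction.
* **FDR** is Benjamini–Hochberg within each declared family ("false
  discovery rate" names no specific procedure; BH is the default
  everywhere in this field).

# The synthetic cohort generator

No per-patient expression data are released for the source cohort, so the
generator is the package's ground-truth instrument. It emulates exactly
the structure the analysis assumes:

* **Subtypes** are multinomial with default mix 71/20/2/7%
  (LumA/LumB/HER2E/Basal) at the default cohort size of 87.
* **Expression**: each subtype gene carries a signature weight in
  [−1, 1] (luminal, proliferation, HER2, basal blocks) plus a fixed
  deterministic per-gene modulation, so profiles differ gene-by-gene as
  real centroids do; the per-gene log2 shift is the weight times
  `expressionSeparation` (default 2 log2 units). Counts are negative
  binomial (overdispersion 0.3) around the exponentiated profile scaled
  to a uniform library size in 50,000–200,000 reads. These values are
  conventions chosen to look like overdispersed targeted RNA-seq; the
  source assay publishes no distributional parameters.
* **IHC channels** are logistic transforms of the matching gene's latent
  deviation (ESR1→ER%, PGR→PR%, MKI67→Ki-67%) plus noise — correlated
  with, but not identical to, expression, which is what makes the
  IHC-vs-molecular concordance analysis non-trivial. Basal latents get
  low-but-positive ER (2–10%), low PR, mostly high Ki-67, and at least
  one positive basal marker with high probability.
* **Immune level** is a latent standard normal shared between the immune
  genes and TILs at correlation `immuneCoupling` (default 0.8).
* **Survival** is exponential with log-hazard
  `Σ covariate · hazardLogHR` (defaults: LumB 0.6, HER2E 0.8, Basal 1.2,
  immune 0.35, size > 1 cm 0.5, baseline 0.004/month for DFS and
  0.0018/month for distant metastasis) and independent exponential
  censoring calibrated so the expected censored fraction equals
  `censoringRate`.

What the generator does **not** emulate: copy-number/mutation structure,
batch effects, non-proportional hazards, informative censoring,
inter-observer Ki-67 variation, or correlated DFS/DMFS event processes
(the two endpoints are drawn independently). Passing tests therefore
demonstrate algorithmic correctness and statistical calibration under the
assumed model — not robustness to the artefacts of real clinical data.

# Numerical choices and problem sizes

Determinism: a cohort is a pure function of its `CohortSpec`, including
the seed; the pipeline flows all randomness from one config seed.
Degenerate inputs are errors with named offenders (constant profiles,
degenerate immune cohorts, zero library sizes, all-censored log-rank) or
flags (zero-variance genes, monotone-likelihood Cox strata, undefined κ).
Singleton training subtypes are an error by default; the pipeline opts
into pooling them into a cohort-mean centroid, which matches how rare
HER2-enriched cases (2% prevalence) must be handled at n = 87.

Test problem sizes were chosen to give stable checks in seconds:
frequency convergence at n = 10,000; subtype recovery with train n = 400
/ test n = 200 at separation 3; null log-rank calibration over 100 seeds
of n = 60 and uniformity over 500 replicates; Cox coverage over 100 seeds
of n = 150 and bias averaged over 20 replicates of n = 2,000; exhaustive
κ enumeration over all 2×2 tables up to n = 20.

# Known limitations

Scores are internally consistent, not vendor-calibrated: absolute ROR-P
and RS values depend on the package's scale conventions (training-cohort
rescaling; reference offset), so only their ordering, classes and
associations — not raw values — should be compared across studies. The
default immune gene list is a placeholder. Cohort-level published
statistics that depend on the unreleased 87-patient expression matrix
(κ between risk classes, exact concordance percentages, the Cox hazard
ratios) are validated structurally, on synthetic cohorts, not
numerically.
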