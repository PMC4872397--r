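---
title: "Brain-aging indices, advanced-aging groups and atrophy-pattern overlap: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-aging indices, advanced-aging groups and atrophy-pattern overlap: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`spareatlas` implements a population-neuroimaging analysis chain: build a
machine-learning index of aging-type brain atrophy from voxel-wise
gray-matter volumetric maps, single out individuals aging faster or slower
than their peers, and ask whether the "fast ager" atrophy pattern is the
Alzheimer pattern or something distinct. This vignette is the package's own
account of the models, the assumptions they rest on, the tunable parameters,
and the numerical choices made where the design was genuinely open.

## The data model

The unit of imaging data is a RAVENS-style regional volumetric map: a 3D
scalar field on a common grid in which each voxel's value is proportional to
the amount of gray matter that maps to that template location. The package
treats these maps as given inputs (a `map_set`, internally a
subjects-by-voxels matrix); tissue segmentation and deformable registration
that would produce them from raw T1 images are explicitly out of scope.
Alongside the maps sits a per-subject cohort table: age, sex, smoking
(never/former/current), education (<8, 8–10, >10 years), physical activity
(four levels), systolic blood pressure (mm Hg), HbA1c (%), waist
circumference (cm), three drug-use indicators, 19 SNP allele counts, an
optional cognitive score, and the derived index columns.

## SPARE indices as SVM decision values

A SPARE index is the signed decision value of a linear support-vector
machine trained to separate two reference groups on flattened voxel
features:

$$d(x) = \langle w, x_{\mathrm{std}} \rangle + b$$

- **SPARE-BA** trains young (age ≤ 45) vs old (age ≥ 60), both bounds
  inclusive, with the young group on the positive side: higher SPARE-BA
  means less aging-type atrophy. Subjects between the thresholds are never
  trained on, only scored.
- **SPARE-AD** trains AD patients vs cognitively normal controls from a
  reference case-control set, with the AD group positive: higher SPARE-AD
  means a more AD-like atrophy pattern.

Design choices the source design leaves open, and what this package does:

- **Kernel and regularization.** Linear kernel, `C = 1` by default
  (exposed). A linear machine keeps the weight vector interpretable as a
  voxel pattern map, which the downstream pattern-mask comparisons need.
- **Feature scaling.** Per-voxel z-standardization using training-set
  statistics, stored in the model so any later scoring reproduces training
  decision values exactly. Voxels constant across the training set are
  dropped (logged); an all-constant input is an error.
- **Sign convention.** e1071's internal decision sign depends on factor
  level order, so the trained weights are flipped if needed until the
  designated positive group has the higher mean training score. Swapping
  the positive label therefore negates every score exactly — a tested
  invariant.
- **No probability calibration.** Raw signed decision values are the index;
  their absolute scale is arbitrary (SVM margin units), so only
  correlations, contrasts and within-cohort comparisons are meaningful.

**Jackknife scoring.** A training subject scored by the model that saw it
would be optimistically biased, so training members receive cross-validated
scores: the training set is partitioned into label-stratified folds, the
machine is refit with each fold held out, and each subject is scored by the
model from which it was excluded. The default is true leave-one-out up to
200 training subjects and 10 folds above that (leave-one-out is the
classical reading of "jackknifing", but at hundreds of subjects the 10-fold
version is an order of magnitude cheaper and, in the package's separable
test fixtures, fold-seed-invariant). The fold partition is seeded;
`jackknife_scores()` returns the fold assignment so uncontamination is
verifiable.

## Advanced and resilient agers

Among subjects at or above the age floor (65 years by default — the age
from which clinical AD prevalence rises substantially), SPARE-BA is
regressed on age by simple OLS, residuals are z-scored with the sample
standard deviation (n − 1), and

- `z < −0.5` → **ABA** (advanced brain aging),
- `z > +0.5` → **RA** (resilient aging),
- anything else, including exact ties at ±0.5, stays unassigned (strict
  inequalities as printed in the source design).

The regression and the z-transform are computed **within the age-eligible
subset** by default. Whether the age regression should use the full age
range is ambiguous in the source design; fitting within the subset makes
the z-scores exactly mean-0/sd-1 in the population they label
(`fit_all_ages = TRUE` is available). High/low SPARE-AD groups for the
AD-pattern contrast are defined the same way on the SPARE-AD column with
the same 0.5 threshold.

## Voxel-wise statistics

Group contrasts are mass-univariate: a two-sided pooled-variance Student
t-test per voxel (`df = n1 + n2 − 2`), Welch's variant behind a flag. The
pooled-variance form is the default because the design names Student's
t-test. Voxels with zero pooled variance are uninformative background and
get `t = 0, p = 1` with a logged count — never an exception, since empty
voxels are normal at map edges. The analysis mask defaults to voxels with
nonzero variance across the pooled sample; Benjamini–Hochberg FDR
adjustment runs over analysis-mask voxels only, and the significance mask
is `q ≤ q_threshold` (0.001 for the pattern maps). Only voxel-level
inference is offered; cluster-extent thresholds are not reproduced because
none are specified in the source design.

A continuous-covariate variant (`continuous_association_map()`) fits
per-voxel OLS of density on a covariate plus optional adjusters and tests
the covariate coefficient — used to check that dichotomized (ABA vs RA) and
continuous (age-adjusted index) maps agree.

The **overlap partition** splits the aging-contrast mask A and AD-contrast
mask B into `A\B` ("blue", aging-specific), `B\A` ("red", AD-specific) and
`A∩B` ("green", shared). Per-region, per-subject mean densities feed a
pooled t shift test between ABA and RA; the expected signature when no AD
deficit exists in the cohort is a shift in blue and green but not red.

## The polygenic risk score

`score = Σ_j count_j · ln(OR_j)` over a 19-SNP panel. The natural logarithm
is the default (the convention for odds-ratio weights; the base is
exposed). Subjects with any missing genotype get a missing score by default,
mirroring analyses restricted to fully genotyped participants; mean
imputation with `2·frequency` is optional. The shipped panel is synthetic —
frequencies and odds-ratio magnitudes typical of genome-wide-significant AD
loci, one APOE-like OR of 2.5 — and claims no fidelity to any published
locus list.

## Risk-factor association models

`fit_index_model()` fits OLS with intercept, dummy-coding categorical
covariates against fixed references (never-smoker, <8 years education, no
sport activity), with models fitted independently per sex stratum. Age is
centered before squaring for the quadratic term — a purely numerical
choice that leaves all other estimates unchanged. Rows with missing model
covariates are dropped listwise with a logged count. Raw p-values are
reported with no multiple-testing correction across covariates, matching
the source design's Table-style reporting at α = 0.05. Rank deficiency is
an error naming the aliased terms, not a silent drop.

## The synthetic cohort generator

Real cohort data are not available, so the generator is a first-class,
tested module that plants exactly the structure the analysis assumes. Each
subject's noise-free map is

$$m(v) = b \; - \; s\,(a - a_{lo})\,\mathbf{1}_{aging}(v) \; - \;
\textstyle\sum_k e_k x_k \,\mathbf{1}_{aging}(v) \; - \;
d\,\mathbf{1}_{AD}(v)\,\mathbf{1}_{ad}$$

with i.i.d. Gaussian voxel noise on top. Defaults and why:

- **Grid 24³, n = 400.** Small enough that the full pipeline (two SVM
  trainings, a 10-fold jackknife, two voxel-wise contrasts) runs in about a
  minute; no algorithm in the chain depends on the grid being brain-sized.
- **Ages uniform on [20, 90].** The real population's age histogram is not
  specified; uniformity makes training-group sizes and regression recovery
  targets analytic.
- **Baseline 100, aging slope 0.5 units/year** inside a spherical aging
  mask; an AD sphere partially overlaps it (shared voxels plus voxels
  unique to each — the geometry the overlap partition is about).
- **Risk effects** (former/current smoking 1.75/3.5 units, anti-hypertensive
  use 2.5, waist 0.09 per cm above 90): equivalent to roughly 3–7 years of
  excess brain aging. These are deliberately at the strong end of
  plausibility: within-group voxel variance in the 65+ subgroup is
  dominated by the age trend itself (≈ 3.6 density units of sd across a
  25-year window), and weaker planted effects would make the ABA-vs-RA
  contrast undetectable at 40-odd subjects per group — a cohort one
  seventh the size of the real one. Exposures are drawn independently with
  fixed prevalences so that every planted coefficient is an analytic
  recovery target.
- **Noise i.i.d. Gaussian, sd 1.** No spatial autocorrelation by default,
  keeping voxel-test calibration analytic; a separable Gaussian smoothing
  of the noise field (`noise_smooth_sd`) is available to emulate spatially
  correlated registration noise, since the smoothness of real volumetric
  maps is unspecified.
- **AD status.** The generator plants the AD deficit only in reference-set
  cases by default (`ad_fraction = 0`). The pipeline's default
  configuration raises this to 15% of subjects aged 65+ — an emulation of
  preclinical AD prevalence — with per-subject probability following a
  logistic tilt in the standardized polygenic score (log-odds 1 per sd), so
  genetic risk and the AD atrophy pattern are coupled the way the
  genetic-association analysis expects.
- **Genotypes** are binomial(2, frequency) per SNP, independent across SNPs
  (no linkage disequilibrium).

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: registration error and anatomy-dependent map
smoothness, non-uniform age structure, correlated risk-factor exposures,
longitudinal change, and LD between loci. Tests against this generator
establish that the implementation recovers what it promises under its
stated assumptions, not that the scientific findings generalize.

## Numerical choices and degenerate inputs

- Exact threshold ties in group assignment are unassigned (strict
  inequalities); the 65-year age floor is inclusive.
- Zero age variance or residuals numerically collinear with age
  (sd below 1e-10 of the score scale) are errors in residualization.
- Constant voxels: dropped (training), `p = 1` (testing) — both logged.
- Maps are written as single-precision NIfTI (the field's convention for
  derived maps); round-trips are exact at float32 resolution. Masks are
  uint8 NIfTI; the affine defaults to identity since the analysis never
  uses world coordinates.
- The master pipeline seed fans out as `seed·8 + offset` (1 cohort,
  2 reference set, 3 jackknife folds) so stages can be rerun in isolation;
  the seed must stay below 2^27 to keep children in integer range.
- Problem sizes used by the test suite: oracle checks at ≤ 10⁴ voxels and
  ≤ 150 subjects; recovery checks on the default 400-subject cohort;
  calibration checks with 200–1000 replicates at small n. These sizes make
  the whole suite run in a few minutes while keeping every Monte-Carlo
  bound at 4 standard errors or tighter.

## Known limitations

- The SVM weight map is interpreted via its top-|w| voxel mask; no
  permutation-based inference on weights is offered.
- Only voxel-level FDR inference; no cluster-extent or FWE control.
- The index scale is arbitrary, so planted covariate effects are verified
  on a density-scale aging index (regional mean over the planted mask),
  where truth is known in the generator's units.
- `fit_all_ages`, Welch tests and mean-imputed genotypes are provided but
  off by default; defaults follow the source design's printed choices.
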