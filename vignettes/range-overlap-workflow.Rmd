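---
title: "Range-overlap change under climate scenarios: methods and design"
author: "hybridrange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Range-overlap change under climate scenarios: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the modelling strategy

Alien ornamental plants that have naturalized somewhere in the world but
not yet in a focal region form a pool of potential future invaders.  One
route by which they can affect the resident flora is hybridization with
congeners, which requires spatial contact: both partners must find the
same places climatically suitable.  This package estimates how the
overlap of climatically suitable ranges between such garden plants and
their resident congeners changes under climate warming, using an ensemble
of correlative species distribution models (SDMs).

Because the real inputs of such an analysis (occurrence archives,
gridded climate, expert species selection) cannot be redistributed, the
package is built around a **virtual-species design**: a synthetic climate
world and species with *known* Gaussian niches.  Every claim the workflow
makes — that pseudo-absences respect the exclusion radius, that the
consensus map recovers the species' true range, that the mixed model
recovers a known mean log ratio — is checked against that known truth in
the test suite.  The same functions accept real data through the
plain-text grid and CSV readers.

## Data model and numerical conventions

* **Grid.** A `climate_stack` holds named layers on a lon/lat grid
  (row 1 = northernmost), a logical land mask, an extent and a scalar
  resolution (default 1/6° = 10′, matching common global climatologies).
  Water cells are `NA` in every layer.
* **Cell footprints are half-open**: `[west, east)` × `(south, north]`.
  A point on a shared boundary therefore belongs to exactly one cell;
  points exactly on the outer extent edge are clamped into the edge
  cells.  This prevents double assignment during occurrence thinning.
* **Distances** are haversine on a sphere of radius 6371 km.  At the
  200 km scale of the exclusion radius the spherical approximation is
  more than adequate.
* **Grid files** are a self-describing plain-text format (header block +
  row-major value blocks, explicit no-data value) playing the role of a
  multi-band raster file; no GDAL-backed raster library is required.
  Writing uses 17 significant digits so round trips are exact.

## The synthetic world

`make_climate()` builds six bioclimatic layers: maximum temperature of
the warmest month (BIO5) and minimum temperature of the coldest month
(BIO6) decline linearly from 36 °C and 15 °C at the southern edge by
26 °C across the latitudinal span; temperature seasonality (BIO4) rises
with latitude; three precipitation layers (BIO16, BIO17, BIO18) decline
eastward (950→350, 280→80, 550→170 mm).  Each layer receives smooth
Gaussian-field noise (temperature sd 0.8 °C, precipitation sd 30 mm,
correlation length ≈ 4 cells) so that climate is not a perfect function
of position.  A contiguous land mask (largest connected component of a
thresholded smooth field, target ≈ 88% cover, accepted within 70–95%)
supplies the water cells that occurrence cleaning must drop.

**Scenarios are additive layer shifts** of graded severity (mild /
medium / severe: +1 / +2 / +4 °C on both temperature layers, slightly
rising seasonality, modest drying).  Real scenario fields have spatial
structure, but the only property the downstream analysis consumes is
graded warming severity, which the additive shift preserves exactly —
and it makes scenario algebra (identity, additivity, composition)
testable.

**Virtual species** have Gaussian product niches
\(s(x) = s_{\max}\exp\{-\sum_j (x_j-\mu_j)^2/2\sigma_j^2\}\) over BIO5
and BIO16.  Occurrences are a multinomial draw over land cells with
probability proportional to suitability, jittered uniformly within the
cell; duplicates are allowed before cleaning, as in aggregated occurrence
databases.  The generator samples the truth niche directly — it does not
attempt to separate realized from fundamental niches, and it includes no
spatial recording bias, no dispersal limitation and no temporal dynamics.
A green recovery test therefore establishes that the pipeline recovers
niches *under ideal sampling*, not that it is robust to biased archives.

### The study design and its rationale

The default design mirrors, scaled down, a study of 34 garden plants and
173 congeners in 16 genera: 4 genera × (2 garden + 4 congener species)
= 24 species, 300 records each, on a 100 × 100 grid.  Temperature optima
are genus-structured (niche conservatism): each genus draws a base
optimum in 24–30 °C, ordinary congeners scatter −6…+3 °C around it, and

* **garden species are warm-shifted** by +6…+9 °C relative to the genus
  base, placing their optima (30–39 °C) at or beyond the warmest climate
  available at baseline (≈ 36 °C).  This is the mechanism by which
  ornamentals native to warm regions hold *warm-edge-truncated* ranges:
  part of their suitable climate simply does not exist in the study area,
  and warming moves it on-map, so their suitable area can only grow or
  saturate with severity — never shrink.  (A first draft drew garden
  optima uniformly inside the available climate; that contradicts the
  warm-region-native mechanism — a mid-landscape optimum means warming
  slides the range poleward at constant size, and can even shrink it once
  the southern flank overheats — and was replaced before the tests were
  frozen.)
* **one congener per genus is cold-adapted** (−10…−14 °C below the genus
  base), emulating the montane/alpine members of the resident flora whose
  ranges are pushed off the cold edge by warming.

Precipitation optima share a genus base (450–750 mm ± 100) with broad
breadths (250–400 mm), so temperature dominates range geometry while the
models still face a correlated second niche axis.  Breadths on
temperature are 2.5–4 °C; `s_max = 1`.

With this geometry the three headline directions — garden ranges expand
with severity, congener ranges do not increase under severe warming, and
the log overlap-ratio intercept is not positive — emerge from the stated
mechanism rather than from tuned constants.

## Pseudo-absences and weighting

* `sample_random_pa()`: 10,000 points uniform over land (cell uniform,
  jitter within cell), drawn **once** per species for the regression
  family — replication is specified only for the machine-learning
  calibration.
* `sample_exclusion_pa()`: per replicate (10 by default), exactly as many
  points as the species has cleaned occurrences, uniform over the cells
  whose **centers** lie farther than `exclusion_km` *plus half the local
  cell diagonal* from every occurrence.  The inflation by the half
  diagonal makes the guarantee strict: a point jittered anywhere inside
  an eligible cell is still beyond the nominal radius.  Cells are drawn
  without replacement when enough are eligible, with replacement
  otherwise (recorded on the result).  Eligibility is judged against the
  cleaned (one-per-cell) records.
* `compute_weights()`: presences keep weight 1 and pseudo-absences get
  `n_p / n_a`, so the weighted class sums are equal exactly.  The same
  weighting is applied when fitting, when finding thresholds and when
  scoring evaluation TSS, so that a 10,000-point background cannot drown
  300 presences.

## The four algorithms

GLM and GAM come from `stats` and `mgcv`; the tree ensembles are built on
an internal weighted CART learner (`src/cart.cpp`) because no tree
package is available in the target environment.  All stochastic fits
draw from R's RNG, so a seed makes them reproducible.

* **GLM** — binomial logistic regression with linear + quadratic terms
  per variable (the standard parametric shape for unimodal climate
  responses).  Complete separation (possible on noiseless fixtures)
  pins fitted probabilities at 0/1 without formal IRLS convergence; such
  fits are accepted, while genuine non-convergence is an error.
* **GAM** — thin-plate smooths, `k = 4` per variable (enough for a
  unimodal response without overfitting six correlated predictors).  For
  calibration sets above 4,000 rows the identical model is fit with
  `mgcv::bam(discrete = TRUE)` for speed.
* **RF** — 100 bagged CART regression trees on the 0/1 response;
  per-split `mtry = ⌊√p⌋`; rows are bootstrapped with probability
  proportional to case weight (the weighted bootstrap implements the
  presence/absence weighting); depth ≤ 12, minimum node size 5.
* **BRT** — logistic gradient boosting: 100 trees of depth 3 on the
  gradient `y − p`, Newton leaf values
  `Σw r / Σw p(1−p)` clamped to ±4, shrinkage 0.1, bag fraction 0.75.

Hyperparameters live in `sdm_settings()`.  They are deliberately modest
(100 trees rather than a reference library's 500) so the full design —
22 members × 4 evaluation fits × 24 species — stays tractable on one
CPU; on the separable and virtual-species fixtures they reach the same
evaluation scores as larger configurations.

## Evaluation, ensembles, consensus

`split_sample_eval()` repeats three times: stratified 80/20 split
(weights recomputed inside each part to preserve the equal-sum
contract), fit on 80%, predict the held-out 20%, binarize at the
TSS-maximizing threshold *found on the held-out predictions*, and record
that TSS.  A split that leaves a part single-class is redrawn with the
next sub-seed.  Because the threshold is optimized on the evaluation
fold, even label-independent data score slightly above zero; the test
suite therefore checks the null case against a permutation oracle rather
than against literal zero.

`maxtss_threshold()` scans the observed unique probabilities as the
candidate set (prediction "suitable" iff `p ≥ t`) and returns the
smallest candidate achieving the maximal weighted TSS — finite,
reproducible, and verified against a brute-force double loop in the
tests.

Each family's members are averaged with weights equal to their mean
split-sample TSS; members with TSS ≤ 0 are dropped with a warning
(a negative weight is meaningless in a weighted mean; if nothing
remains, the species fails).  The family threshold is computed once per
species on the family's pooled calibration rows — the ensemble
probability at those rows against their labels and weights — and reused
for every scenario projection, so scenario binaries differ only through
the climate, not through re-thresholding.  Final projections use models
refit on 100% of the calibration data (the evaluated configurations,
refit — the alternative of projecting the 80% fits is noted as an open
choice).  The consensus map is the cell-wise AND of the two family
binaries: deliberately conservative.

## Overlap and change statistics

`overlap_tss()` builds the confusion matrix over unmasked land cells
only (water carries no prediction) with the **congener as reference**:
`a` both suitable, `b` garden-only, `c` congener-only, `d` neither, and
`TSS = a/(a+c) + d/(b+d) − 1`.  The numerator `ad − bc` is symmetric but
the margins are not, so orientation matters; the congener-as-reference
orientation is the package default and a symmetrized mean is available
for sensitivity runs.  `overlap_cells()` is the plain count of cells
suitable to both.  Pairs are formed within genus and life form; pairs
with a degenerate margin (a map all-suitable or all-unsuitable) are
excluded and reported.  Metrics are averaged per garden plant
(unweighted over its congeners), separately per scenario.

Change is the natural-log ratio `ln(future/current)` of the per-garden
mean (natural log: convention only, inference is scale-free).  Records
with a zero metric in either period cannot enter a log ratio; they are
excluded and counted, and `n_input = n_used + n_excluded` is asserted in
the tests.  The per-scenario test is an intercept-only linear mixed
model with a genus random intercept, REML, Wald z-test of μ = 0 and a
normal-approximation 95% CI.  Simulation (16 genera × 2 species,
σ_genus = 0.1, σ_resid = 0.2) shows near-nominal coverage and type-I
error for this design.  Two boundary cases are handled explicitly: a
singular fit (genus variance estimated at zero) is reported with a flag,
and a design with one observation per genus — where the two variance
components are unidentifiable and `lmer` refuses — falls back to the
zero-genus-variance boundary estimate (an intercept-only least-squares
fit), also flagged.

## What a green test establishes — and what it does not

The acceptance-style checks verify: the TSS and threshold kernels
against brute force; the exclusion-radius guarantee; the exact weighting
contract; the consensus subset law on every pipeline output; recovery of
known true ranges (consensus TSS ≥ 0.6 for ≥ 90% of the 24 default
virtual species); mixed-model calibration against known truth; and the
directional reproduction of the headline pattern (garden expansion with
severity, no congener increase under severe warming, non-positive
overlap-ratio intercept) on the warm-biased default world.

They do **not** establish robustness to spatially biased sampling,
niche truncation by dispersal history, non-equilibrium occupancy, or
scenario fields with realistic spatial structure — none of which the
generator emulates.  The log-ratio analysis also inherits a survivorship
caveat: pairs whose overlap collapses to exactly zero leave the ratio
test rather than pulling its mean down, so the reported intercept is
conservative about decreases.  Runtime considerations (not statistics)
set the tree counts and the `bam` switch-over; both are recorded in
`sdm_settings()` and can be raised for production analyses.
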