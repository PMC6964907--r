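---
title: "Methods: seasonal niche models, paleo-projection and residency classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonal niche models, paleo-projection and residency classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoniche)
```

## The question the package answers

A fossil deposit with a rich, well-identified species list — the La Brea
tar pits are the motivating case — records which birds were at one place at
the Last Glacial Maximum (LGM, ~20 ka). Climatic niche models fitted on a
species' *modern* occurrence records can be projected onto LGM climate
reconstructions to ask the converse question: given where the species lives
now, was its climatic niche available at the fossil site then? Doing this
per season (breeding and winter records modeled separately) upgrades the
answer from presence/absence to a *residency status*: a species predicted
within reach of the site in both seasons was plausibly a year-round
resident; in one season only, a seasonal visitor.

`paleoniche` implements that workflow end to end — occurrence filtering,
presence-background maximum-entropy modeling, projection, thresholding,
distance-to-site measurement, status classification, and the summary
statistics built on top (shift cross-tabulations, Simpson turnover, Levins
niche breadth) — together with a synthetic-data generator that produces
worlds where the right answer is known, so every stage can be validated.

## Data model and conventions

* **Occurrences** are per-species, per-season longitude/latitude records
  (WGS84). Ingestion drops unparsable or out-of-range rows (counted, not
  silent) and collapses exact duplicate coordinates.
* **Climate** is a stack of the 19 bioclimatic variables (BIO1–BIO19) on a
  shared grid, one stack per epoch/GCM. Grids use cell-centre
  registration; row 1 is the northernmost row; the nodata mask is unioned
  across layers. I/O is the plain-text ESRI ASCII grid format.
* **Distances** are haversine great-circle distances on a sphere of mean
  radius 6371.0088 km. Thresholds stated in km (thinning distance, buffer,
  presence distance) are all interpreted with this metric.

## Occurrence filtering

Three filters precede fitting, mirroring common practice with continental
survey data:

* `filter_west_of(occ, -104)` restricts records to the region relevant to a
  western focal site. "West of" is a strict `<` on longitude.
* `thin_occurrences(occ, min_km = 20)` enforces a minimum pairwise spacing
  to blunt spatial sampling bias. The algorithm shuffles record order under
  the seed, then repeatedly deletes the record with the most neighbours
  within `min_km` (ties to the lowest shuffled index) until no pair
  violates the bound — deterministic per seed, and never worse than a
  single greedy pass on small instances (property-tested). Thinning is an
  optional stage: the reference analysis applied it only in a sensitivity
  subset, so the default configuration leaves it off.
* `subsample(occ, max_n = 1500)` caps very dense record sets by uniform
  sampling without replacement.

All three are idempotent and seed-reproducible.

## The maximum-entropy model

The core is a from-scratch presence-background maxent fit. Let
`f_j` be features built from the climate variables, scaled to the
background. The model is the Gibbs distribution over background cells

```
q(x) = exp(sum_j lambda_j f_j(x)) / Z
```

fitted by maximising the L1-penalised log-likelihood
`mean_presences eta(x) - log Z - sum_j beta_j |lambda_j|`.

**Features.** Variables are min/max-scaled over the background to `z` in
[0, 1]; features are `z` (linear), `z^2` (quadratic), `z_a z_b` (product,
all pairs), forward hinges `max(0, (z - k)/(1 - k))` at 50 evenly spaced
knots per variable, and step functions (threshold, off by default). Which
classes enter follows the standard presence-count ladder (fewer than 10
presences: linear; 10–14: + quadratic; 15–79: + hinge; 80+: + product);
an explicit class list overrides the ladder.

**Regularization.** Per-feature penalties follow the published per-class
interpolation tables against the presence count `m`:
`beta_j = multiplier * base(class, m) * sd_presence(f_j) / sqrt(m)`,
floored at 1e-4 so perfectly separable features cannot drive weights to
infinity. The floor is the package's own choice; it only matters for
features whose presence standard deviation is ~0.

**Optimizer.** Cyclic coordinate descent with soft-thresholding: each
coordinate takes a damped Newton step on the smooth part of the objective,
soft-thresholded by `beta_j`, and the step is halved until the penalised
objective does not decrease — so the objective trace is non-decreasing by
construction (asserted per sweep in the tests). Convergence is declared
when a full sweep improves the objective by less than `tol` (1e-5 default;
sweep caps of 1000 and 5000 mirror the two iteration budgets of the
reference analysis). At the optimum the KKT conditions give the classical
feature-matching bound `|E_presence f_j - E_q f_j| <= beta_j`, which the
test suite checks directly.

**Output scales.** `raw` is `q` normalised over the training background
(sums to 1 there, checked to 1e-9). `cloglog`, the default for
thresholding, is `1 - exp(-exp(H) * raw)` with `H` the entropy of the
fitted background distribution — the bounded output modern maxent
implementations report. The reference analysis predates the cloglog
default and does not state its output scale, so the scale is configurable.

**Projection.** `predict()` evaluates the model on any co-registered
stack. `clamp = TRUE` truncates projection-epoch covariates to the
training range before expansion; `extrapolate = FALSE` masks cells outside
the training range to nodata instead (the "no clamping or extrapolation"
sensitivity variant uses exactly that pairing).

## Background ("accessible area")

`build_background()` samples `n_bg` cells (10000 by default) uniformly
without replacement from the cells whose centres fall in the study area:
the minimum convex polygon of the records buffered outward by 150 km. The
buffer membership test is great-circle distance to the hull boundary;
point-in-polygon is planar in lon/lat, with the hull expanded by a
relative 1e-7 so cell centres lying exactly on the hull count as inside
(at continental extents the planar/spherical discrepancy is far below one
cell). Degenerate record sets (< 3 distinct non-collinear points) fall
back to a buffered bounding box, flagged on the result. `buffer_km = Inf`
selects the full valid extent, covering analyses that use the whole layer
rectangle as background.

## From suitability to residency status

* **Threshold.** The default rule is the 10th-percentile
  training-presence threshold: the nearest-rank (`k = ceiling(p n)`,
  no interpolation) 10th percentile of the fitted suitability at the
  training presences. With the `>=` comparison used in `binarize()`, at
  least 90% of training presences remain predicted present — the defining
  property, tested for every `n` in 1..200. The phrase "10% probability
  threshold" in the source literature is ambiguous between this rule and a
  fixed 0.10 cutoff; the percentile reading follows the cited thresholding
  literature, and a `fixed_value` rule is available for sensitivity.
  The threshold is resolved once per species and season on the
  training-epoch predictions and applied unchanged to the past-epoch
  projection.
* **Distance.** `distance_to_site()` returns 0 when the site's own cell is
  predicted present, otherwise the minimum haversine distance to a present
  cell centre; a map with no present cell yields the `NA` sentinel
  ("not computed"), which downstream classification treats as "farther
  than any threshold".
* **Classification.** With presence distance `D` (100 km by default):
  within `D` in both seasons → `resident`; breeding only → `breeding`;
  winter only → `winter`; neither → `not_present`. The boundary `<= D`
  counts as presence ("within 100 km or less"). `migrant` and `extinct`
  are metadata statuses assigned from natural history, never from
  distances.

## The packaged distance/status table

The package ships the printed 187-species distance/status table for the La
Brea avifauna as a plain-text fixture (`labrea_table()`), parsed with
explicit rules for its sentinel entries (`NC` = no predicted range, `>500`
= censored distance, trailing `?`/`*` = uncertainty qualifiers).
Reconstruction tests reproduce the printed shift cross-tabulation cell by
cell, the per-epoch residency counts, and the shifter total.

`check_status_consistency()` re-derives each modeled species' LGM status
from its own printed distances. Rows with a distance exactly at the 100-km
boundary are routed to a boundary-conflict report because the printed
table is internally inconsistent there (it classifies different
exactly-100 rows in different directions). Two further rows ("greater sage
grouse", 55/80 km printed as breeding-only; "House Finch", 0/150 km
printed as resident) contradict their own distances away from the
boundary; the checker reports them as mismatches rather than silently
reconciling either reading, and the corresponding acceptance test is
expected to flag them.

## Niche breadth and turnover

`levins_breadth()` computes the Levins inverse-concentration breadth on
the continuous suitability map over the projection extent (the convention
of the standard ENM toolkit): normalise suitabilities to `p_i`, then
`B_raw = 1 / sum(p_i^2)` and `B_std = (B_raw - 1)/(n - 1)`. `B_raw` is
scale-invariant; `B_std` runs from 0 (point mass) to 1 (uniform) and
increases monotonically along any point-mass-to-uniform mixture (tested).
Because `B_std` depends on `n`, cross-epoch comparisons must use a common
extent. Breadth comparisons use the Pearson product-moment correlation
(two-sided p from the t distribution on `n - 2` df); the source analysis
names both "rank-order" and "product-moment" in different places, so the
Spearman variant is available by flag.

`simpson_turnover(a, b, c) = min(b, c) / (a + min(b, c))` measures
turnover between the two epochs' species lists; it is symmetric in `b` and
`c` and undefined only when all three counts are zero.

`compare_scenarios()` scores agreement between two model runs (different
GCMs or settings) as the fraction of species whose within-`D` verdicts
coincide in every shared season; a species predicted absent by both runs
counts as agreement — two models that both keep a species away from the
site do not conflict.

## The synthetic world and what it does (and does not) show

`make_climate()` builds 19-layer stacks from per-layer planes (distinct
north–south and east–west gradients per layer so the layers are not
collinear) plus spatially autocorrelated noise (moving-average-smoothed
white noise rescaled to a target marginal sd); `apply_epoch_shift()`
derives a past epoch by per-layer affine change and a latitudinal
gradient. Species are Gaussian product kernels in climate space
(`synthetic_species()`): smooth, unimodal, analytically known, and —
deliberately — with log-suitability exactly quadratic in the variables, so
a linear + quadratic feature basis can represent the truth and parameter
recovery is a well-posed question. Winter niches are the breeding niche
shifted by a per-variable offset. Presences are drawn at cell centres with
probability proportional to suitability, which aligns sampling with
extraction exactly (no within-cell interpolation ambiguity).

`true_status()` computes ground-truth statuses by applying the *same*
thresholding/distance/classification rules to the true suitability
surfaces, with the percentile threshold taken in its sampling limit (the
suitability-weighted value distribution), so truth does not depend on a
finite presence draw.

`status_recovery_experiment()` is the package's reference validation: 30
species, 300 presences per season, on a 30 × 30 cell two-epoch world, with
niche centres placed either within 50 km of the focal site or beyond
280 km ("well separated" relative to the 100-km presence distance), niche
widths 0.5–1.2 times the per-layer climate spread, and an epoch shift that
displaces ranges by far less than 100 km. Under these conditions the
pipeline recovers at least 95% of (species, epoch) statuses (typically
98–100% across seeds), and fitted suitability rank-correlates with truth
at Spearman ≥ 0.9. The problem sizes (n_bg = 600, linear + quadratic
features) were chosen so the whole experiment runs in well under a minute;
they are stated here because recovery rates are only meaningful relative
to their conditions.

What passing these tests shows: the estimator, thresholding and
classification machinery are internally consistent and can recover known
truth when the model family contains it. What they do not show: anything
about real occurrence data — synthetic worlds have no sampling bias, no
spatial autocorrelation in detection, no niche truncation at range edges,
and layers far better behaved than real WorldClim surfaces. Species whose
true range edge sits near the 100-km contour of the site are inherently
unstable to classify — with an epoch shift that moves ranges by a
boundary-scale distance, any method's recovery degrades; the validation
conditions avoid that regime on purpose, and users should treat statuses
of real species with near-boundary distances with the same caution.

## Numerical choices and degenerate inputs

* Nearest-rank percentiles everywhere (no interpolation dialects).
* `>=` at threshold boundaries (presence retention guarantee) and `<= D`
  at the presence distance (boundary counts as presence).
* Coordinate-descent steps are accepted only if the penalised objective
  does not decrease; the convergence flag distinguishes tolerance-met from
  iteration-capped fits.
* Zero-variance features are dropped with a warning; duplicate presence
  cells are collapsed before fitting; presences on nodata cells are
  dropped and counted.
* Thinning of a single record returns it unchanged; an empty post-filter
  occurrence set warns rather than errors (the batch runner records it).
* Per-species failures in `run_batch()` become error rows; a 180-species
  batch does not abort on one degenerate input.
* Every report row carries the MD5 hash of the configuration that
  produced it.

## Known limitations

* Raster I/O is ESRI ASCII grid only; the format is text and
  self-describing, and co-registration is enforced on read.
* No replication of the reference Java implementation's exact numerics is
  attempted (different optimizer, different hinge dictionary); agreement
  is at the level of the model family and its defining properties.
* Straight-line distances only — no least-cost paths or habitat-aware
  reachability.
* No AUC/omission evaluation suite; model quality checks are the
  property-based ones described above.
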