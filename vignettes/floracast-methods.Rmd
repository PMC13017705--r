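---
title: "Methods: ensemble range projections for a regional flora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble range projections for a regional flora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floracast)
```

## The problem

High-latitude and other climatically marginal floras are expected to
reorganize substantially over the 21st century: species ranges shift
poleward, expand, or contract depending on the emission pathway, and the
species currently confined to the coldest available habitat can be left
with nowhere to go. `floracast` packages the standard analysis chain for
quantifying this at the flora level:

1. presence-only occurrence records are filtered by a minimum record
   count and thinned to the model grid;
2. per-species habitat suitability is modelled with a five-learner
   ensemble, weighted by cross-validated AUC;
3. suitability is binarized at the maximum-TSS threshold and projected
   onto a current + 4-period x 4-scenario climate matrix (17 maps per
   species);
4. range maps are reduced to area-of-habitat (AOH) change classes, fold
   changes, extinction flags, and distributional-centroid migration
   vectors;
5. binary maps are stacked into species-richness surfaces and summarized
   per longitudinal sector.

Because the real inputs (collection records, downscaled GCM output) are
large and access-restricted, the package ships a virtual-species module
that generates every input with known ground truth, so the full chain is
testable offline and its recovery properties can be measured exactly.

## The model

### Suitability learners

For species $s$ with presence cells $P_s$ and background cells $B_s$, a
covariate vector $x$ is scored by five learners, each mapping to
$[0, 1]$:

* **envelope** — the fraction of covariates inside the presence
  $[p_{5}, p_{95}]$ percentile box;
* **mahalanobis** — $\exp(-D^2/2)$, with $D^2$ the Mahalanobis distance
  to the presence centroid under a ridge-regularized covariance;
* **logistic2** — maximum-likelihood logistic regression on linear and
  quadratic covariate terms, so unimodal responses are representable;
* **knn** — the inverse-distance-weighted presence fraction among the
  $k = \min(10, |P_s|)$ nearest training cells in standardized covariate
  space;
* **boost_stumps** — a gradient-boosted additive model of 100 depth-1
  stumps on logistic loss (shrinkage 0.1), passed through the logistic
  function.

The five span envelope, parametric, and nonparametric families, which is
the point of multi-algorithm SDM ensembles: no single inductive bias
dominates the projection.

### Evaluation and combination

Each learner is scored by stratified $k$-fold ($k = 5$) cross-validated
AUC, computed with the Mann–Whitney pair formulation (ties count 1/2).
Learners below the inclusion cutoff (default AUC 0.7) are dropped;
the rest are combined as a weighted mean with

$$w_i \propto \max(\mathrm{AUC}_i - 0.5,\; 0),$$

so a chance-level learner contributes nothing even if it sneaks past the
cutoff. If no learner passes, the species is flagged unmodelable, logged,
and excluded from downstream statistics rather than silently filled in.

### Binarization and projection

The ensemble score is cut at the threshold maximizing
$\mathrm{TSS} = \text{sensitivity} + \text{specificity} - 1$ over the
training presences and backgrounds, scanning the unique observed scores
plus midpoints and breaking exact ties toward the lower threshold. One
threshold per species, fit on current-period data, binarizes all 17
projections — letting the threshold drift across scenarios would
confound every change metric downstream.

Projection assumes unlimited dispersal (future occupancy is wherever
suitability clears the threshold), matching a *potential* distribution
framing. Covariate values outside the training range are clamped to the
training min/max rather than dropped; the clamped fraction is recorded
per map. Clamping avoids holes in the projection at the cost of flat
extrapolation, which is the conservative choice for a monotone response
edge.

### Areas, centroids, migration

All areas are spherical: a cell at centre latitude $\varphi$ with
resolution $\Delta$ has area
$R^2\,\Delta\lambda\,(\sin\varphi_2 - \sin\varphi_1)$ with
$R = 6371.0088$ km. AOH is the area sum over occupied cells. The
distributional centroid is the area-weighted mean of occupied-cell unit
vectors on the sphere, renormalized — never a planar mean, because study
regions can cross the antimeridian. Migration vectors report
$\Delta\text{lat}$, $\Delta\text{lon}$ wrapped to $(-180, 180]$, and the
haversine displacement; $\Delta\text{lat} = 0$ is counted with
"southward" so the northward percentage is conservative. Species whose
future AOH is zero are excluded from centroid statistics and counted as
extinctions.

### Change classes and richness

Relative AOH change is measured against the current AOH; species within
the ±5% stability band are "stable", otherwise the sign decides
expansion/contraction. A zero current AOH has no defined baseline: such
species are reported separately, never classified. Richness is the
per-cell sum of binary occupancies; mean species richness (MSR, species
per grid cell) is the *unweighted* cell mean, matching the "per grid
cell" unit, with an area-weighted variant behind a flag. MSR is returned
at full precision and rounded (half-up, one decimal) only at reporting —
per-call rounding would break the partition identity that sector MSRs,
weighted by cell counts, recompose the whole-mask MSR, and that identity
is tested.

## The synthetic world

`generate_climate()` builds one current grid and 16 future grids. The
temperature-like layer decreases linearly with latitude (default lapse
0.45 °C per degree) plus a smooth Gaussian random field (white noise
smoothed by a separable Gaussian weight matrix, correlation length 5
cells); a precipitation-like layer carries a longitudinal gradient; two
further layers are pure smooth fields. Future grids add a warming
increment per (period, scenario), required nondecreasing in both period
and emission level. The default table spans 2.8 °C (low-emission) to
10.4 °C (high-emission) by the 2090s — the projected end-of-century
Arctic surface-warming range across the SSP1-2.6 to SSP5-8.5 scenarios —
with earlier decades interpolated monotonically. Only temperature
changes by default, keeping the ground truth interpretable.

Virtual species have Gaussian responses per covariate,
$\prod_j \exp(-(x_j - o_j)^2 / 2\tau_j^2)$; optima are drawn from an
interior quantile window of each covariate's current distribution and
tolerances as 0.75–1.5 covariate standard deviations. With a product of
four responses, narrower tolerances frequently produce species whose
suitability never reaches the occupancy cutoff (0.5); parameters are
redrawn until the true range is non-empty, because a virtual species
without a range cannot serve as ground truth. Occurrences are sampled
from occupied cells with probability proportional to suitability times
an optional bias field, then jittered strictly inside the cell,
emulating presence-only collection data.

What the generator does **not** emulate: spatial autocorrelation in
sampling effort beyond the bias field, coordinate error, taxonomic
misidentification, dispersal limitation, biotic interactions, and
non-Gaussian (e.g. skewed or bimodal) responses. A green test therefore
establishes that the pipeline recovers what its own model family can
express — not that any real flora satisfies those assumptions.

## The recovery experiment

`shift_recovery_experiment()` is the analysis-grade validation surface.
Its world has a *single* covariate, temperature, strictly linear in
latitude with no noise, so a uniform warming increment of
$0.45 \times 2 = 0.9$ °C shifts every species' true range poleward by
exactly 2.0° — the imposed shift is known, not approximately known. An
earlier design with an added nuisance covariate recovered the latitude
band exactly but produced longitudinally patchy maps (the learners
partly respond to the nuisance layer), i.e. it measured SDM nuisance
sensitivity instead of parameter recovery; the construction was
simplified before the tests were frozen. At the default 50 species with
100 presences on a 40 x 80 grid, the pipeline's mean recovered shift is
within 0.25° of truth, ensemble AUC against the true range exceeds 0.9
for at least 90% of species, and current AOH is recovered within 25% for
at least 80% — all three are asserted in the acceptance suite and
recomputed by `scripts/acceptance.R`.

Individual species' recovered shifts scatter around 2.0° by up to
roughly half a grid cell: the max-TSS threshold often sits exactly on an
observed presence score, so a one-ulp difference between the current and
the shifted temperature field can flip a boundary row of occupancy. The
mean over species is unaffected.

## Numerical and design choices

* **"More than 25 records"** is a strict inequality; a species with
  exactly 25 records is excluded. Configurable via `min_records`.
* **Coverage percentages** are rounded half-up to one decimal, matching
  the reporting style of floristic checklists.
* **Background sampling** defaults to 10x the presence count, capped at
  10 000, uniform over non-presence cells — common presence-background
  practice; the sample is clamped with a warning when the grid is small.
* **AUC weighting baseline 0.5** (not 0) so weights measure skill above
  chance; **inclusion cutoff 0.7** is the conventional "fair/good"
  boundary.
* **Sector bands**: the five-sector division of the circumpolar flora
  (ER-WSS, ESS, BS, CS, NAS) is supplied as a longitude-band table with
  antimeridian wrapping; the published borders are cartographic, so the
  defaults are stand-ins and real analyses should pass their own bounds.
  Species are assigned to sectors by their *current* centroid.
* **Stability band base**: relative change is measured against the
  current AOH (the natural baseline); the band is configurable.
* **Degenerate inputs** raise typed conditions (`fc_invalid_config`,
  `fc_no_habitat`, `fc_unmodelable`, `fc_alignment_error`, ...) so
  callers can distinguish data problems from bugs.
* **Serialization** is plain text (long-format CSV + JSON sidecars) with
  round-trip tests; no binary raster dependency is required.

## Known limitations

* The five learners are deliberately simple stand-ins spanning the usual
  algorithm families; there is no MaxEnt, GAM, or spatial-block CV.
* Unlimited dispersal overstates attainable future range for poorly
  dispersing species; the framework reports *potential* habitat.
* MSR is sensitive to grid resolution (it is "per grid cell"); compare
  MSR values only at a fixed resolution.
* Longitude-band sectors are an approximation of cartographic sector
  borders.
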