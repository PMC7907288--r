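---
title: "Landmark-based dysmorphology analysis and treatment scoring with morphoscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-based dysmorphology analysis and treatment scoring with morphoscore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoscore)
```

## The problem

Syndromic conditions such as trisomy 21 alter craniofacial form in
consistent, quantifiable ways. Given 3D coordinates of homologous
anatomical landmarks digitized on every specimen — a dozen skeletal
landmarks on a mouse snout, or 21 soft-tissue landmarks on a child's face
— we want to (i) place every specimen in a common shape space free of
position, size and orientation, (ii) localize which facial dimensions
differ between an affected group and controls, and (iii) decide whether a
treatment moved the affected group measurably back toward the control
morphology. `morphoscore` implements that full chain, together with a
synthetic cohort generator so that every stage can be validated against
known ground truth.

## Generalized Procrustes superimposition

`gpa_superimpose()` centres each configuration, scales it to unit
centroid size, and iteratively rotates all configurations onto the
arithmetic mean shape until the consensus stabilizes (partial Procrustes
with pre-scaling). Two numerical choices matter:

* **Proper rotations only.** Optimal rotations are constrained to
  determinant +1. Anatomical configurations must never be mirrored, even
  when a reflected fit would be numerically closer.
* **Canonical orientation.** GPA determines shapes only up to a common
  rotation, which depends on the input poses. After convergence the
  consensus is rotated onto its principal axes with signs fixed on the
  rotated coordinates (the landmark with the largest coordinate on each
  axis made positive; the minor axis yields if needed to keep the
  rotation proper). Aligned coordinates are then a deterministic function
  of the shapes alone: re-running on arbitrarily translated, rotated and
  rescaled copies of the input reproduces every coordinate to ~1e-9.

Defaults: convergence tolerance 1e-10 on the root-mean-square consensus
change, at most 100 iterations. Shape coordinates are used directly; no
tangent-space projection is applied (variation in these cohorts is small
relative to the curvature of shape space; the option would matter only
for very disparate shapes).

`procrustes_distance()` is the partial Procrustes distance: the root
summed squared difference after optimal proper rotation of one (centred,
unit-size) shape onto the other. It is the statistic of the permutation
tests and the diagnostic metric throughout.

## Allometric correction

Cohorts spanning a growth period confound shape differences with growth.
`allometry_correct()` fits, within each declared age stratum, an
ordinary least-squares regression of every flattened Procrustes
coordinate on age, and replaces shapes by residuals re-centred on the
stratum consensus. Residuals are exactly age-uncorrelated within each
stratum and retain the stratum mean, and correcting twice changes
nothing. Strata need at least 3 specimens and non-constant age; both
violations abort with the stratum named. Single-age designs (e.g. mice
all sampled at postnatal day 29) skip the correction — this is the
pipeline default for mouse-style runs.

## Ordination and range-of-variation membership

`pca_fit()` eigendecomposes the specimen covariance of the (corrected)
shape coordinates. Eigenvector signs are fixed so the largest-magnitude
loading of each component is positive, making ordinations reproducible;
scores are centred projections whose covariance is diagonal with the
eigenvalues on the diagonal, and the percent-variance vector sums to 100.

"Fell within the range of variation of the controls" is made geometric by
`hull_membership()`: the convex hull of the reference group's scores in a
chosen component plane (PC1–PC2 by default), with query points counted
inside when on or within the boundary (closed hull — the stabler
convention; the source studies do not state a rule). Collinear reference
sets are rejected rather than silently producing a degenerate polygon.

## EDMA contrasts

`pairwise_distances()` converts each specimen to its K(K−1)/2 unique
inter-landmark distances (210 for K = 21), a coordinate-free shape
representation. `edma_contrast()` compares two groups distance by
distance using the form-difference ratio of group mean distances (null
value 1; a difference-of-means mode with null 0 is available). The
classic EDMA form-difference matrix is a ratio, which is why the ratio is
the default. Uncertainty comes from a non-parametric bootstrap: specimens
are resampled with replacement independently within each group (10,000
resamples by default), and a pair is significant when the two-tailed
percentile interval at level 1 − α (α = 0.10 by default, i.e. the
5th/95th bootstrap percentiles) excludes the null value.

Numerical details worth knowing:

* Ratio intervals are computed as exponentiated percentile intervals of
  the log ratio. This is the natural scale for a ratio and makes group
  swapping exactly self-consistent: exchanging the two groups inverts
  every statistic about 1 and reproduces the identical significance set.
* Resample indices derive deterministically from the master seed and each
  group's label, so results are bit-reproducible and independent of how
  many distance pairs exist.
* **No multiple-testing correction is applied across pairs.** Each of the
  D distances is tested at raw level α, matching standard EDMA reporting.
  The percent-significant summary therefore has expectation ≈ 100α under
  the null, not 0 — interpret it as a relative, not absolute, measure.
  The simulated null calibration (two groups of 20, K = 12, σ = 0.02)
  puts the mean per-pair rejection rate at ≈ 0.115 for α = 0.10; the
  slight excess is the usual small-sample anti-conservatism of percentile
  bootstrap intervals.

## The treatment score and its scaffolded null

The facial treatment score summarizes rescue as the relative reduction in
the percentage of significantly different distances,

FTS = 100 × (pct_ref − pct_trt) / pct_ref,

where pct_ref comes from the affected-vs-control contrast and pct_trt
from the treated-affected-vs-control contrast. 100 means complete rescue,
0 no change, negative values a worsening. The score is undefined when
pct_ref = 0 (nothing to rescue); such cases abort (observed score) or are
excluded as NA from the null (simulations), with the count reported.

Significance comes from the scaffolded resampling null implemented in
`fts_null_distribution()`. With N treated-affected specimens, the pooled
affected sample (treated plus untreated) is repeatedly re-partitioned
into a pseudo-treated group of size N containing exactly M truly treated
members (M scaffolds over 0 … N−1, `reps_per_m` draws per M, uniformly
without replacement) and a pseudo-untreated complement; both contrasts
and the score are recomputed each time. Control groups are never
re-partitioned. The p-value is the fraction of null scores strictly
exceeding the observed score (ties count against significance). The
default `reps_per_m = 75` gives, at N = 5, a null of ~375 simulations —
the resolution at which a p-value of 0.008 corresponds to 3 exceedances.

Two design choices:

* **M = N is the observed value, not part of the null** (a flag includes
  it if desired).
* **Common random numbers.** One bootstrap stream is shared by the
  observed score and all scaffold simulations, and by the reference and
  treated contrasts within a simulation. Simulations then differ only in
  group composition, not in bootstrap Monte-Carlo noise; a treated group
  identical to the affected group scores exactly zero, and the null
  comparison is sharper at no cost in validity (p-values remain uniform
  under label randomization — verified by a KS check in the test suite).

### A genuine limitation discovered in validation

Under *perfect* rescue (every treated specimen distributionally identical
to controls), pseudo-treated groups at large M contain a single
dysmorphic contaminant. That contaminant inflates the pseudo-group's
within-group variance, which *widens* the bootstrap intervals and
*suppresses* false-positive distances — so those null scores
systematically exceed the observed score, and the scaffold p-value
plateaus around 0.05–0.2 even for a perfect treatment. The artifact is a
property of any CI-based EDMA inside this scaffold, is maximal for
homogeneous (all-responder) treated groups, and vanishes for the
heterogeneous responder mixtures that real cohorts exhibit (and that the
generator's default π_resp = 0.6 emulates). Interpret scaffold p-values
cautiously when a treated group is suspiciously homogeneous.

## Permutation tests on Procrustes distances

`procrustes_perm_test()` tests a two-group mean-shape difference: the
statistic is the Procrustes distance between group mean shapes; labels
are permuted (10,000 rounds by default) over the globally aligned
coordinates — alignment is not re-run per permutation because labels are
exchangeable under the null and a global GPA does not depend on them.
Permuted distances ≥ observed count as exceedances, so an observed
distance of zero gives p = 1. The add-one convention
p = (1 + b)/(1 + n_rounds) is the default (never reports exactly zero);
the raw ratio b/n_rounds is available for comparability with analyses
that used it.

## The synthetic cohort generator

`simulate_cohort()` draws each specimen as

template + genotype displacement + treatment rescue + allometric growth + noise.

What the pieces emulate, and the defaults:

* **Templates** (`make_template()`): fixed bilateral configurations with
  unit centroid size — 12 landmarks (4 midline + 4 pairs, snout-like) and
  21 landmarks (7 midline + 7 pairs, face-like). Emitted coordinates are
  template units × 15 mm (mouse-like) or × 100 mm (human-like).
* **Genotype displacement**: a fixed documented field concentrated on
  midface/nasal landmarks (retraction and flattening), scaled so the
  most-affected landmark moves by `delta` (default 0.1 template units).
  Normalizing by the maximum landmark displacement makes `delta` directly
  comparable to the noise σ — "delta = 5σ" means the most-affected
  landmark moves five noise standard deviations.
* **Treatment**: each treated-affected specimen is a responder with
  probability `pi_resp` (default 0.6, echoing the observed 60/40 split of
  rescued-vs-dysmorphic treated animals); responders have the genotype
  displacement reduced by fraction `rho` (default 1); non-responders are
  unchanged. `kappa` ≥ 1 inflates treated-affected noise (default 1),
  emulating the enlarged phenotypic variation reported under aggressive
  dosing.
* **Ages and allometry**: mouse-style cohorts are single-age (P29, no
  allometry). Human-style cohorts draw ages uniformly within group bounds
  (default 0–3 years) and add `allometry_slope` (default 0.01 template
  units/year) along a fixed growth field (lower-face elongation, nasal
  projection).
* **Noise**: isotropic Gaussian per landmark, σ = 0.02 template units by
  default. On the human template this corresponds to ~2 mm at the 100 mm
  scale — dominated by biological individual variation; reported
  digitization error (~0.3 mm) is an order of magnitude smaller and is
  not modelled separately.
* **Group sizes** default to the two study designs: 14/15/6/5
  (untreated/treated control, untreated/treated affected; mouse low-dose)
  and 57/20/7 (control, affected, treated affected; human 0–3 years, no
  treated control).

What the generator does **not** emulate: spatially correlated noise,
landmark-specific digitization precision, asymmetry, growth
non-linearity, dose–response structure, or any covariance structure
fitted to real data. Passing tests on these cohorts therefore validate
the *statistical machinery* — calibration, power, invariances, parameter
recovery — not the biological fidelity of any particular dataset.

## Problem sizes used in validation

The test suite exercises: type-I calibration over 200 null cohorts
(n = 20 + 20, K = 12, 1,000 resamples); scaffold-null uniformity over 100
cohorts (N = 5, 20 draws per M, 200 resamples); full-rescue recovery over
20 cohorts (all groups n = 20, 10 draws per M, 2,000 resamples);
responder-mixture recovery at n = 400 per group. These sizes make the
Monte-Carlo error small relative to each acceptance band while keeping a
full run of the suite in the minutes range.

## Known limitations

* Percentile bootstrap intervals at group sizes of 3–10 are appreciably
  anti-conservative; percent-significant values from very small groups
  run above nominal. BCa or studentized intervals are not implemented.
* The scaffold p-value artifact under homogeneous treated groups,
  described above.
* No missing-landmark handling: datasets with absent or non-finite
  coordinates are rejected outright rather than imputed.
* No semilandmarks, bilateral-symmetry decomposition, or surface
  morphing; ordination output is tabular, not rendered.
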