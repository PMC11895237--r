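---
title: "Methods: cranial morphometrics of flying squirrels across diets and biomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cranial morphometrics of flying squirrels across diets and biomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pteromorph)
```

## The scientific problem

Flying squirrels (Pteromyini) span tropical and temperate forests and eat
everything from conifer needles to flesh fruit. Two questions structure the
analysis this package implements:

1. **Does diet shape the cranium?** Ventral cranial form is summarized by
   2D landmarks and semilandmarks; diet and size effects on shape are
   tested with a phylogenetically informed multivariate model.
2. **Are tropical assemblages more disparate?** Per-biome morphological
   disparity is compared against a Monte Carlo null that holds species
   richness fixed, so a biome can only be called "more disparate" if it
   exceeds what a random draw of the same number of species would show.

The museum coordinate data are not publicly deposited, so the package
ships a synthetic-data generator that reproduces the statistical structure
of the study — the analysis pipeline itself is identical whichever data
source is used.

## Digitization template and bilateral expansion

The template (`pteromyini_template()`) has 19 fixed landmarks and four
semilandmark curves in the ventral view: the snout contour between
landmarks 1 and 19 (8 semilandmarks), the outer (19–18) and inner (7–9)
zygomatic-arch curves (18 each), and the closed outline of the fourth
upper premolar (18), i.e. 81 points per side. Because the cranium is
bilaterally symmetric, one side is digitized and reflected
(`mirror_configuration()`) across the total-least-squares line through the
mid-sagittal landmarks. Landmarks 1, 10, 11, 13 and 14 are mid-sagittal by
their anatomical definitions and form the default axis; landmarks 2
(incisor-socket midpoint) and 12 (pterygoid apophysis) sit near the
midline but are not constrained to it, so they are excluded by default
(the set is configurable). The closed premolar curve is stored with a
wrap-around flag so its sliding tangents have no endpoints.

## Superimposition

`gpa()` implements Generalised Procrustes Analysis: every configuration is
centered, scaled to unit centroid size, and rotated to the evolving mean;
the mean is recomputed and the loop stops when it moves by less than `tol`
(default `1e-10`, max 200 iterations — an error, not a silent stop, if
exceeded). Rotations are proper (det +1): with bilateral configurations a
reflection would otherwise be a genuine risk. Centroid size — the square
root of the summed squared distances of the points to their centroid — is
recorded before scaling and log-transformed downstream.

Semilandmarks are slid (optionally, each of the first 10 iterations) to
minimize the thin-plate-spline bending energy of the deformation from the
current mean to each specimen. Each semilandmark moves along its local
tangent (central difference of its curve neighbours in the same specimen;
open-curve ends are anchored by the bounding fixed landmarks); the optimal
joint displacement solves one small linear system per specimen in the
bending-energy metric of the mean. Because zero displacement is always
admissible, the energy never increases — a property the tests audit
directly. Distances between shapes are full Procrustes distances computed
on the aligned unit-size coordinates; no separate tangent-space projection
is applied, which matches the distance definition used throughout the
downstream statistics.

## Morphospace

`shape_pca()` is an eigen-decomposition of the covariance of the flattened
aligned coordinates (species means by default). Axes are orthonormal and
deterministically oriented (largest-magnitude loading positive), scores
have zero column means, and `axis_endpoint_shapes()` returns the mean
shape displaced to the observed extremes of an axis — the deformation
grids usually drawn at the ends of PC axes.

## Comparative models

`bm_covariance()` builds the Brownian-motion covariance (shared
root-to-ancestor path lengths) from the tree; `lambda_transform()`
multiplies its off-diagonal by Pagel's λ. `estimate_lambda()` maximizes,
over a common λ ∈ [0, 1], the summed per-coordinate Gaussian profile
log-likelihood of the residuals of the *non-phylogenetic* fit of the full
model — the workflow the pipeline then applies by refitting every model
with the λ̂-rescaled covariance. The estimate is deterministic (bounded
scalar optimization, tolerance 1e-6, interval ends checked).

`pgls_fit()` premultiplies response and design by the inverse square root
of the (λ-rescaled) covariance and decomposes variation sequentially
(type I, formula order, diet before size): each term's SS is the drop in
summed squared residuals between nested models, which for multivariate
shape data is exactly the Procrustes (distance-based) decomposition.
Significance uses randomization of reduced-model residuals (RRPP):
residuals of the term's reduced model are permuted, added back to the
reduced fit, and F recomputed; `p` counts the observed arrangement among
`n_perm` (default 1000), and `Z` is the position of log F in the permuted
distribution. The same machinery fits scalar responses (log centroid
size), so the size-on-diet test shares code with the shape models.

Two ambiguities were resolved as follows:

* **Interaction rule.** The headline shape model is additive
  (`interaction = "never"`): the published table's degrees of freedom
  (diet 4, size 1, residuals 14 of 19 total) show no interaction row was
  fitted. `"always"` and `"auto"` (include the interaction only when the
  size-on-diet test is significant) are available.
* **λ source.** λ is estimated once, from the residuals of the full
  additive model, and applied to all reported fits; per-model estimation
  is possible by calling `estimate_lambda()` on another fit's residuals.

`pairwise_dispersion()` compares, for every pair of diet categories, the
mean distance of members to their group mean computed on residuals in the
transformed space, with label-free permutation of the residual vectors
(`"rms"` dispersion available behind a flag). `allometry_scores()`
projects each species' centered shape onto the GLS-estimated size
regression vector; the phylogeny enters through the estimated direction,
and the scores are comparable directly with log size. Species lacking
diet information are dropped from all comparative fits (they stay in the
disparity pool); the run manifest records how many.

## Disparity and the richness-conditioned null

For each biome, `biome_disparity()` computes every occupant's Procrustes
distance to the biome mean shape (occupants' mean, re-standardized to unit
centroid size); the headline statistic `D` is the mean squared distance
(Foote-style Procrustes variance). The alternative `"variance"` statistic
(summed squares over n − 1) is shipped but not default: being unbiased,
its expectation does not grow with the number of species drawn, which
would erase the increasing disparity–richness relationship the null model
is designed to expose. `"mean"` (mean distance) is also available. Size
disparity replaces distances with absolute deviations of log centroid
size. Species occupying several biomes contribute to each; a biome with
fewer than two occupants is flagged undefined (the savanna, with two
species, is computed but marked low-power).

`richness_null()` draws, for each richness k, `n_rep` subsets of k species
uniformly without replacement from the full 35-species pool and records
each draw's disparity; `richness_regression()` fits the expected
disparity–richness line. `biome_null_test()` then compares each biome's
observed disparity to the null replicates at its exact richness, one-sided
in the direction of the biogeographic hypothesis (tropical biomes I, II
and II/III tested for *higher*, temperate/boreal V, VI, VIII for *lower*
disparity), with the reverse tail also reported. p-values use the add-one
convention (count at least as extreme + 1)/(n_rep + 1), so they are never
exactly zero and the two tails sum to at least 1; "significant" means the
observed value lies outside the one-sided 95% bound.

## The synthetic-data generator

`simulate_dataset()` emulates the study conditions; its defaults are fixed
and the tests are run against them.

* **Sampling structure.** The species list, per-species specimen counts
  (151 specimens over 35 species, including several singletons), diet
  categories and biome occupancy are taken from the shipped sampling
  table. Purely synthetic tables (balanced diets, a tropicality-graded
  occupancy gradient with overlapping biome windows) are available for
  arbitrary n.
* **Phylogeny.** A pure-birth tree rescaled to unit depth stands in for
  the published phylogeny, which is not deposited.
* **Species means.** Grand mean = the template's deterministic base
  geometry; plus a diet displacement (magnitude 0.0043 shape units,
  0.0058 for the needle-feeding folivores, along random orthonormal
  directions), an allometric displacement (0.010 per unit log size along
  an orthogonal direction), and a Brownian deviation (expected norm
  `sigma_bm = 0.008` over unit depth) drawn on the λ-transformed tree.
  These magnitudes were chosen once so that the realized sequential r²
  on noiseless species means reproduces the published variance partition
  (diet ≈ 0.28–0.30, size ≈ 0.15, size-on-diet ≈ 0.28 and usually
  non-significant at n = 20–23).
* **Tangent-free signal.** All species-level effect vectors are projected
  off the local curve-tangent directions at semilandmarks (the Brownian
  term rescaled so `sigma_bm` keeps its meaning). Along-curve position is
  a digitization artifact that sliding is entitled to remove; placing
  generator signal there would make the slid pipeline erase real signal.
  Specimen noise stays isotropic — that is precisely the error sliding
  should clean.
* **Specimens.** Species mean + iid Gaussian coordinate noise
  (sd 5e-4 per coordinate, about the magnitude of between-species
  differences — realistic for cranial data), then an arbitrary rotation
  (uniform), translation (uniform ±10) and scale (log-normal, sd 0.2)
  that GPA must undo. Centroid sizes are log-normal per diet
  (means 4.92–5.12, log-mm scale).
* **`true_values`.** Every generating quantity (mean shapes, directions,
  magnitudes, deviations, realized r²) is returned for recovery tests.

What passing tests on these data do **not** show: the generator has no
cranial anatomy (its base shape is an ellipse-and-arcs geometry), no
digitization-optics error model, no integration among modules of the
skull, and its diet effects are linear displacements rather than
correlated regional deformations. Recovery and calibration results
therefore validate the estimators and the pipeline plumbing, not any
biological claim about real crania.

## Numerical choices and degenerate inputs

* GPA tolerance 1e-10 on mean displacement, max 200 iterations, sliding in
  the first 10 iterations; non-convergence is an error carrying the last
  change.
* The sliding system carries a 1e-12 relative ridge; since the zero
  displacement remains admissible, monotone energy decrease is preserved.
* Zero-size (all-coincident) configurations, coincident mean points in
  the bending-energy matrix, singular covariances, rank-deficient
  designs, singleton dispersion groups and sub-2-species biomes all raise
  structured errors or flagged reports rather than propagating NaNs.
* Permutation p-values include the observed arrangement, so they lie in
  (0, 1]; all permutation streams are seeded and reproducible.
* PCA axis signs follow the largest-loading-positive convention for
  platform-stable output.

## Problem sizes used in the shipped checks

The test-suite calibration studies use deliberately small cases chosen to
estimate each property with adequate Monte Carlo precision: 50-seed
recovery studies on 50-tip trees for λ and 30-species datasets for the
diet effect; 200-replicate null studies for the type-I error of the PGLS,
dispersion and disparity ANOVA tests; 1000 null draws and 1000 pseudo-
observed draws for the null-test calibration and coverage; the end-to-end
runs in the acceptance script use the full 151-specimen, 81-point,
35-species conditions with 1000 permutations and 1000 null replicates.

## Known limitations

* 2D ventral view only; no 3D superimposition or missing-landmark
  estimation.
* Brownian motion (optionally λ-rescaled) is the only evolutionary model;
  no OU or early-burst alternatives, and λ is common to all coordinates.
* λ̂ estimated from species means is attenuated by specimen sampling
  noise (singleton species especially); under the default conditions the
  end-to-end λ̂ is typically 0.4–0.5 even though the generating signal is
  1. This is a property of the published workflow itself, which the
  package reproduces rather than corrects.
* The disparity ANOVA treats a species present in several biomes as one
  observation per biome; the alternative (each species once) is not
  implemented.
* Biome assignment and diet categorization are consumed as metadata; the
  GIS and literature work that produced them is out of scope.
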