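# pteromorph

Geometric-morphometric analysis of cranial shape in flying squirrels
(Pteromyini), for morphometricians and comparative biologists who want the
whole workflow — landmark I/O, superimposition, phylogenetic models,
biome-level disparity nulls — as tested, composable R functions rather
than a one-off script.

The package asks two questions of ventral-cranium landmark data:

1. **Diet and allometry.** Do diet category and cranial size explain
   cranial shape once phylogeny is accounted for? Shape is the matrix of
   Procrustes-aligned coordinates **Y** (19 landmarks + 62 slid
   semilandmarks per side); the models are Procrustes PGLS fits of
   `size ~ diet`, `shape ~ diet + size` and `shape ~ size`, estimated
   after premultiplying data and design by **C**<sub>λ</sub><sup>−1/2</sup>,
   where **C** is the Brownian-motion covariance of the phylogeny and λ is
   Pagel's lambda estimated from the residuals of the non-phylogenetic
   fit. Sums of squares are sequential Procrustes (distance-based) SS;
   significance comes from RRPP permutation of reduced-model residuals
   (F, Z, and permutation p per term). Dispersion around diet mean shapes
   is compared pairwise, and allometry is summarized by regression scores
   against log centroid size.
2. **Disparity across biomes.** For each Walter biome occupied by flying
   squirrels (I, II, II/III, V, VI, VIII), disparity is the Procrustes
   variance D = mean squared Procrustes distance of the occupant species
   to the biome mean shape (or the variance of log centroid size). Each
   observed D is tested against a Monte Carlo null built by repeatedly
   drawing the same number of species from the full pool — one-sided,
   *higher* than expected for tropical biomes, *lower* for
   temperate/boreal ones, with the reverse tail reported too.

Because the museum specimens are not publicly deposited, a first-class
synthetic-data generator reproduces the study's statistical structure
(species means evolving by Brownian motion on a phylogeny, additive diet
and allometric shape effects, per-diet log-normal sizes, specimen-level
noise, arbitrary rotation/translation/scale per specimen, and the real
sampling table's specimen counts, diets and biome occupancy), so every
stage of the pipeline is testable end to end.

## Worked example

A small synthetic study end to end (15 species, 3 specimens each,
18-point template):

```r
library(pteromorph)

tpl <- landmark_template(
  n_landmarks = 8,
  curves = data.frame(start = c(1, 3), end = c(2, 4),
                      n_semi = c(5, 5), closed = FALSE),
  midline = c(1, 2))

params  <- simulation_params(n_species = 15, n_specimens_per_species = 3)
dataset <- simulate_dataset(params, tpl, seed = 42)

aligned <- dataset$coords |> gpa(template = tpl, slide = TRUE)
glance(aligned)
#>       n     k iterations final_change procrustes_variance
#> 1    45    18         12     9.31e-14           0.0000891
```

GPA converged in 12 iterations; the Procrustes variance (mean squared
distance of the 45 aligned specimens to the mean shape) is 8.9e-5 in
unit-centroid-size shape units. Species means, the morphospace and the
phylogenetic model:

```r
species <- species_means(aligned)
space   <- shape_pca(species)
tidy(space)
#>    axis variance_explained cumulative
#> 1     1              0.358      0.358
#> 2     2              0.214      0.572
#> 3     3              0.138      0.709

cv  <- bm_covariance(dataset$tree, dataset$metadata$species)
dat <- data.frame(diet = factor(dataset$metadata$diet),
                  size = species$log_sizes)
pgls_fit(cbind(species$coords[, , 1], species$coords[, , 2]),
         ~ diet + size, dat, cov = cv, n_perm = 999, seed = 1)
#> <comparative_fit> n = 15, q = 36, 999 permutations, lambda = 1
#>        term df       SS        MS      r2     F     Z        p
#> 1      diet  4 0.016402 0.0041005 0.75475 23.02 6.357 0.001001
#> 2      size  1 0.003726 0.0037264 0.17147 20.92 3.296 0.001001
#> 3 Residuals  9 0.001603 0.0001781 0.07378    NA    NA       NA
#> 4     Total 14 0.021732        NA 1.00000    NA    NA       NA
```

Diet explains 75% and size a further 17% of shape variation in this small
simulated clade, both significant at the permutation resolution
(p = 1/999 ≈ 0.001; at 15 balanced species the generator's diet signal is
much stronger than at the study's 23 usable species). Disparity against
the richness-conditioned null:

```r
disp <- disparity_analysis(species, dataset$metadata,
                           metric = "shape", n_rep = 500, seed = 2)
disp$summary
#>   biome  n_species         D side      p reverse_p low_power
#> 1 I             11 0.0000768 upper 0.743     0.261 FALSE
#> 2 II             7 0.0000871 upper 0.228     0.774 FALSE
#> 3 II/III         2 0.0000631 upper 0.218     0.790 TRUE
#> 4 V              6 0.0000617 lower 0.162     0.840 FALSE
#> 5 VI             3 0.0000504 lower 0.373     0.631 FALSE
#> 6 VIII           5 0.0000794 lower 0.653     0.349 FALSE
```

No biome deviates from its richness-matched expectation (all stated-side
p > 0.05) — the correct answer here, since the generator assigned biome
occupancy independently of shape. `autoplot()` methods draw the
morphospace, the null histograms and the disparity–richness regression;
`run_pipeline(run_config(...))` executes all stages in one call and
`summarize_run()` renders the tables.

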