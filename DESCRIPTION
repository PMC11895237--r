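Package: pteromorph
Title: Geometric Morphometrics of Flying Squirrel Crania Across Diets and Biomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for 2D landmark-based geometric
    morphometrics of flying squirrel (Pteromyini) crania: reading TPS and
    long-format CSV landmark files, bilateral (mirror) expansion of one-sided
    digitizations, Generalised Procrustes Analysis with semilandmarks slid
    under the minimum bending energy criterion, principal component
    morphospaces, Procrustes phylogenetic generalized least squares with
    Pagel's lambda branch rescaling and randomized-residual (RRPP)
    permutation inference, pairwise dispersion comparisons among diet
    categories, and biome-level shape and size disparity tested against a
    richness-conditioned Monte Carlo null. Includes a synthetic-data
    generator that emulates the statistical structure of the museum
    dataset (specimen noise around species means, Brownian-motion species
    means on a phylogeny, additive diet and allometric shape effects) so
    the full analysis is reproducible without specimen access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
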