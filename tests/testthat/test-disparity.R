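md_for <- function(al, biomes) {
  sp <- dimnames(al$coords)[[1]]
  md <- tibble::tibble(species = sp)
  for (b in names(biomes)) {
    md[[b]] <- as.integer(sp %in% biomes[[b]])
  }
  md
}

test_that("disparity of identical shapes is zero and two-point form is exact", {
  k <- 8
  base <- pteromorph:::.center_scale(rand_shape(k, seed = 70))$points
  arr <- array(rep(base, each = 4), c(4, k, 2),
               dimnames = list(paste0("s", 1:4), NULL, NULL))
  al <- pteromorph:::new_aligned_shapes(arr, rep(2.5, 4),
                                        tibble::tibble(specimen = paste0("s", 1:4),
                                                       species = paste0("s", 1:4)))
  md <- md_for(al, list(I = paste0("s", 1:4)))
  rep1 <- biome_disparity(al, md, "I", "shape")
  expect_equal(rep1$D_observed, 0, tolerance = 1e-18)
  expect_equal(rep1$distances$distance, rep(0, 4), tolerance = 1e-9)
  # size disparity of equal sizes is zero
  expect_equal(biome_disparity(al, md, "I", "size")$D_observed, 0)
  # two species: each sits ~d/2 from the midpoint shape, so the
  # sample-variance statistic equals d^2/2 and the mean-square d^2/4
  al2 <- make_aligned(2, k = 10, sd = 0.03, seed = 71)
  md2 <- md_for(al2, list(I = dimnames(al2$coords)[[1]]))
  d12 <- procrustes_distance(al2$coords[1, , ], al2$coords[2, , ])
  D_var <- biome_disparity(al2, md2, "I", "shape",
                           stat = "variance")$D_observed
  expect_equal(D_var, d12^2 / 2, tolerance = 1e-3)
  D_msq <- biome_disparity(al2, md2, "I", "shape")$D_observed
  expect_equal(D_msq, d12^2 / 4, tolerance = 1e-3)
  # fewer than two occupants: flagged undefined
  md1 <- md_for(al2, list(I = dimnames(al2$coords)[[1]][1]))
  expect_true(biome_disparity(al2, md1, "I", "shape")$undefined)
})

test_that("adding a species at the biome mean dilutes disparity", {
  al <- make_aligned(6, k = 9, sd = 0.08, seed = 72)
  sp <- dimnames(al$coords)[[1]]
  md <- md_for(al, list(I = sp[1:5]))
  D5 <- biome_disparity(al, md, "I", "shape", stat = "meansq")$D_observed
  # append a species sitting exactly at the 5-species mean
  mn <- pteromorph:::.center_scale(apply(al$coords[1:5, , ], c(2, 3),
                                         mean))$points
  arr <- array(NA_real_, c(7, 9, 2),
               dimnames = list(c(sp, "mean_sp"), NULL, NULL))
  arr[1:6, , ] <- al$coords
  arr[7, , ] <- mn
  al7 <- pteromorph:::new_aligned_shapes(arr, c(al$centroid_sizes, 1),
                                         tibble::tibble(specimen = c(sp, "mean_sp"),
                                                        species = c(sp, "mean_sp")))
  md7 <- md_for(al7, list(I = c(sp[1:5], "mean_sp")))
  D6 <- biome_disparity(al7, md7, "I", "shape", stat = "meansq")$D_observed
  expect_lt(D6, D5)
})

test_that("disparity is invariant to labeling order and global rotation", {
  al <- make_aligned(8, k = 8, sd = 0.07, seed = 73)
  sp <- dimnames(al$coords)[[1]]
  md <- md_for(al, list(I = sp[c(2, 4, 5, 7)]))
  D1 <- biome_disparity(al, md, "I", "shape")$D_observed
  # permute storage order
  perm <- sample(8)
  al2 <- al
  al2$coords <- al$coords[perm, , ]
  al2$log_sizes <- al$log_sizes[perm]
  al2$centroid_sizes <- al$centroid_sizes[perm]
  dimnames(al2$coords)[[1]] <- sp[perm]
  expect_equal(biome_disparity(al2, md, "I", "shape")$D_observed, D1,
               tolerance = 1e-12)
  # rotate every aligned shape by one global rotation
  al3 <- al
  R <- rot2(0.9)
  for (i in 1:8) al3$coords[i, , ] <- al$coords[i, , ] %*% R
  expect_equal(biome_disparity(al3, md, "I", "shape")$D_observed, D1,
               tolerance = 1e-9)
})

test_that("the across-biome ANOVA behaves at both ends", {
  al <- make_aligned(12, k = 8, sd = 0.08, seed = 74)
  sp <- dimnames(al$coords)[[1]]
  md <- md_for(al, list(I = sp[1:6], V = sp[7:12]))
  reps <- list(biome_disparity(al, md, "I", "shape"),
               biome_disparity(al, md, "V", "shape"))
  av <- disparity_anova(reps)
  expect_true(is.finite(av$F) && av$p > 0 && av$p <= 1)
  # one biome with inflated disparity is detected most of the time
  hits <- vapply(1:50, function(s) {
    set.seed(800 + s)
    big <- matrix(rnorm(12 * 10, 0, 2), 12, 10)
    sml <- matrix(rnorm(12 * 10, 0, 1), 12, 10)
    d_big <- sqrt(rowSums(sweep(big, 2, colMeans(big))^2))
    d_sml <- sqrt(rowSums(sweep(sml, 2, colMeans(sml))^2))
    r1 <- structure(list(biome = "A", undefined = FALSE,
                         distances = tibble::tibble(species = 1:12,
                                                    distance = d_big)),
                    class = "disparity_report")
    r2 <- structure(list(biome = "B", undefined = FALSE,
                         distances = tibble::tibble(species = 1:12,
                                                    distance = d_sml)),
                    class = "disparity_report")
    disparity_anova(list(r1, r2))$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.7)
})

test_that("the richness null is exhaustive at full pool and exact at k = 2", {
  al <- make_aligned(10, k = 8, sd = 0.08, seed = 75)
  # k = pool size: every replicate equals the pool disparity
  ntab <- richness_null(al, "shape", richness_range = 10, n_rep = 20,
                        seed = 1)
  md_all <- md_for(al, list(I = dimnames(al$coords)[[1]]))
  D_all <- biome_disparity(al, md_all, "I", "shape")$D_observed
  expect_equal(ntab$D, rep(D_all, 20), tolerance = 1e-12)
  # k = 2: Monte Carlo mean matches exhaustive pair enumeration
  ntab2 <- richness_null(al, "shape", richness_range = 2, n_rep = 2000,
                         seed = 2)
  sp <- dimnames(al$coords)[[1]]
  prs <- combn(sp, 2)
  Dpairs <- vapply(seq_len(ncol(prs)), function(j) {
    pteromorph:::.disparity_of(al, prs[, j], "shape", "meansq")$D
  }, numeric(1))
  mc_se <- sd(ntab2$D) / sqrt(2000)
  expect_lt(abs(mean(ntab2$D) - mean(Dpairs)), 4 * mc_se + 1e-12)
  # determinism
  expect_identical(richness_null(al, "shape", richness_range = 3:4,
                                 n_rep = 50, seed = 9)$D,
                   richness_null(al, "shape", richness_range = 3:4,
                                 n_rep = 50, seed = 9)$D)
  expect_error(richness_null(al, "shape", richness_range = 11, n_rep = 10),
               "pool")
})

test_that("the richness regression matches the normal equations", {
  al <- make_aligned(12, k = 8, sd = 0.1, seed = 76)
  ntab <- richness_null(al, "shape", richness_range = 2:8, n_rep = 60,
                        seed = 3)
  rr <- richness_regression(ntab)
  x <- ntab$richness; y <- ntab$D
  slope_cf <- (sum(x * y) - length(x) * mean(x) * mean(y)) /
    (sum(x^2) - length(x) * mean(x)^2)
  expect_equal(rr$slope, slope_cf, tolerance = 1e-10)
  expect_equal(rr$intercept, mean(y) - slope_cf * mean(x), tolerance = 1e-10)
  # zero-variance pool: slope exactly 0 and flagged
  base <- pteromorph:::.center_scale(rand_shape(8, seed = 77))$points
  arr <- array(rep(base, each = 6), c(6, 8, 2),
               dimnames = list(paste0("s", 1:6), NULL, NULL))
  alz <- pteromorph:::new_aligned_shapes(arr, rep(1, 6),
                                         tibble::tibble(specimen = paste0("s", 1:6),
                                                        species = paste0("s", 1:6)))
  ntz <- richness_null(alz, "shape", richness_range = 2:4, n_rep = 20,
                       seed = 4)
  rrz <- richness_regression(ntz)
  expect_true(rrz$flagged)
  expect_equal(rrz$slope, 0)
  # expected slope is positive for heterogeneous pools
  signs <- vapply(1:30, function(s) {
    alh <- make_aligned(12, k = 8, sd = 0.1, seed = 1000 + s)
    nt <- richness_null(alh, "shape", richness_range = c(2, 4, 6),
                        n_rep = 30, seed = s)
    richness_regression(nt)$slope > 0
  }, logical(1))
  expect_gte(mean(signs), 0.95)
})

test_that("directional null tests use the add-one convention on both tails", {
  rep0 <- structure(
    list(biome = "I", n_species = 4, D_observed = 99, metric = "shape",
         stat = "variance", undefined = FALSE,
         distances = tibble::tibble(species = 1:4, distance = 1),
         null_distribution = numeric(), p_upper = NA, p_lower = NA,
         side_tested = NA, p_stated = NA, reverse_p = NA),
    class = "disparity_report")
  ntab <- tibble::tibble(richness = 4, rep = 1:1000, D = runif(1000))
  done <- biome_null_test(rep0, ntab, "tropical_higher")
  expect_equal(done$p_upper, 1 / 1001, tolerance = 1e-12) # above all nulls
  expect_equal(done$p_stated, done$p_upper)
  expect_equal(done$reverse_p, done$p_lower)
  expect_gte(done$p_upper + done$p_lower, 1)
  # observed at the null median: both tails near 0.5
  rep_med <- rep0; rep_med$D_observed <- median(ntab$D)
  done2 <- biome_null_test(rep_med, ntab, "temperate_lower")
  expect_equal(done2$p_lower, 0.5, tolerance = 0.01)
  expect_equal(done2$p_upper, 0.5, tolerance = 0.01)
  expect_error(biome_null_test(rep0, tibble::tibble(richness = 9, rep = 1,
                                                    D = 1),
                               "tropical_higher"), "richness")
})

test_that("the full disparity analysis completes with the study's metadata", {
  p <- simulation_params(n_species = 12, n_specimens_per_species = 1)
  d <- simulate_dataset(p, tpl_small(), seed = 78)
  al <- gpa(d$coords)
  sm <- species_means(al)
  da <- disparity_analysis(sm, d$metadata, metric = "shape", n_rep = 100,
                           seed = 5)
  expect_true(all(c("reports", "summary", "anova", "null_table",
                    "regression") %in% names(da)))
  expect_true(all(da$summary$p > 0 & da$summary$p <= 1))
  expect_true(all(da$summary$side %in% c("upper", "lower")))
  trop <- da$summary$side[da$summary$biome %in% c("I", "II", "II/III")]
  expect_true(all(trop == "upper"))
})
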