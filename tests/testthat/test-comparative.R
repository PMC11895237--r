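test_that("BM covariance matches closed forms and a path-intersection oracle", {
  t2 <- ape::read.tree(text = "(a:1,b:1);")
  expect_equal(unname(bm_covariance(t2)$C), diag(2), tolerance = 1e-12)
  t3 <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  C3 <- bm_covariance(t3, c("a", "b", "c"))$C
  expect_equal(C3["a", "b"], 1, tolerance = 1e-12)
  expect_equal(C3["a", "c"], 0, tolerance = 1e-12)
  expect_equal(unname(diag(C3)), rep(2, 3), tolerance = 1e-12)
  # brute force: shared root-to-tip path length for every pair
  tr <- simulate_tree(20, seed = 60)
  C <- bm_covariance(tr)$C
  root <- ape::Ntip(tr) + 1
  edge_len <- function(child) tr$edge.length[tr$edge[, 2] == child]
  path_edges <- function(tip) {
    out <- integer(); node <- tip
    while (node != root) {
      out <- c(out, node)
      node <- tr$edge[tr$edge[, 2] == node, 1]
    }
    out
  }
  paths <- lapply(seq_len(20), path_edges)
  for (i in 1:20) for (j in i:20) {
    shared <- if (i == j) paths[[i]] else intersect(paths[[i]], paths[[j]])
    brute <- sum(vapply(shared, edge_len, numeric(1)))
    expect_equal(C[tr$tip.label[i], tr$tip.label[j]], brute,
                 tolerance = 1e-14)
  }
  expect_error(bm_covariance(tr, c(tr$tip.label[1], "nope")), "missing")
})

test_that("the lambda transform equals the covariance of a rebuilt rescaled tree", {
  tr <- simulate_tree(15, seed = 61)
  cv <- bm_covariance(tr)
  expect_equal(lambda_transform(cv, 1)$C, cv$C, tolerance = 1e-15)
  C0 <- lambda_transform(cv, 0)$C
  expect_equal(unname(C0), diag(diag(cv$C)), tolerance = 1e-15)
  lam <- 0.63
  # oracle: scale every branch by lambda, then stretch each terminal branch
  # to restore the tip depth
  tr2 <- tr
  depths <- ape::node.depth.edgelength(tr)[seq_len(ape::Ntip(tr))]
  tr2$edge.length <- tr$edge.length * lam
  tipe <- match(seq_len(ape::Ntip(tr)), tr$edge[, 2])
  tr2$edge.length[tipe] <- tr2$edge.length[tipe] + (1 - lam) * depths
  C_oracle <- ape::vcv.phylo(tr2)[cv$taxa, cv$taxa]
  expect_equal(lambda_transform(cv, lam)$C, C_oracle, tolerance = 1e-12)
  expect_error(lambda_transform(cv, 1.2), "lambda")
})

test_that("lambda ML estimate maximizes the profile likelihood on a grid", {
  set.seed(62)
  tr <- simulate_tree(25, seed = 62)
  cv <- bm_covariance(tr)
  half <- lambda_transform(cv, 0.5)$C
  R <- t(chol(half)) %*% matrix(rnorm(25 * 6), 25, 6)
  lam <- as.numeric(estimate_lambda(R, cv))
  grid <- seq(0, 1, by = 0.001)
  ll <- vapply(grid, pteromorph:::.lambda_loglik, numeric(1), R = R, cov = cv)
  expect_gte(pteromorph:::.lambda_loglik(lam, R, cv), max(ll) - 1e-6)
  expect_lt(abs(lam - grid[which.max(ll)]), 0.002)
})

test_that("PGLS with a star transform reduces to ordinary Procrustes ANOVA", {
  set.seed(63)
  n <- 16
  tr <- simulate_tree(n, seed = 63)
  cv0 <- lambda_transform(bm_covariance(tr), 0)
  Y <- matrix(rnorm(n * 8), n, 8)
  dat <- data.frame(g = factor(rep(letters[1:4], 4)), z = rnorm(n))
  f_star <- pgls_fit(Y, ~ g + z, dat, cv0, n_perm = 199, seed = 5)
  f_none <- pgls_fit(Y, ~ g + z, dat, NULL, n_perm = 199, seed = 5)
  expect_equal(f_star$anova$SS, f_none$anova$SS, tolerance = 1e-9)
  expect_equal(f_star$anova$F, f_none$anova$F, tolerance = 1e-9)
  expect_equal(f_star$anova$p, f_none$anova$p, tolerance = 1e-12)
})

test_that("the ANOVA table keeps the study's bookkeeping structure", {
  set.seed(64)
  n <- 20
  tr <- simulate_tree(n, seed = 64)
  cv <- bm_covariance(tr)
  Y <- t(chol(cv$C)) %*% matrix(rnorm(n * 10), n, 10)
  dat <- data.frame(diet = factor(rep(c("F1", "F2", "Fr", "Nu", "Ge"), 4)),
                    size = rnorm(n))
  f <- pgls_fit(Y, ~ diet + size, dat, cv, n_perm = 199, seed = 6)
  tab <- tidy(f)
  expect_equal(tab$df[tab$term == "diet"], 4) # 5 diet levels
  expect_equal(tab$df[tab$term == "size"], 1)
  expect_equal(tab$df[tab$term == "Total"], n - 1)
  expect_equal(sum(tab$df[!tab$term %in% "Total"]), n - 1)
  # SS additivity and r2 partition
  model_rows <- !tab$term %in% c("Residuals", "Total")
  expect_equal(sum(tab$SS[model_rows]) + tab$SS[tab$term == "Residuals"],
               tab$SS[tab$term == "Total"], tolerance = 1e-9)
  expect_equal(sum(tab$r2[model_rows]) + tab$r2[tab$term == "Residuals"], 1,
               tolerance = 1e-12)
  expect_true(all(tab$r2 >= 0 & tab$r2 <= 1))
  expect_true(all(tab$p[model_rows] > 0 & tab$p[model_rows] <= 1))
})

test_that("permutation p-values are seed-reproducible and scale-invariant", {
  set.seed(65)
  n <- 15
  Y <- matrix(rnorm(n * 6), n, 6)
  dat <- data.frame(g = factor(rep(letters[1:3], 5)))
  f1 <- pgls_fit(Y, ~ g, dat, NULL, n_perm = 299, seed = 11)
  f2 <- pgls_fit(Y, ~ g, dat, NULL, n_perm = 299, seed = 11)
  expect_identical(f1$anova$p, f2$anova$p)
  f3 <- pgls_fit(Y * 10, ~ g, dat, NULL, n_perm = 299, seed = 11)
  expect_equal(f3$anova$p, f1$anova$p, tolerance = 1e-12)
  expect_equal(f3$anova$F, f1$anova$F, tolerance = 1e-9)
  expect_equal(f3$anova$SS, f1$anova$SS * 100, tolerance = 1e-9)
})

test_that("lambda-rescaled covariance and rebuilt rescaled tree give one fit", {
  set.seed(66)
  n <- 18
  tr <- simulate_tree(n, seed = 66)
  cv <- bm_covariance(tr)
  lam <- 0.4
  tr2 <- tr
  depths <- ape::node.depth.edgelength(tr)[seq_len(n)]
  tr2$edge.length <- tr$edge.length * lam
  tipe <- match(seq_len(n), tr$edge[, 2])
  tr2$edge.length[tipe] <- tr2$edge.length[tipe] + (1 - lam) * depths
  Y <- matrix(rnorm(n * 5), n, 5)
  dat <- data.frame(z = rnorm(n))
  fA <- pgls_fit(Y, ~ z, dat, lambda_transform(cv, lam), n_perm = 99, seed = 2)
  fB <- pgls_fit(Y, ~ z, dat, bm_covariance(tr2), n_perm = 99, seed = 2)
  expect_equal(fA$anova$SS, fB$anova$SS, tolerance = 1e-10)
  expect_equal(fA$anova$F, fB$anova$F, tolerance = 1e-10)
})

test_that("dispersion comparisons detect variance heterogeneity and not phantoms", {
  # identical per-group shape distributions -> d = 0, p = 1
  set.seed(67)
  R <- matrix(rnorm(10 * 6), 10, 6)
  Y <- rbind(R, R)
  g <- factor(rep(c("a", "b"), each = 10))
  pw <- pairwise_dispersion(Y, g, n_perm = 199, seed = 3)
  expect_equal(pw$d, 0, tolerance = 1e-12)
  expect_equal(pw$p, 1, tolerance = 1e-12)
  # structure: all unordered pairs, non-negative d
  Y3 <- matrix(rnorm(30 * 4), 30, 4)
  g3 <- factor(rep(c("a", "b", "c"), each = 10))
  pw3 <- pairwise_dispersion(Y3, g3, n_perm = 99, seed = 4)
  expect_equal(nrow(pw3), 3)
  expect_true(all(pw3$d >= 0))
  # singleton groups are dropped with a warning
  g4 <- factor(c(rep("a", 10), rep("b", 19), "c"))
  expect_warning(pairwise_dispersion(Y3, g4, n_perm = 99, seed = 5),
                 "singleton")
  # power: 4:1 variance ratio, n = 15 per group
  hits <- vapply(1:50, function(s) {
    set.seed(900 + s)
    Ya <- matrix(rnorm(15 * 8, 0, 2), 15, 8)
    Yb <- matrix(rnorm(15 * 8, 0, 1), 15, 8)
    pw <- pairwise_dispersion(rbind(Ya, Yb),
                              factor(rep(c("a", "b"), each = 15)),
                              n_perm = 199, seed = s)
    pw$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("allometry scores track size when allometry exists and flag when not", {
  tpl <- tpl_curves()
  p <- simulation_params(n_species = 20, n_specimens_per_species = 1,
                         specimen_noise_sd = 0, sigma_bm = 0.002)
  d <- simulate_dataset(p, tpl, seed = 68)
  cv <- bm_covariance(d$tree, d$metadata$species)
  sc <- allometry_scores(d$true_values$species_means,
                         d$true_values$log_sizes, cv)
  expect_gte(abs(cor(sc$score, sc$log_size)), 0.7)
  # adding a constant to all log sizes leaves the scores unchanged
  sc2 <- allometry_scores(d$true_values$species_means,
                          d$true_values$log_sizes + 5, cv)
  expect_equal(sc2$score, sc$score, tolerance = 1e-8)
  # no allometry, no noise: zero regression vector is flagged
  p0 <- simulation_params(
    n_species = 8, n_specimens_per_species = 1, allometry_slope = 0,
    sigma_bm = 0, specimen_noise_sd = 0,
    diet_effects = c(Folivore_1 = 0, Folivore_2 = 0, Frugivore = 0,
                     Nucivore = 0, Generalist = 0, NoInfo = 0))
  d0 <- simulate_dataset(p0, tpl, seed = 69)
  sc0 <- allometry_scores(d0$true_values$species_means,
                          d0$true_values$log_sizes, NULL)
  expect_true(attr(sc0, "flagged"))
  expect_equal(sc0$score, rep(0, 8))
})

test_that("diet effects of the generated magnitude are detected by PGLS", {
  tpl <- tpl_curves()
  hits <- vapply(1:50, function(s) {
    p <- simulation_params(n_species = 30, n_specimens_per_species = 1)
    d <- simulate_dataset(p, tpl, seed = 200 + s)
    cv <- bm_covariance(d$tree, d$metadata$species)
    f <- pgls_fit(d$true_values$species_means, ~ diet + size,
                  data.frame(diet = factor(d$metadata$diet),
                             size = d$true_values$log_sizes),
                  cv, n_perm = 199, seed = s)
    f$anova$p[1] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
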