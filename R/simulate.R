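#' Simulate an ultrametric phylogeny
#'
#' Either a stochastic pure-birth tree or a deterministic (seed-free)
#' cluster-shaped tree; in both cases binary, ultrametric, with positive
#' branch lengths and total depth normalized to 1.
#'
#' @param n_species Number of tips (>= 2).
#' @param mode `"pure_birth"` (Yule process) or `"fixed"` (deterministic
#'   average-linkage topology, useful for exactly reproducible geometry).
#' @param seed Optional integer seed (pure-birth mode).
#' @param tip_labels Optional tip names (default `sp01`, `sp02`, ...).
#' @return An `ape::phylo` tree.
#' @export
simulate_tree <- function(n_species, mode = c("pure_birth", "fixed"),
                          seed = NULL, tip_labels = NULL) {
  mode <- match.arg(mode)
  if (n_species < 2) stop("need at least 2 species", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "pure_birth") {
    tree <- ape::rphylo(n_species, birth = 1, death = 0)
  } else {
    hc <- stats::hclust(stats::dist(seq_len(n_species)^1.3),
                        method = "average")
    tree <- ape::as.phylo(hc)
  }
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- tip_labels %||%
    sprintf("sp%02d", seq_len(n_species))
  tree
}

#' Parameters of the synthetic cranial dataset
#'
#' The generator's defaults are the study conditions: the species list,
#' per-species specimen counts, diet categories and biome occupancy come
#' from the sampled Pteromyini table ([pteromyini_species()]), species mean
#' shapes evolve by Brownian motion (with signal `lambda_true`) on a
#' pure-birth tree of depth 1, diet adds a category-specific displacement
#' along a random orthonormal direction, log centroid size is drawn per
#' diet and displaces shape along an orthogonal allometric direction, and
#' specimens scatter around their species mean with iid Gaussian
#' coordinate noise before being arbitrarily rotated, translated and
#' scaled (which GPA must undo). All species-level effect vectors are kept
#' normal to the semilandmark curves: along-curve position is a
#' digitization artifact that sliding removes, so no signal is placed
#' there; specimen noise stays isotropic.
#'
#' @param metadata Species table (`species, n_specimens, diet`, biome
#'   flags); `NULL` builds a balanced synthetic table from `n_species`.
#' @param n_species,n_specimens_per_species Used only when
#'   `metadata = NULL`.
#' @param biome_richness Named biome -> species-count map used only when
#'   `metadata = NULL`.
#' @param tree_mode Passed to [simulate_tree()].
#' @param sigma_bm Root expected squared norm (summed over all coordinates)
#'   of the Brownian shape deviation accumulated over unit tree depth,
#'   in unit-centroid-size shape units.
#' @param lambda_true Phylogenetic signal in `[0, 1]` used to transform the
#'   tree covariance before drawing Brownian deviations.
#' @param diet_effects Named diet -> displacement magnitude (shape units).
#' @param allometry_slope Shape displacement per unit log centroid size.
#' @param size_by_diet Data frame `diet, mean, sd` of log centroid size
#'   (natural log of size in mm).
#' @param specimen_noise_sd Per-coordinate specimen noise sd (shape units).
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(metadata = NULL, n_species = NULL,
                              n_specimens_per_species = 5,
                              biome_richness = NULL,
                              tree_mode = "pure_birth",
                              sigma_bm = 0.008, lambda_true = 1,
                              diet_effects = c(
                                Folivore_1 = 0.0043, Folivore_2 = 0.0058,
                                Frugivore = 0.0043, Nucivore = 0.0043,
                                Generalist = 0.0043, NoInfo = 0),
                              allometry_slope = 0.010,
                              size_by_diet = NULL,
                              specimen_noise_sd = 5e-4) {
  stopifnot(lambda_true >= 0, lambda_true <= 1, sigma_bm >= 0,
            specimen_noise_sd >= 0)
  if (is.null(size_by_diet)) {
    size_by_diet <- tibble::tibble(
      diet = c("Folivore_1", "Folivore_2", "Frugivore", "Nucivore",
               "Generalist", "NoInfo"),
      mean = c(5.05, 5.12, 4.92, 4.95, 5.05, 5.0),
      sd = c(0.3, 0.3, 0.3, 0.45, 0.35, 0.35)
    )
  }
  if (is.null(metadata)) {
    if (is.null(n_species)) {
      metadata <- pteromyini_species()
    } else {
      metadata <- .balanced_metadata(n_species, n_specimens_per_species,
                                     biome_richness)
    }
  }
  if (any(!is.na(metadata$diet) &
          !(as.character(metadata$diet) %in% names(diet_effects)))) {
    stop("diet_effects must name every diet category in the metadata",
         call. = FALSE)
  }
  structure(
    list(metadata = metadata, tree_mode = tree_mode, sigma_bm = sigma_bm,
         lambda_true = lambda_true, diet_effects = diet_effects,
         allometry_slope = allometry_slope, size_by_diet = size_by_diet,
         specimen_noise_sd = specimen_noise_sd),
    class = "simulation_params"
  )
}

# projector removing, at every semilandmark, the displacement component
# along the local curve tangent of the reference shape; operates on
# flattened (x1..xk, y1..yk) columns-are-vectors matrices
.tangent_projector <- function(template, base) {
  nb <- template$neighbors
  k <- nrow(base)
  if (!nrow(nb)) return(function(M) M)
  tg <- base[nb$nxt, , drop = FALSE] - base[nb$prev, , drop = FALSE]
  tg <- tg / pmax(sqrt(rowSums(tg^2)), 1e-12)
  s <- nb$point
  function(M) {
    vx <- M[s, , drop = FALSE]
    vy <- M[k + s, , drop = FALSE]
    along <- vx * tg[, 1] + vy * tg[, 2]
    M[s, ] <- vx - along * tg[, 1]
    M[k + s, ] <- vy - along * tg[, 2]
    M
  }
}

# balanced diets and a tropicality-graded occupancy matrix
.balanced_metadata <- function(n_species, n_spec, biome_richness = NULL) {
  diets <- c("Folivore_1", "Folivore_2", "Frugivore", "Nucivore",
             "Generalist")
  md <- tibble::tibble(
    species = sprintf("sp%02d", seq_len(n_species)),
    n_specimens = rep_len(n_spec, n_species),
    diet = rep_len(diets, n_species)
  )
  if (is.null(biome_richness)) {
    # richness gradient proportional to the observed table (26..2 over 6 biomes)
    biome_richness <- round(stats::setNames(
      pmax(2, n_species * c(0.74, 0.49, 0.06, 0.40, 0.23, 0.31)),
      c("I", "II", "II/III", "V", "VI", "VIII")))
  }
  if (any(biome_richness > n_species)) {
    stop("biome richness cannot exceed n_species", call. = FALSE)
  }
  # latent tropicality: tropical biomes take the top of the ranking,
  # temperate ones a window shifted toward the bottom; windows overlap
  b <- length(biome_richness)
  for (j in seq_len(b)) {
    r <- biome_richness[j]
    off <- round((j - 1) * (n_species - r) / max(1, b - 1))
    occ <- integer(n_species)
    occ[off + seq_len(r)] <- 1L
    md[[names(biome_richness)[j]]] <- occ
  }
  md
}

#' Simulate a full landmark dataset
#'
#' Draws a phylogeny, species mean shapes, per-diet log centroid sizes and
#' individual specimens according to `params` (see [simulation_params()]),
#' then disguises every specimen with an arbitrary rotation
#' (uniform on the circle), translation (uniform in +-10) and scale
#' (log-normal, sd 0.2) so that superimposition has real work to do.
#'
#' @param params A [simulation_params()] object.
#' @param template A one-sided [landmark_template()]; the grand mean shape
#'   is [template_base_shape()] scaled to unit centroid size.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A list: `coords` (long landmark tibble of raw specimens),
#'   `metadata`, `tree`, and `true_values` (every generating quantity:
#'   species mean shapes, log sizes, effect directions and magnitudes,
#'   Brownian deviations, and the realized diet/size r2 computed on the
#'   noiseless species means).
#' @export
simulate_dataset <- function(params, template = pteromyini_template(),
                             seed = 1) {
  stopifnot(inherits(params, "simulation_params"),
            inherits(template, "landmark_template"))
  set.seed(seed)
  md <- params$metadata
  n <- nrow(md)
  tree <- simulate_tree(n, params$tree_mode, seed = NULL,
                        tip_labels = md$species)
  base <- .center_scale(template_base_shape(template))$points
  k <- nrow(base)
  q <- 2 * k
  m0 <- c(base[, 1], base[, 2])
  # species-level effects act normal to the semilandmark curves: the
  # along-curve position of a semilandmark is a digitization artifact that
  # sliding is entitled to remove, so no biological signal is placed there
  proj <- .tangent_projector(template, base)
  # orthonormal effect directions: one per diet category plus allometry
  diets <- names(params$diet_effects)
  raw <- proj(matrix(stats::rnorm(q * (length(diets) + 1)), q))
  U <- qr.Q(qr(raw))
  dirs <- U[, seq_along(diets), drop = FALSE]
  colnames(dirs) <- diets
  v_allo <- U[, length(diets) + 1]
  # per-species log centroid size
  sbd <- params$size_by_diet
  idx <- match(as.character(md$diet), sbd$diet)
  log_sizes <- stats::rnorm(n, sbd$mean[idx], sbd$sd[idx])
  # Brownian deviations on the lambda-transformed tree
  cv <- lambda_transform(bm_covariance(tree, md$species), params$lambda_true)
  L <- chol(cv$C)
  dev <- t(L) %*% matrix(stats::rnorm(n * q), n, q) *
    (params$sigma_bm / sqrt(q))
  # remove tangential components, rescaling so sigma_bm keeps its meaning
  # as the root expected squared norm of the deviation
  n_semi <- nrow(template$neighbors)
  dev <- t(proj(t(dev))) * sqrt(q / (q - n_semi))
  mags <- params$diet_effects[as.character(md$diet)]
  means <- matrix(m0, n, q, byrow = TRUE) +
    t(dirs[, as.character(md$diet), drop = FALSE]) * mags +
    outer(params$allometry_slope * (log_sizes - mean(log_sizes)), v_allo) +
    dev
  # realized effect sizes on the noiseless species means (sequential SS);
  # undefined when the design cannot be fitted (too few species per level)
  fit0 <- tryCatch(
    pgls_fit(means, ~ diet + size,
             data = data.frame(diet = factor(md$diet), size = log_sizes),
             cov = NULL, n_perm = 99, seed = 1),
    error = function(e) NULL)
  coords <- vector("list", n)
  for (i in seq_len(n)) {
    ni <- md$n_specimens[i]
    mu <- .unflatten_shape(means[i, ])
    sp <- vector("list", ni)
    for (j in seq_len(ni)) {
      pts <- mu + matrix(stats::rnorm(q, 0, params$specimen_noise_sd), k, 2)
      pts <- .center_scale(pts)$points
      cs_true <- exp(log_sizes[i] + stats::rnorm(1, 0, 0.2))
      th <- stats::runif(1, 0, 2 * pi)
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      pts <- pts %*% R * cs_true
      pts <- sweep(pts, 2, stats::runif(2, -10, 10), `+`)
      sp[[j]] <- tibble::tibble(
        specimen = sprintf("%s_%d", gsub(" ", "_", md$species[i]), j),
        species = md$species[i], side = "left", point = seq_len(k),
        x = pts[, 1], y = pts[, 2]
      )
    }
    coords[[i]] <- dplyr::bind_rows(sp)
  }
  list(
    coords = dplyr::bind_rows(coords),
    metadata = md,
    tree = tree,
    true_values = list(
      mean_shape = base, species_means = means, log_sizes = log_sizes,
      diet_directions = dirs, diet_magnitudes = params$diet_effects,
      allometry_direction = v_allo,
      allometry_slope = params$allometry_slope,
      bm_deviations = dev, lambda_true = params$lambda_true,
      generating_r2 = if (is.null(fit0)) {
        c(diet = NA_real_, size = NA_real_)
      } else {
        stats::setNames(fit0$anova$r2[1:2], fit0$anova$term[1:2])
      }
    ),
    params = params, seed = seed
  )
}

#' Write a simulated dataset to standard interchange files
#'
#' @param dataset Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @param format `"tps"` or `"csv"` for the landmark file.
#' @return Named vector of written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir, format = c("csv", "tps")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lm_path <- file.path(dir, paste0("landmarks.", format))
  write_landmarks(dataset$coords, lm_path, format)
  md_path <- file.path(dir, "species_metadata.csv")
  readr::write_csv(dataset$metadata, md_path)
  tr_path <- file.path(dir, "tree.nwk")
  ape::write.tree(dataset$tree, tr_path)
  invisible(c(landmarks = lm_path, metadata = md_path, tree = tr_path))
}
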