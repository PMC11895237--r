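#' Shape or size disparity of the species occupying one biome
#'
#' Shape disparity is built from the Procrustes distance of every occupant
#' species to the biome mean shape (the arithmetic mean of the occupants'
#' aligned shapes, re-standardized to unit centroid size). Size disparity
#' uses the absolute deviation of log centroid size from the biome mean.
#' The headline statistic `D` is, by default, the mean squared distance —
#' the Foote-style Procrustes variance for shape. The `"variance"` option
#' divides the summed squared distances by `n - 1` instead (for size this
#' is exactly `var(log size)`); being unbiased, its expectation does not
#' grow with richness, so the mean-square default is the one that
#' reproduces the increasing disparity-richness null curve.
#'
#' @param aligned Species-level `aligned_shapes` (see [species_means()]).
#' @param metadata Species metadata with biome occupancy flags.
#' @param biome Biome column name (e.g. `"I"`).
#' @param metric `"shape"` or `"size"`.
#' @param stat Disparity statistic: `"meansq"` (mean d^2, default),
#'   `"variance"` (sum d^2 / (n-1)) or `"mean"` (mean distance).
#' @return A `disparity_report`: `biome`, `n_species`, per-species
#'   `distances` tibble, `D_observed`, and (until [biome_null_test()]
#'   completes it) empty null fields. Biomes with < 2 occupants are
#'   flagged undefined.
#' @export
biome_disparity <- function(aligned, metadata, biome,
                            metric = c("shape", "size"),
                            stat = c("meansq", "variance", "mean")) {
  metric <- match.arg(metric)
  stat <- match.arg(stat)
  stopifnot(inherits(aligned, "aligned_shapes"), biome %in% names(metadata))
  occ <- metadata$species[metadata[[biome]] > 0]
  occ <- intersect(dimnames(aligned$coords)[[1]], occ)
  res <- .disparity_of(aligned, occ, metric, stat)
  structure(
    list(biome = biome, n_species = length(occ),
         distances = tibble::tibble(species = occ, distance = res$distances),
         D_observed = res$D, metric = metric, stat = stat,
         undefined = length(occ) < 2,
         null_distribution = numeric(), p_upper = NA_real_,
         p_lower = NA_real_, side_tested = NA_character_,
         p_stated = NA_real_, reverse_p = NA_real_),
    class = "disparity_report"
  )
}

# disparity of a species subset; shared by observed reports and null draws
.disparity_of <- function(aligned, species, metric, stat) {
  n <- length(species)
  if (n < 2) {
    return(list(distances = rep(NA_real_, n), D = NA_real_))
  }
  if (metric == "shape") {
    idx <- match(species, dimnames(aligned$coords)[[1]])
    sub <- aligned$coords[idx, , , drop = FALSE]
    mn <- .center_scale(apply(sub, c(2, 3), mean))$points
    d <- vapply(seq_len(n), function(i) {
      optimal_superposition(mn, sub[i, , ])$distance
    }, numeric(1))
  } else {
    ls <- aligned$log_sizes[match(species, dimnames(aligned$coords)[[1]])]
    d <- abs(ls - mean(ls))
  }
  D <- switch(stat,
              variance = sum(d^2) / (n - 1),
              meansq = mean(d^2),
              mean = mean(d))
  list(distances = d, D = D)
}

#' @export
print.disparity_report <- function(x, ...) {
  cat(sprintf("<disparity_report> biome %s: n = %d, %s D = %s%s\n",
              x$biome, x$n_species, x$metric,
              format(x$D_observed, digits = 4),
              if (x$undefined) " [undefined: < 2 occupants]" else ""))
  if (!is.na(x$p_stated)) {
    cat(sprintf("  %s-tail p = %.4g (reverse %.4g), null n = %d\n",
                x$side_tested, x$p_stated, x$reverse_p,
                length(x$null_distribution)))
  }
  invisible(x)
}

#' One-way ANOVA of per-species disparity distances across biomes
#'
#' Species occupying several biomes contribute one observation per biome
#' (matching the per-biome dot plots the distances feed).
#'
#' @param reports A list of `disparity_report`s (same metric).
#' @return A tibble with `F`, `p`, and the degrees of freedom; `F` is
#'   flagged `NA` when all distances are identical.
#' @export
disparity_anova <- function(reports) {
  dd <- dplyr::bind_rows(lapply(reports, function(r) {
    if (r$undefined) return(NULL)
    tibble::tibble(biome = r$biome, distance = r$distances$distance)
  }))
  if (length(unique(dd$biome)) < 2) {
    stop("need at least 2 biomes with >= 2 species", call. = FALSE)
  }
  if (stats::sd(dd$distance) == 0) {
    return(tibble::tibble(F = NA_real_, p = NA_real_,
                          df_between = NA_integer_, df_within = NA_integer_))
  }
  av <- summary(stats::aov(distance ~ biome, data = dd))[[1]]
  tibble::tibble(F = av$`F value`[1], p = av$`Pr(>F)`[1],
                 df_between = av$Df[1], df_within = av$Df[2])
}

#' Richness-conditioned Monte Carlo null for disparity
#'
#' For every richness `k` in `richness_range`, draws `n_rep` random
#' subsets of `k` species (uniform, without replacement) from the full
#' species pool and records the disparity of each draw — the expected
#' disparity distribution at that richness under random biome assembly.
#'
#' @param aligned Species-level `aligned_shapes` (the species pool).
#' @param metric,stat As in [biome_disparity()].
#' @param richness_range Integer vector of richness values (each between 2
#'   and the pool size).
#' @param n_rep Replicates per richness value.
#' @param seed Optional integer seed.
#' @return A tibble `richness, rep, D` of class `richness_null`.
#' @export
richness_null <- function(aligned, metric = c("shape", "size"),
                          stat = c("meansq", "variance", "mean"),
                          richness_range = NULL, n_rep = 1000, seed = NULL) {
  metric <- match.arg(metric)
  stat <- match.arg(stat)
  stopifnot(inherits(aligned, "aligned_shapes"))
  pool <- dimnames(aligned$coords)[[1]]
  if (is.null(richness_range)) richness_range <- 2:length(pool)
  if (any(richness_range < 2) || any(richness_range > length(pool))) {
    stop("richness values must lie in [2, pool size]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(richness_range, function(k) {
    D <- vapply(seq_len(n_rep), function(r) {
      .disparity_of(aligned, sample(pool, k), metric, stat)$D
    }, numeric(1))
    tibble::tibble(richness = k, rep = seq_len(n_rep), D = D)
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("richness_null", class(res))
  attr(res, "metric") <- metric
  attr(res, "stat") <- stat
  res
}

#' Regression of null disparity on species richness
#'
#' Ordinary least squares of the Monte Carlo replicate disparities on
#' richness — the expected disparity-richness curve against which observed
#' biomes are plotted.
#'
#' @param null_table A `richness_null` tibble spanning >= 3 richness
#'   values.
#' @return A list: `slope`, `intercept`, the `lm` fit, a per-richness
#'   `null_means` tibble, and `flagged` (TRUE when disparity is constant,
#'   giving a zero slope).
#' @export
richness_regression <- function(null_table) {
  if (length(unique(null_table$richness)) < 3) {
    stop("null table must span at least 3 richness values", call. = FALSE)
  }
  # constant disparity, including the all-identical-shapes case where the
  # replicate values are pure floating-point noise
  flagged <- stats::sd(null_table$D) == 0 ||
    max(abs(null_table$D)) < 1e-12
  fit <- stats::lm(D ~ richness, data = null_table)
  means <- dplyr::summarise(dplyr::group_by(null_table, .data$richness),
                            D_mean = mean(.data$D), .groups = "drop")
  list(slope = if (flagged) 0 else unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       fit = fit, null_means = means, flagged = flagged)
}

#' Test an observed biome disparity against its richness-matched null
#'
#' One-sided Monte Carlo test at the biome's exact richness, with the
#' direction set by the biogeographic hypothesis: tropical biomes are
#' tested for disparity *higher* than expected, temperate/boreal biomes
#' for *lower*. p-values use the add-one convention
#' `(count at least as extreme + 1) / (n_rep + 1)`; the reverse-direction
#' p is also reported, and significance corresponds to the observed value
#' lying outside the one-sided 95% bound of the null.
#'
#' @param report A `disparity_report` from [biome_disparity()].
#' @param null_table A `richness_null` containing the report's richness.
#' @param hypothesis `"tropical_higher"` (upper tail is the stated side)
#'   or `"temperate_lower"` (lower tail).
#' @return The completed `disparity_report` (null distribution, `p_upper`,
#'   `p_lower`, stated-side p and reverse p filled in).
#' @export
biome_null_test <- function(report, null_table,
                            hypothesis = c("tropical_higher",
                                           "temperate_lower")) {
  hypothesis <- match.arg(hypothesis)
  stopifnot(inherits(report, "disparity_report"))
  if (report$undefined) {
    warning("disparity undefined for biome ", report$biome)
    return(report)
  }
  nd <- null_table$D[null_table$richness == report$n_species]
  if (!length(nd)) {
    stop("null table lacks richness ", report$n_species, call. = FALSE)
  }
  nr <- length(nd)
  p_up <- (sum(nd >= report$D_observed) + 1) / (nr + 1)
  p_lo <- (sum(nd <= report$D_observed) + 1) / (nr + 1)
  report$null_distribution <- nd
  report$p_upper <- p_up
  report$p_lower <- p_lo
  report$side_tested <- if (hypothesis == "tropical_higher") "upper" else "lower"
  report$p_stated <- if (report$side_tested == "upper") p_up else p_lo
  report$reverse_p <- if (report$side_tested == "upper") p_lo else p_up
  report
}

#' Run the full biome disparity analysis
#'
#' Observed disparity per biome, the across-biome ANOVA, the richness-
#' conditioned null, the richness regression, and the directional null
#' tests (tropical biomes I, II and savanna II/III tested for higher than
#' expected disparity; temperate/boreal V, VI, VIII for lower).
#'
#' @param aligned Species-level `aligned_shapes`.
#' @param metadata Metadata with biome occupancy flags.
#' @param metric,stat As in [biome_disparity()].
#' @param n_rep Null replicates per richness.
#' @param seed Optional integer seed.
#' @return A list: `reports` (completed, one per biome with >= 2
#'   occupants), `summary` tibble (biome, N, D, stated-side p, reverse p),
#'   `anova`, `null_table`, `regression`.
#' @export
disparity_analysis <- function(aligned, metadata,
                               metric = c("shape", "size"),
                               stat = c("meansq", "variance", "mean"),
                               n_rep = 1000, seed = NULL) {
  metric <- match.arg(metric)
  stat <- match.arg(stat)
  biomes <- biome_labels(metadata)
  reports <- lapply(biomes, function(b)
    biome_disparity(aligned, metadata, b, metric, stat))
  names(reports) <- biomes
  reports <- Filter(function(r) !r$undefined || r$n_species >= 2, reports)
  defined <- Filter(function(r) !r$undefined, reports)
  richness <- sort(unique(vapply(defined, `[[`, 0L, "n_species")))
  nt <- richness_null(aligned, metric, stat,
                      richness_range = 2:max(richness), n_rep = n_rep,
                      seed = seed)
  tropical <- c("I", "II", "II/III")
  completed <- lapply(defined, function(r) {
    biome_null_test(r, nt, if (r$biome %in% tropical) "tropical_higher"
                    else "temperate_lower")
  })
  summary <- dplyr::bind_rows(lapply(completed, function(r) {
    tibble::tibble(biome = r$biome, n_species = r$n_species,
                   D = r$D_observed, side = r$side_tested,
                   p = r$p_stated, reverse_p = r$reverse_p,
                   low_power = r$n_species < 3)
  }))
  list(reports = completed, summary = summary,
       anova = disparity_anova(completed), null_table = nt,
       regression = richness_regression(nt), metric = metric, stat = stat)
}
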