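#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an aligned set into a long coordinate tibble
#'
#' @param x An `aligned_shapes` object.
#' @param ... Unused.
#' @return Long tibble `specimen, species, point, x, y, centroid_size,
#'   log_size`.
#' @export
tidy.aligned_shapes <- function(x, ...) {
  info <- x$info
  info$centroid_size <- x$centroid_sizes
  info$log_size <- x$log_sizes
  array_to_coords(x$coords, info = info)
}

#' @rdname tidy.aligned_shapes
#' @export
glance.aligned_shapes <- function(x, ...) {
  tibble::tibble(
    n = dim(x$coords)[1], k = dim(x$coords)[2],
    iterations = x$iterations, final_change = x$final_change,
    procrustes_variance = procrustes_variance(x)
  )
}

#' Tidy a comparative fit into its ANOVA table
#'
#' @param x A `comparative_fit`.
#' @param ... Unused.
#' @return The ANOVA tibble (`term, df, SS, MS, r2, F, Z, p`).
#' @export
tidy.comparative_fit <- function(x, ...) x$anova

#' @rdname tidy.comparative_fit
#' @export
glance.comparative_fit <- function(x, ...) {
  model_rows <- !(x$anova$term %in% c("Residuals", "Total"))
  tibble::tibble(
    n = x$n, q = x$q, n_perm = x$n_perm, lambda = x$lambda,
    r2_model = sum(x$anova$r2[model_rows]),
    flagged = x$flagged
  )
}

#' Per-axis variance table of a morphospace
#'
#' @param x A `morphospace`.
#' @param ... Unused.
#' @return Tibble `axis, variance_explained, cumulative`.
#' @export
tidy.morphospace <- function(x, ...) {
  tibble::tibble(
    axis = seq_along(x$variance_explained),
    variance_explained = x$variance_explained,
    cumulative = cumsum(x$variance_explained)
  )
}

#' @rdname tidy.morphospace
#' @export
glance.morphospace <- function(x, ...) {
  tibble::tibble(n = nrow(x$scores), n_axes = ncol(x$scores),
                 total_variance = sum(apply(x$scores, 2, stats::var)))
}

#' Morphospace scores with specimen metadata
#'
#' @param space A `morphospace`.
#' @param axes Axis indices to keep.
#' @return Tibble with `specimen`, `species`, `log_size` and one `PCi`
#'   column per requested axis.
#' @export
pc_scores <- function(space, axes = seq_len(min(3, ncol(space$scores)))) {
  stopifnot(inherits(space, "morphospace"))
  out <- tibble::tibble(specimen = space$labels,
                        species = space$info$species,
                        log_size = space$log_sizes)
  for (a in axes) out[[paste0("PC", a)]] <- space$scores[, a]
  out
}

#' Per-species distances of a disparity report
#'
#' @param x A `disparity_report`.
#' @param ... Unused.
#' @return Tibble `biome, species, distance`.
#' @export
tidy.disparity_report <- function(x, ...) {
  dplyr::mutate(x$distances, biome = x$biome, .before = 1)
}

#' @rdname tidy.disparity_report
#' @export
glance.disparity_report <- function(x, ...) {
  tibble::tibble(
    biome = x$biome, n_species = x$n_species, D = x$D_observed,
    metric = x$metric, stat = x$stat, side = x$side_tested,
    p = x$p_stated, reverse_p = x$reverse_p,
    undefined = x$undefined
  )
}
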