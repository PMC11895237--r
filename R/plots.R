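#' Morphospace scatter plot
#'
#' PCA scatter with points scaled by centroid size and coloured by a
#' grouping variable (typically diet), mirroring the usual morphospace
#' figure.
#'
#' @param object A `morphospace`.
#' @param axes Two axis indices.
#' @param colour_by Optional tibble `species, <group>` (first non-species
#'   column used for colour), e.g. the metadata's species/diet columns.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.morphospace <- function(object, axes = c(1, 2), colour_by = NULL,
                                 ...) {
  df <- pc_scores(object, axes)
  xv <- paste0("PC", axes[1]); yv <- paste0("PC", axes[2])
  if (!is.null(colour_by)) {
    gv <- setdiff(names(colour_by), "species")[1]
    df <- dplyr::left_join(df, colour_by[, c("species", gv)], by = "species")
  } else gv <- NULL
  ve <- 100 * object$variance_explained[axes]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data[[xv]], .data[[yv]])) +
    ggplot2::geom_point(ggplot2::aes(
      size = exp(.data$log_size),
      colour = if (is.null(gv)) NULL else .data[[gv]])) +
    ggplot2::labs(
      x = sprintf("%s (%.2f%%)", xv, ve[1]),
      y = sprintf("%s (%.2f%%)", yv, ve[2]),
      size = "centroid size", colour = gv) +
    ggplot2::theme_minimal()
  p
}

#' Null histogram for a completed disparity report
#'
#' Histogram of the richness-matched null disparity with the one-sided 95%
#' bound (solid) and the observed disparity (dashed).
#'
#' @param object A completed `disparity_report` (see [biome_null_test()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.disparity_report <- function(object, ...) {
  if (!length(object$null_distribution)) {
    stop("report has no null distribution; run biome_null_test() first",
         call. = FALSE)
  }
  nd <- tibble::tibble(D = object$null_distribution)
  bound <- stats::quantile(
    nd$D, if (object$side_tested == "upper") 0.95 else 0.05)
  ggplot2::ggplot(nd, ggplot2::aes(.data$D)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = bound, linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = object$D_observed, linetype = 2) +
    ggplot2::labs(
      title = sprintf("Biome %s (N = %d): %s-tail p = %.3g",
                      object$biome, object$n_species, object$side_tested,
                      object$p_stated),
      x = sprintf("%s disparity", object$metric), y = "null frequency") +
    ggplot2::theme_minimal()
}

#' Disparity-richness regression plot
#'
#' Null replicates against richness with the fitted expectation line;
#' observed biomes can be overlaid.
#'
#' @param object A `richness_null` table.
#' @param observed Optional tibble `biome, n_species, D` (e.g. the
#'   `summary` element of [disparity_analysis()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.richness_null <- function(object, observed = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$richness, .data$D)) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.1, size = 0.4) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black") +
    ggplot2::labs(x = "species richness",
                  y = sprintf("%s disparity", attr(object, "metric"))) +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_point(
      data = observed,
      ggplot2::aes(.data$n_species, .data$D, colour = .data$biome),
      size = 3, inherit.aes = FALSE)
  }
  p
}

#' Allometry scatter plot
#'
#' PGLS regression scores against log centroid size, coloured by diet.
#'
#' @param scores Tibble from [allometry_scores()] (a `diet` column, if
#'   present, is used for colour).
#' @return A ggplot.
#' @export
plot_allometry <- function(scores) {
  has_diet <- "diet" %in% names(scores)
  ggplot2::ggplot(scores, ggplot2::aes(.data$log_size, .data$score)) +
    ggplot2::geom_point(if (has_diet) ggplot2::aes(colour = .data$diet)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40", linewidth = 0.5) +
    ggplot2::labs(x = "log centroid size", y = "shape regression score") +
    ggplot2::theme_minimal()
}
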