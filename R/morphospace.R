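#' Principal component morphospace of aligned shapes
#'
#' Eigen-decomposition of the covariance of the flattened aligned
#' coordinates about their sample mean. Axes are orthonormal, ordered by
#' decreasing variance, and deterministically oriented so each axis's
#' largest-magnitude loading is positive.
#'
#' @param aligned An `aligned_shapes` object (n >= 3 shapes); species means
#'   for the species-level morphospace, or specimen-level data.
#' @return A `morphospace` object with `scores` (n x p, zero column means),
#'   `variance_explained` (sums to 1 over the non-null axes), orthonormal
#'   `axes` (p x 2k loadings), `mean_shape` and the point count `k`.
#' @export
shape_pca <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_shapes"))
  X <- .flatten_shapes(aligned$coords)
  n <- nrow(X)
  if (n < 3) stop("PCA needs at least 3 shapes", call. = FALSE)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  pc <- stats::prcomp(Xc, center = FALSE, scale. = FALSE)
  keep <- pc$sdev^2 > max(pc$sdev^2) * 1e-12
  scores <- pc$x[, keep, drop = FALSE]
  axes <- t(pc$rotation[, keep, drop = FALSE])
  # sign convention: largest-|loading| entry of each axis positive
  for (j in seq_len(nrow(axes))) {
    w <- which.max(abs(axes[j, ]))
    if (axes[j, w] < 0) {
      axes[j, ] <- -axes[j, ]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- pc$sdev[keep]^2
  structure(
    list(scores = scores, variance_explained = ev / sum(ev), axes = axes,
         mean_flat = ctr, mean_shape = .unflatten_shape(ctr),
         labels = dimnames(aligned$coords)[[1]],
         info = aligned$info, log_sizes = aligned$log_sizes,
         k = dim(aligned$coords)[2]),
    class = "morphospace"
  )
}

#' @export
print.morphospace <- function(x, ...) {
  ve <- x$variance_explained
  cat(sprintf("<morphospace> %d shapes, %d axes; PC1-3 explain %s%%\n",
              nrow(x$scores), length(ve),
              format(round(100 * sum(ve[seq_len(min(3, length(ve)))]), 2))))
  invisible(x)
}

#' Shape deformations at the extremes of a morphospace axis
#'
#' The mean shape displaced along one principal axis to the observed
#' minimum and maximum scores — the deformation grids drawn at the ends of
#' PCA axes in morphospace figures.
#'
#' @param space A `morphospace` from [shape_pca()].
#' @param axis Axis index (1-based).
#' @return A list with `shape_min` and `shape_max`, each k x 2.
#' @export
axis_endpoint_shapes <- function(space, axis = 1) {
  stopifnot(inherits(space, "morphospace"))
  if (axis < 1 || axis > nrow(space$axes)) {
    stop("invalid axis index ", axis, call. = FALSE)
  }
  rng <- range(space$scores[, axis])
  list(
    shape_min = .unflatten_shape(space$mean_flat + rng[1] * space$axes[axis, ]),
    shape_max = .unflatten_shape(space$mean_flat + rng[2] * space$axes[axis, ])
  )
}
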