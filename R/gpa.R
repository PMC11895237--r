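new_aligned_shapes <- function(coords, centroid_sizes, info, template = NULL,
                               iterations = NA_integer_,
                               final_change = NA_real_) {
  mn <- apply(coords, c(2, 3), mean)
  mn <- .center_scale(mn)$points
  structure(
    list(coords = coords, centroid_sizes = centroid_sizes,
         log_sizes = log(centroid_sizes), mean_shape = mn, info = info,
         template = template, iterations = iterations,
         final_change = final_change),
    class = "aligned_shapes"
  )
}

#' @export
print.aligned_shapes <- function(x, ...) {
  cat(sprintf(
    "<aligned_shapes> %d configurations x %d points (GPA, %s iterations)\n",
    dim(x$coords)[1], dim(x$coords)[2],
    ifelse(is.na(x$iterations), "?", x$iterations)))
  invisible(x)
}

#' Optimal rotational superposition of two configurations
#'
#' Finds the proper rotation (no reflection) minimizing the summed squared
#' distance between two centered, unit-centroid-size configurations, and
#' the residual Procrustes distance after rotating.
#'
#' @param a,b k x 2 matrices, centered with unit centroid size.
#' @return A list with `rotation` (2 x 2, det +1), `angle` (radians,
#'   counterclockwise rotation applied to `b`), `distance` (residual
#'   Procrustes distance) and `degenerate` (TRUE when either configuration
#'   has rank < 2, in which case the optimum is not unique).
#' @export
optimal_superposition <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) == nrow(b), ncol(a) == 2, ncol(b) == 2)
  S <- crossprod(b, a)
  theta <- atan2(S[2, 1] - S[1, 2], S[1, 1] + S[2, 2])
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  resid <- a - b %*% R
  degen <- min(svd(a)$d[2], svd(b)$d[2]) < 1e-12 * nrow(a)
  list(rotation = R, angle = theta,
       distance = sqrt(sum(resid^2)), degenerate = degen)
}

#' Procrustes distance between two shapes
#'
#' Square root of the summed squared inter-landmark distances after
#' centering, scaling to unit centroid size, and optimal rotation of `b`
#' onto `a`. Symmetric; zero iff the shapes coincide up to similarity.
#'
#' @param a,b k x 2 coordinate matrices (any location/scale/orientation).
#' @return Non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  aa <- .center_scale(as.matrix(a))$points
  bb <- .center_scale(as.matrix(b))$points
  optimal_superposition(aa, bb)$distance
}

#' Generalised Procrustes Analysis
#'
#' Iteratively removes position, scale and orientation from a sample of
#' configurations: each shape is centered and scaled to unit centroid size,
#' rotated onto the current mean, the mean is recomputed (and rescaled to
#' unit size), and the cycle repeats until the mean stops moving. With
#' `slide = TRUE` and a template defining semilandmark curves, each of the
#' first `slide_rounds` iterations also slides semilandmarks along their
#' curve tangents to minimize the thin-plate-spline bending energy of each
#' specimen's deformation from the current mean (see
#' [slide_semilandmarks()]).
#'
#' @param coords Long landmark tibble (or n x k x 2 array).
#' @param template Optional [landmark_template()] (required when
#'   `slide = TRUE`); for bilateral configurations pass the
#'   [mirror_template()].
#' @param slide Slide semilandmarks by minimum bending energy?
#' @param tol Convergence tolerance on the root-summed-squared displacement
#'   of the mean shape between iterations.
#' @param max_iter Maximum outer iterations; exceeded means an error
#'   carrying the last change.
#' @param slide_rounds Maximum outer iterations in which sliding is applied.
#' @return An `aligned_shapes` object: unit-size centered `coords`,
#'   `centroid_sizes` and `log_sizes` taken before scaling, `mean_shape`,
#'   specimen `info`, and iteration diagnostics.
#' @export
gpa <- function(coords, template = NULL, slide = FALSE, tol = 1e-10,
                max_iter = 200, slide_rounds = 10) {
  if (is.array(coords) && length(dim(coords)) == 3) {
    arr <- coords
    info <- tibble::tibble(specimen = dimnames(arr)[[1]] %||%
                             as.character(seq_len(dim(arr)[1])),
                           species = NA_character_)
  } else {
    arr <- coords_to_array(coords)
    info <- dplyr::distinct(
      coords[, intersect(c("specimen", "species"), names(coords))])
    info <- info[match(dimnames(arr)[[1]], info$specimen), , drop = FALSE]
    if (!"species" %in% names(info)) info$species <- NA_character_
  }
  n <- dim(arr)[1]
  if (n < 2) stop("GPA needs at least 2 configurations", call. = FALSE)
  if (slide && is.null(template)) {
    stop("sliding requires a template", call. = FALSE)
  }
  if (!is.null(template) && dim(arr)[2] != n_points(template)) {
    stop(sprintf("configurations have %d points but template defines %d",
                 dim(arr)[2], n_points(template)), call. = FALSE)
  }
  sizes <- numeric(n)
  for (i in seq_len(n)) {
    cs <- .center_scale(arr[i, , ])
    arr[i, , ] <- cs$points
    sizes[i] <- cs$size
  }
  # initial reference: first shape; then iterate rotations against the mean
  mean_shape <- arr[1, , ]
  change <- Inf
  iter <- 0
  while (change > tol) {
    iter <- iter + 1
    if (iter > max_iter) {
      stop(sprintf("GPA did not converge after %d iterations (last change %g)",
                   max_iter, change), call. = FALSE)
    }
    for (i in seq_len(n)) {
      os <- optimal_superposition(mean_shape, arr[i, , ])
      arr[i, , ] <- arr[i, , ] %*% os$rotation
    }
    if (slide && iter <= slide_rounds) {
      arr <- slide_semilandmarks(arr, mean_shape, template)
      for (i in seq_len(n)) {
        cs <- .center_scale(arr[i, , ])
        arr[i, , ] <- cs$points
        os <- optimal_superposition(mean_shape, arr[i, , ])
        arr[i, , ] <- arr[i, , ] %*% os$rotation
      }
    }
    new_mean <- .center_scale(apply(arr, c(2, 3), mean))$points
    os <- optimal_superposition(mean_shape, new_mean)
    new_mean <- new_mean %*% os$rotation
    change <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
  }
  for (i in seq_len(n)) { # final pass against the converged mean
    os <- optimal_superposition(mean_shape, arr[i, , ])
    arr[i, , ] <- arr[i, , ] %*% os$rotation
  }
  out <- new_aligned_shapes(arr, sizes, info, template,
                            iterations = iter, final_change = change)
  out
}

#' Thin-plate-spline bending energy matrix
#'
#' The k x k matrix `B` such that the bending energy of a deformation
#' taking the reference to target coordinates `(x', y')` is
#' `x'^T B x' + y'^T B y'` (up to a constant factor). `B` annihilates
#' affine deformations, so the energy of any affine map is exactly zero.
#'
#' @param ref k x 2 reference configuration (no coincident points).
#' @return k x k symmetric matrix.
#' @export
bending_energy_matrix <- function(ref) {
  ref <- as.matrix(ref)
  k <- nrow(ref)
  d2 <- as.matrix(stats::dist(ref))^2
  if (any(d2[upper.tri(d2)] < 1e-24)) {
    pr <- which(d2 < 1e-24 & upper.tri(d2), arr.ind = TRUE)
    stop(sprintf("coincident reference points %d and %d: bending energy matrix is singular",
                 pr[1, 1], pr[1, 2]), call. = FALSE)
  }
  K <- ifelse(d2 > 0, d2 * log(d2), 0)
  Q <- cbind(1, ref)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  Li <- solve(L)
  B <- Li[seq_len(k), seq_len(k)]
  (B + t(B)) / 2
}

#' Bending energy of a deformation
#'
#' @param ref Reference (k x 2); defines the spline.
#' @param target Target coordinates (k x 2).
#' @return Non-negative scalar; 0 for any affine map of `ref`.
#' @export
bending_energy <- function(ref, target) {
  B <- bending_energy_matrix(ref)
  target <- as.matrix(target)
  max(0, drop(crossprod(target[, 1], B %*% target[, 1]) +
                crossprod(target[, 2], B %*% target[, 2])))
}

#' Slide semilandmarks by minimum bending energy
#'
#' Each semilandmark may move along its local curve tangent (central
#' difference of its curve neighbours within the same specimen; wrapped for
#' closed curves, anchored by the bounding fixed landmarks for open ones).
#' The displacement of all semilandmarks of a specimen is solved jointly as
#' the linear system minimizing the thin-plate-spline bending energy of the
#' deformation from the reference (mean) shape to the specimen. Fixed
#' landmarks never move, and the energy never increases (no displacement is
#' always admissible).
#'
#' @param shapes n x k x 2 array (or a single k x 2 matrix) of aligned
#'   configurations.
#' @param mean_shape Reference k x 2 configuration.
#' @param template [landmark_template()] describing curves (use the
#'   bilateral template for mirrored data).
#' @return Array (or matrix) of the same dimensions with semilandmarks slid.
#' @export
slide_semilandmarks <- function(shapes, mean_shape, template) {
  stopifnot(inherits(template, "landmark_template"))
  single <- is.matrix(shapes)
  if (single) shapes <- array(shapes, c(1, nrow(shapes), 2))
  k <- dim(shapes)[2]
  stopifnot(k == n_points(template), nrow(mean_shape) == k)
  nb <- template$neighbors
  if (!nrow(nb)) return(if (single) shapes[1, , ] else shapes)
  B <- bending_energy_matrix(mean_shape)
  s <- nb$point
  for (i in seq_len(dim(shapes)[1])) {
    Y <- shapes[i, , ]
    tg <- Y[nb$nxt, , drop = FALSE] - Y[nb$prev, , drop = FALSE]
    tg <- tg / pmax(sqrt(rowSums(tg^2)), 1e-12)
    M <- B[s, s, drop = FALSE] * tcrossprod(tg)
    gx <- drop(B %*% Y[, 1])[s]
    gy <- drop(B %*% Y[, 2])[s]
    rhs <- -(tg[, 1] * gx + tg[, 2] * gy)
    t_opt <- tryCatch(
      solve(M + 1e-12 * mean(diag(M)) * diag(nrow(M)), rhs),
      error = function(e) stop("singular sliding system: ", conditionMessage(e),
                               call. = FALSE))
    Y[s, 1] <- Y[s, 1] + tg[, 1] * t_opt
    Y[s, 2] <- Y[s, 2] + tg[, 2] * t_opt
    shapes[i, , ] <- Y
  }
  if (single) shapes[1, , ] else shapes
}

#' Procrustes variance of an aligned set
#'
#' Mean squared Procrustes distance of the aligned shapes to their mean.
#'
#' @param aligned An `aligned_shapes` object.
#' @return Non-negative scalar.
#' @export
procrustes_variance <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_shapes"))
  n <- dim(aligned$coords)[1]
  mean(vapply(seq_len(n), function(i) {
    optimal_superposition(aligned$mean_shape, aligned$coords[i, , ])$distance^2
  }, numeric(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
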