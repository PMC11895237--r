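#' Convert a long landmark table to a coordinate array
#'
#' The package's tabular interchange format is one row per digitized point:
#' columns `specimen`, `species` (optional), `side` (optional), `point`,
#' `x`, `y`. Internally shapes are k x 2 matrices stacked in an
#' n x k x 2 array; these two helpers move between the representations.
#'
#' @param coords A long landmark tibble.
#' @return For `coords_to_array()`, an n x k x 2 array with specimen ids as
#'   first dimnames; for [array_to_coords()], a long tibble.
#' @export
coords_to_array <- function(coords) {
  stopifnot(all(c("specimen", "point", "x", "y") %in% names(coords)))
  if (anyNA(coords$x) || anyNA(coords$y)) {
    bad <- unique(coords$specimen[is.na(coords$x) | is.na(coords$y)])
    stop("missing coordinates for specimen(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ids <- unique(coords$specimen)
  kk <- sort(unique(coords$point))
  counts <- table(coords$specimen)
  if (length(unique(counts)) != 1) {
    stop("specimens have unequal point counts", call. = FALSE)
  }
  arr <- array(NA_real_, c(length(ids), length(kk), 2),
               dimnames = list(ids, NULL, c("x", "y")))
  ord <- order(match(coords$specimen, ids), coords$point)
  cc <- coords[ord, ]
  arr[, , 1] <- matrix(cc$x, length(ids), length(kk), byrow = TRUE)
  arr[, , 2] <- matrix(cc$y, length(ids), length(kk), byrow = TRUE)
  arr
}

#' @rdname coords_to_array
#' @param arr An n x k x 2 array.
#' @param info Optional tibble of per-specimen metadata (first column joined
#'   by specimen id) to carry along.
#' @export
array_to_coords <- function(arr, info = NULL) {
  ids <- dimnames(arr)[[1]]
  if (is.null(ids)) ids <- as.character(seq_len(dim(arr)[1]))
  k <- dim(arr)[2]
  out <- tibble::tibble(
    specimen = rep(ids, each = k),
    point = rep(seq_len(k), times = length(ids)),
    x = as.vector(t(arr[, , 1, drop = FALSE][, , 1])),
    y = as.vector(t(arr[, , 2, drop = FALSE][, , 1]))
  )
  if (!is.null(info) && "specimen" %in% names(info)) {
    out <- dplyr::left_join(out, info, by = "specimen")
  }
  out
}

# flatten n x k x 2 -> n x 2k (x1..xk, y1..yk) and back
.flatten_shapes <- function(arr) {
  cbind(arr[, , 1, drop = FALSE][, , 1], arr[, , 2, drop = FALSE][, , 1])
}

.unflatten_shape <- function(v) {
  k <- length(v) / 2
  cbind(v[seq_len(k)], v[k + seq_len(k)])
}

#' Centroid size of a configuration
#'
#' The standard geometric-morphometric size measure: the square root of the
#' summed squared distances of all points to their centroid. Invariant to
#' rotation and translation; scales linearly under isotropic scaling.
#'
#' @param points A k x 2 coordinate matrix (k >= 2).
#' @return A non-negative scalar; 0 for fully coincident points (degenerate).
#' @examples
#' centroid_size(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))) # sqrt(2)
#' @export
centroid_size <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) >= 2, all(is.finite(points)))
  ctr <- colMeans(points)
  sqrt(sum((points[, 1] - ctr[1])^2 + (points[, 2] - ctr[2])^2))
}

# center and scale a k x 2 matrix to unit centroid size
.center_scale <- function(points) {
  ctr <- colMeans(points)
  pts <- sweep(points, 2, ctr)
  cs <- sqrt(sum(pts^2))
  if (cs <= 0) stop("degenerate configuration: zero centroid size",
                    call. = FALSE)
  list(points = pts / cs, size = cs)
}
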