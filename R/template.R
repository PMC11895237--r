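#' Define a landmark digitization template
#'
#' A template describes how a cranium (or any 2D structure) was digitized:
#' a set of fixed anatomical landmarks followed by semilandmark curves, and
#' which landmarks lie on the sagittal midline (used when a one-sided
#' digitization is mirrored into a bilateral configuration).
#'
#' Point indices are assigned in digitization order: fixed landmarks
#' `1..n_landmarks`, then the semilandmarks of each curve in curve order.
#' An open curve runs between two fixed landmarks, which anchor the sliding
#' of its first and last semilandmarks; a closed curve (e.g. a tooth
#' outline) has no anchoring landmarks and its semilandmarks wrap around.
#'
#' @param n_landmarks Number of fixed landmarks.
#' @param curves A data frame with one row per semilandmark curve and
#'   columns `start`, `end` (fixed landmark ids delimiting an open curve;
#'   ignored for closed curves), `n_semi` (number of semilandmarks, >= 1)
#'   and `closed` (logical). `start`/`end` may be `NA` for closed curves.
#' @param midline Integer ids of fixed landmarks lying on the sagittal
#'   midline. May be empty if mirroring is never requested.
#' @param labels Optional character vector of landmark definitions,
#'   length `n_landmarks`.
#' @return An object of class `landmark_template`.
#' @examples
#' tpl <- landmark_template(
#'   n_landmarks = 4,
#'   curves = data.frame(start = 1, end = 2, n_semi = 3, closed = FALSE),
#'   midline = c(1, 2)
#' )
#' n_points(tpl)
#' @export
landmark_template <- function(n_landmarks, curves = NULL, midline = integer(),
                              labels = NULL) {
  stopifnot(is.numeric(n_landmarks), n_landmarks >= 1)
  n_landmarks <- as.integer(n_landmarks)
  if (is.null(curves)) {
    curves <- tibble::tibble(start = integer(), end = integer(),
                             n_semi = integer(), closed = logical())
  }
  curves <- tibble::as_tibble(curves)
  if (!"closed" %in% names(curves)) curves$closed <- FALSE
  stopifnot(all(c("start", "end", "n_semi", "closed") %in% names(curves)))
  if (any(curves$n_semi < 1)) {
    stop("every curve must carry at least one semilandmark", call. = FALSE)
  }
  open <- !curves$closed
  ep <- c(curves$start[open], curves$end[open])
  if (any(is.na(ep)) || any(ep < 1L | ep > n_landmarks)) {
    stop("open-curve endpoints must be existing fixed landmark ids",
         call. = FALSE)
  }
  midline <- sort(unique(as.integer(midline)))
  if (length(midline) && any(midline < 1L | midline > n_landmarks)) {
    stop("midline ids must be fixed landmark ids", call. = FALSE)
  }
  if (!is.null(labels) && length(labels) != n_landmarks) {
    stop("labels must have one entry per fixed landmark", call. = FALSE)
  }
  tpl <- structure(
    list(n_landmarks = n_landmarks, curves = curves, midline = midline,
         labels = labels, bilateral = FALSE),
    class = "landmark_template"
  )
  tpl$roles <- .template_roles(tpl)
  tpl$neighbors <- .template_neighbors(tpl)
  tpl
}

# point-by-point role table for a one-sided template
.template_roles <- function(tpl) {
  roles <- tibble::tibble(
    point = seq_len(tpl$n_landmarks),
    role = "landmark",
    curve = NA_integer_
  )
  nxt <- tpl$n_landmarks
  for (ci in seq_len(nrow(tpl$curves))) {
    m <- tpl$curves$n_semi[ci]
    roles <- dplyr::bind_rows(roles, tibble::tibble(
      point = nxt + seq_len(m), role = "semilandmark", curve = ci
    ))
    nxt <- nxt + m
  }
  roles
}

# prev/next point of each semilandmark, used for sliding tangents
.template_neighbors <- function(tpl) {
  out <- list(tibble::tibble(point = integer(), prev = integer(),
                             nxt = integer()))
  nxt <- tpl$n_landmarks
  for (ci in seq_len(nrow(tpl$curves))) {
    m <- tpl$curves$n_semi[ci]
    ids <- nxt + seq_len(m)
    if (tpl$curves$closed[ci]) {
      prv <- ids[c(m, seq_len(m - 1))]
      nx <- ids[c(seq_len(m - 1) + 1, 1)]
    } else {
      prv <- c(tpl$curves$start[ci], ids[-m])
      nx <- c(ids[-1], tpl$curves$end[ci])
    }
    out[[ci]] <- tibble::tibble(point = ids, prev = prv, nxt = nx)
    nxt <- nxt + m
  }
  dplyr::bind_rows(out)
}

#' Number of points implied by a template
#'
#' @param template A [landmark_template()].
#' @return Fixed landmarks plus all semilandmarks (one-sided count, or the
#'   bilateral count for a mirrored template).
#' @export
n_points <- function(template) {
  stopifnot(inherits(template, "landmark_template"))
  nrow(template$roles)
}

#' @export
print.landmark_template <- function(x, ...) {
  cat(sprintf(
    "<landmark_template> %d fixed landmarks, %d curves (%d semilandmarks), %d points%s\n",
    x$n_landmarks, nrow(x$curves), sum(x$curves$n_semi), n_points(x),
    if (isTRUE(x$bilateral)) " [bilateral]" else ""
  ))
  if (length(x$midline)) {
    cat("midline landmarks:", paste(x$midline, collapse = ", "), "\n")
  }
  invisible(x)
}

#' The Pteromyini cranial digitization template
#'
#' The ventral-cranium scheme used throughout the package: 19 fixed
#' landmarks and four semilandmark curves — the snout contour between
#' landmarks 1 and 19 (8 semilandmarks), the outer (19 to 18) and inner
#' (7 to 9) curves of the zygomatic arch (18 semilandmarks each), and the
#' closed outline of the fourth upper premolar (18 semilandmarks), for 81
#' points per side. Landmarks 1, 10, 11, 13 and 14 are mid-sagittal by
#' definition and form the default mirroring axis; landmarks 2 (incisor
#' tooth sockets midpoint) and 12 (pterygoid apophysis) sit near but not
#' on the midline and are excluded by default.
#'
#' @param midline Fixed landmark ids treated as mid-sagittal.
#' @return A [landmark_template()] with 81 one-sided points.
#' @export
pteromyini_template <- function(midline = c(1, 10, 11, 13, 14)) {
  labels <- c(
    "Anterior (mid-sagittal) point of the premaxilla",
    "Midpoint of the tooth sockets of the incisors",
    "Anterior end of the incisor foramen",
    "Posterior end of the incisor foramen",
    "Tip of the masseter tubercle",
    "Anterior end of the fourth upper premolar",
    "Maximum curvature at the internal zygomatic arch",
    "Posterior end of tooth row",
    "Anterior end of the alisphenoid-squamosal suture",
    "Maxilla-palatine suture in the mid-sagittal plane",
    "Posterior end of the interpalatine suture",
    "Pterygoid apophysis",
    "Anterior edge of the foramen magnum",
    "Posterior edge of the foramen magnum",
    "Occipital condyle at the internal edge of the foramen magnum",
    "Outermost point of the occipital condyle",
    "Anterior tip of the external auditory meatus",
    "Posterior tip of the zygomatic arch",
    "Rostrum point furthest from the sagittal plane"
  )
  landmark_template(
    n_landmarks = 19,
    curves = tibble::tibble(
      start = c(1L, 19L, 7L, NA),
      end = c(19L, 18L, 9L, NA),
      n_semi = c(8L, 18L, 18L, 18L),
      closed = c(FALSE, FALSE, FALSE, TRUE)
    ),
    midline = midline,
    labels = labels
  )
}

#' Expand a one-sided template to its bilateral (mirrored) form
#'
#' Mirrored configurations contain the original points `1..k` followed by
#' reflected copies of every non-midline point, in original order. This
#' function builds the matching template so that downstream operations
#' (notably semilandmark sliding) know the role and curve neighbours of
#' every bilateral point.
#'
#' @param template A one-sided [landmark_template()] with a non-empty
#'   midline set.
#' @return A `landmark_template` flagged bilateral, with `mirror_map`
#'   giving, for each one-sided point, its reflected partner's index
#'   (midline points map to themselves).
#' @export
mirror_template <- function(template) {
  stopifnot(inherits(template, "landmark_template"))
  if (isTRUE(template$bilateral)) return(template)
  if (!length(template$midline)) {
    stop("mirroring requires a non-empty midline set", call. = FALSE)
  }
  k <- n_points(template)
  is_mid <- template$roles$point %in% template$midline &
    template$roles$role == "landmark"
  map <- integer(k)
  map[is_mid] <- which(is_mid)
  map[!is_mid] <- k + seq_len(sum(!is_mid))
  roles2 <- template$roles[!is_mid, ]
  roles2$point <- map[!is_mid]
  roles2$curve <- ifelse(is.na(roles2$curve), NA_integer_,
                         roles2$curve + nrow(template$curves))
  nb <- template$neighbors
  nb2 <- tibble::tibble(point = map[nb$point], prev = map[nb$prev],
                        nxt = map[nb$nxt])
  out <- template
  out$bilateral <- TRUE
  out$mirror_map <- map
  out$roles <- dplyr::bind_rows(template$roles, roles2)
  out$neighbors <- dplyr::bind_rows(nb, nb2)
  out$curves <- dplyr::bind_rows(template$curves, template$curves)
  out
}

#' Reference geometry for a template
#'
#' A deterministic, roughly cranium-proportioned base configuration used by
#' the synthetic-data generator as the grand-mean shape: fixed landmarks on
#' an ellipse, open-curve semilandmarks along slightly bowed arcs between
#' their anchoring landmarks, closed-curve semilandmarks on a small circle.
#' Purely geometric; carries no anatomical realism beyond point counts.
#'
#' @param template A [landmark_template()] (one-sided).
#' @return A `n_points(template)` x 2 matrix.
#' @export
template_base_shape <- function(template) {
  stopifnot(inherits(template, "landmark_template"),
            !isTRUE(template$bilateral))
  k <- template$n_landmarks
  # fixed landmarks on a half-ellipse (one-sided digitization)
  th <- seq(0.1, pi - 0.1, length.out = k)
  pts <- cbind(1.5 * cos(th), sin(th))
  out <- matrix(NA_real_, n_points(template), 2)
  out[seq_len(k), ] <- pts
  nxt <- k
  for (ci in seq_len(nrow(template$curves))) {
    m <- template$curves$n_semi[ci]
    if (template$curves$closed[ci]) {
      # small closed outline placed off-axis
      a <- seq(0, 2 * pi, length.out = m + 1)[-(m + 1)]
      ctr <- c(0.6, 0.45) + 0.05 * ci
      sl <- cbind(ctr[1] + 0.18 * cos(a), ctr[2] + 0.18 * sin(a))
    } else {
      p0 <- pts[template$curves$start[ci], ]
      p1 <- pts[template$curves$end[ci], ]
      tfr <- seq_len(m) / (m + 1)
      seg <- p1 - p0
      nrm <- c(-seg[2], seg[1]) / max(sqrt(sum(seg^2)), 1e-12)
      bow <- 0.15 * sin(pi * tfr) * (1 + 0.2 * ci)
      sl <- cbind(p0[1] + tfr * seg[1] + bow * nrm[1],
                  p0[2] + tfr * seg[2] + bow * nrm[2])
    }
    out[nxt + seq_len(m), ] <- sl
    nxt <- nxt + m
  }
  out
}
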