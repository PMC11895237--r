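#' Read landmark configurations
#'
#' Reads digitized 2D configurations from either a TPS file (`LM=` /
#' coordinate pairs / `ID=` blocks, with optional `SCALE=` applied
#' multiplicatively) or a long-format CSV with columns
#' `specimen, point, x, y` and optionally `species`, `side`.
#'
#' @param path File to read.
#' @param format `"tps"` or `"csv"`; guessed from the extension by default.
#' @param template Optional [landmark_template()]; when supplied, each
#'   specimen's point count is validated against `n_points(template)`.
#' @return A long landmark tibble (`specimen, species, side, point, x, y`).
#' @export
read_landmarks <- function(path, format = c("auto", "tps", "csv"),
                           template = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tps$", path, ignore.case = TRUE)) "tps" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  out <- if (format == "tps") .read_tps(path) else .read_lm_csv(path)
  if (!is.null(template)) {
    counts <- dplyr::count(out, .data$specimen)
    bad <- counts[counts$n != n_points(template), ]
    if (nrow(bad)) {
      stop(sprintf(
        "point-count mismatch for specimen '%s': expected %d, found %d",
        bad$specimen[1], n_points(template), bad$n[1]), call. = FALSE)
    }
  }
  out
}

.read_tps <- function(path) {
  lines <- readLines(path, warn = FALSE)
  specs <- list()
  i <- 1
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1; next }
    if (!grepl("^LM=", ln, ignore.case = TRUE)) {
      stop(sprintf("TPS parse error at line %d: expected LM= record", i),
           call. = FALSE)
    }
    k <- as.integer(sub("^LM=", "", ln, ignore.case = TRUE))
    xy <- matrix(NA_real_, k, 2)
    for (j in seq_len(k)) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + j]),
                                                "[ \t]+")[[1]]))
      if (length(v) != 2 || anyNA(v)) {
        stop(sprintf("TPS parse error at line %d: expected two coordinates",
                     i + j), call. = FALSE)
      }
      xy[j, ] <- v
    }
    i <- i + k + 1
    id <- NULL; scale <- NA_real_
    while (i <= length(lines) &&
           grepl("^(ID|IMAGE|SCALE)=", trimws(lines[i]), ignore.case = TRUE)) {
      ln <- trimws(lines[i])
      if (grepl("^ID=", ln, ignore.case = TRUE)) {
        id <- sub("^ID=", "", ln, ignore.case = TRUE)
      } else if (grepl("^SCALE=", ln, ignore.case = TRUE)) {
        scale <- as.numeric(sub("^SCALE=", "", ln, ignore.case = TRUE))
      }
      i <- i + 1
    }
    if (is.null(id)) id <- as.character(length(specs) + 1)
    if (is.finite(scale)) xy <- xy * scale
    specs[[length(specs) + 1]] <- tibble::tibble(
      specimen = id, species = NA_character_, side = "left",
      point = seq_len(k), x = xy[, 1], y = xy[, 2]
    )
  }
  dplyr::bind_rows(specs)
}

.read_lm_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("specimen", "point", "x", "y")
  if (!all(need %in% names(out))) {
    stop("landmark CSV must contain columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyNA(out$x) || anyNA(out$y)) {
    bad <- unique(out$specimen[is.na(out$x) | is.na(out$y)])
    stop("missing coordinate(s) for specimen(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!"species" %in% names(out)) out$species <- NA_character_
  if (!"side" %in% names(out)) out$side <- "left"
  out$specimen <- as.character(out$specimen)
  dplyr::select(out, "specimen", "species", "side", "point", "x", "y")
}

#' Write landmark configurations
#'
#' Inverse of [read_landmarks()]; full double precision is preserved so that
#' a write/read round trip is lossless.
#'
#' @param coords A long landmark tibble.
#' @param path Output file.
#' @param format `"tps"` or `"csv"` (default from extension).
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(coords, path, format = c("auto", "tps", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tps$", path, ignore.case = TRUE)) "tps" else "csv"
  }
  if (format == "csv") {
    readr::write_csv(coords, path)
    return(invisible(path))
  }
  ids <- unique(coords$specimen)
  con <- file(path, "w")
  on.exit(close(con))
  for (id in ids) {
    cc <- coords[coords$specimen == id, ]
    cc <- cc[order(cc$point), ]
    writeLines(sprintf("LM=%d", nrow(cc)), con)
    writeLines(sprintf("%.17g %.17g", cc$x, cc$y), con)
    writeLines(sprintf("ID=%s", id), con)
  }
  invisible(path)
}

#' Read a species metadata table
#'
#' Expects the Table-1-style layout: `species`, `n_specimens`, `diet`
#' (one of Folivore_1, Folivore_2, Frugivore, Nucivore, Generalist, NoInfo)
#' and 0/1 occupancy flags for the Walter biome columns
#' I, II, II/III, V, VI, VIII.
#'
#' @param path CSV file; defaults to the Pteromyini table shipped with the
#'   package.
#' @return A tibble with a `diet` factor and integer occupancy flags.
#' @export
read_species_metadata <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pteromyini_species.csv",
                        package = "pteromorph", mustWork = TRUE)
  }
  md <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("species", "diet") %in% names(md)))
  lv <- c("Folivore_1", "Folivore_2", "Frugivore", "Nucivore", "Generalist",
          "NoInfo")
  bad <- setdiff(unique(md$diet), lv)
  if (length(bad)) {
    stop("unknown diet categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  md$diet <- factor(md$diet, levels = lv)
  md
}

#' Sampled Pteromyini species, diets and biome occupancy
#'
#' The study's sampling table: 35 flying-squirrel species (out of the 52 in
#' the tribe), number of specimens measured per species, diet category, and
#' occupancy of the Walter biomes I (equatorial rainforest),
#' II (tropical deciduous woodland), II/III (savanna), V (temperate
#' evergreen forest), VI (broad-leaf deciduous forest) and VIII (taiga).
#'
#' @return A tibble with one row per species.
#' @export
pteromyini_species <- function() read_species_metadata(NULL)

#' Biome labels of a metadata table
#' @param metadata A metadata tibble from [read_species_metadata()].
#' @return Character vector of biome column names present.
#' @export
biome_labels <- function(metadata) {
  intersect(c("I", "II", "II/III", "V", "VI", "VIII"), names(metadata))
}

#' Mirror a one-sided configuration across its midline
#'
#' Crania are bilaterally symmetric, so digitizing one side and reflecting
#' it yields the full structure without doubling measurement error. The
#' mirroring axis is the total-least-squares line through the midline
#' landmarks; every non-midline point is reflected across it and appended
#' (in original point order) after the original points.
#'
#' @param coords Long landmark tibble of one-sided configurations.
#' @param template The one-sided [landmark_template()]; its `midline` set
#'   (>= 2 landmarks) defines the axis.
#' @return A long landmark tibble of bilateral configurations with
#'   `2k - m` points each (`m` = number of midline landmarks), matching
#'   [mirror_template()] ordering.
#' @export
mirror_configuration <- function(coords, template) {
  stopifnot(inherits(template, "landmark_template"))
  if (any(coords$side == "bilateral")) {
    stop("configurations are already bilateral", call. = FALSE)
  }
  if (length(template$midline) < 2) {
    stop("at least 2 midline landmarks are needed to define the axis",
         call. = FALSE)
  }
  arr <- coords_to_array(coords)
  if (dim(arr)[2] != n_points(template)) {
    stop(sprintf("expected %d points per specimen, found %d",
                 n_points(template), dim(arr)[2]), call. = FALSE)
  }
  btpl <- mirror_template(template)
  map <- btpl$mirror_map
  mirrored_src <- which(map > n_points(template))
  info <- dplyr::distinct(
    coords[, intersect(c("specimen", "species"), names(coords))]
  )
  out <- vector("list", dim(arr)[1])
  for (i in seq_len(dim(arr)[1])) {
    pts <- arr[i, , ]
    refl <- .reflect_points(pts[mirrored_src, , drop = FALSE],
                            pts[template$midline, , drop = FALSE])
    full <- rbind(pts, refl)
    out[[i]] <- tibble::tibble(
      specimen = dimnames(arr)[[1]][i], point = seq_len(nrow(full)),
      x = full[, 1], y = full[, 2]
    )
  }
  res <- dplyr::bind_rows(out)
  res$side <- "bilateral"
  if (nrow(info) && "species" %in% names(info)) {
    res <- dplyr::left_join(res, info, by = "specimen")
  }
  dplyr::select(res, "specimen", dplyr::any_of("species"), "side",
                "point", "x", "y")
}

# reflect pts across the total-least-squares line through axis_pts
.reflect_points <- function(pts, axis_pts) {
  ctr <- colMeans(axis_pts)
  dv <- sweep(axis_pts, 2, ctr)
  sv <- svd(dv)
  d <- sv$v[, 1] # principal direction of the midline points
  H <- 2 * tcrossprod(d) - diag(2) # reflection across the line
  sweep(sweep(pts, 2, ctr) %*% H, 2, ctr, `+`)
}

#' Average aligned shapes and sizes within species
#'
#' Species-level shape is the coordinate-wise arithmetic mean of the
#' species' aligned specimens; species size is the mean of the specimens'
#' log centroid sizes. The returned set is re-standardized so every species
#' mean has centroid at the origin and unit centroid size.
#'
#' @param aligned An `aligned_shapes` object from [gpa()].
#' @param species Character vector of species labels, one per specimen;
#'   defaults to the `species` column carried in `aligned$info`.
#' @return An `aligned_shapes` object with one shape per species.
#' @export
species_means <- function(aligned, species = NULL) {
  stopifnot(inherits(aligned, "aligned_shapes"))
  if (is.null(species)) species <- aligned$info$species
  if (anyNA(species)) {
    stop("every specimen needs a species label", call. = FALSE)
  }
  sp <- unique(species)
  n <- length(sp)
  k <- dim(aligned$coords)[2]
  arr <- array(NA_real_, c(n, k, 2), dimnames = list(sp, NULL, c("x", "y")))
  logsz <- numeric(n)
  for (i in seq_len(n)) {
    sel <- species == sp[i]
    mn <- apply(aligned$coords[sel, , , drop = FALSE], c(2, 3), mean)
    cs <- .center_scale(mn)
    arr[i, , ] <- cs$points
    logsz[i] <- mean(aligned$log_sizes[sel])
  }
  new_aligned_shapes(
    coords = arr, centroid_sizes = exp(logsz),
    info = tibble::tibble(specimen = sp, species = sp),
    template = aligned$template, iterations = aligned$iterations
  )
}
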