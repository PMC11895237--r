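# shared fixtures: small templates and shape generators (built in code)

tpl_small <- function() {
  landmark_template(
    5,
    curves = data.frame(start = c(1, NA), end = c(2, NA),
                        n_semi = c(3, 4), closed = c(FALSE, TRUE)),
    midline = c(1, 2)
  )
}

tpl_curves <- function() {
  landmark_template(
    8,
    curves = data.frame(start = c(1, 3), end = c(2, 4), n_semi = c(5, 5),
                        closed = FALSE),
    midline = c(1, 2)
  )
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# a well-spread k-point configuration (deterministic given seed)
rand_shape <- function(k, seed = 1, sd = 0.2) {
  set.seed(seed)
  th <- seq(0, 2 * pi, length.out = k + 1)[-1]
  cbind(cos(th), sin(th)) + matrix(rnorm(2 * k, 0, sd), k, 2)
}

# aligned set of n noisy variants of a base shape
make_aligned <- function(n, k = 8, sd = 0.05, seed = 1,
                         labels = sprintf("s%02d", seq_len(n))) {
  set.seed(seed)
  base <- rand_shape(k, seed)
  arr <- array(NA_real_, c(n, k, 2), dimnames = list(labels, NULL, NULL))
  for (i in seq_len(n)) {
    pts <- base + matrix(rnorm(2 * k, 0, sd), k, 2)
    arr[i, , ] <- pts %*% rot2(runif(1, 0, 2 * pi)) * exp(rnorm(1, 0, 0.1))
  }
  gpa(arr)
}

# long tibble from an n x k x 2 array with species labels
coords_tbl <- function(arr, species = NULL) {
  tb <- array_to_coords(arr)
  tb$side <- "left"
  if (!is.null(species)) {
    tb$species <- species[match(tb$specimen, unique(tb$specimen))]
  } else tb$species <- tb$specimen
  tb
}
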