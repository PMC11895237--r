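#' Brownian-motion phylogenetic covariance
#'
#' Under Brownian motion the expected covariance of a trait between two
#' tips equals the depth of their most recent common ancestor; the diagonal
#' holds tip depths. Computed with [ape::vcv.phylo()] and reordered to the
#' requested taxa.
#'
#' @param tree An `ape::phylo` tree with positive branch lengths.
#' @param taxa Species to keep, in the desired row order (default: all tips).
#' @return A `phylo_covariance` object: `taxa`, matrix `C`, and the
#'   `lambda` applied (1 for the raw BM matrix).
#' @export
bm_covariance <- function(tree, taxa = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(taxa)) taxa <- tree$tip.label
  miss <- setdiff(taxa, tree$tip.label)
  if (length(miss)) {
    stop("taxa missing from tree: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (length(taxa) < nrow(as.matrix(tree$edge)) &&
      length(setdiff(tree$tip.label, taxa))) {
    tree <- ape::keep.tip(tree, taxa)
  }
  C <- ape::vcv.phylo(tree)[taxa, taxa]
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) {
    stop("phylogenetic covariance is singular (zero-length terminal branches?)",
         call. = FALSE)
  }
  structure(list(taxa = taxa, C = C, lambda = 1),
            class = "phylo_covariance")
}

#' @export
print.phylo_covariance <- function(x, ...) {
  cat(sprintf("<phylo_covariance> %d taxa, lambda = %g\n",
              length(x$taxa), x$lambda))
  invisible(x)
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies the off-diagonal entries by `lambda`, leaving tip variances
#' unchanged — equivalent to rescaling the internal branches of the tree.
#' `lambda = 0` gives a star phylogeny (independence), `lambda = 1` the raw
#' Brownian-motion matrix.
#'
#' @param cov A `phylo_covariance`.
#' @param lambda Scalar in `[0, upper]`.
#' @param upper Upper bound accepted (default 1).
#' @return A transformed `phylo_covariance` (its `lambda` field records the
#'   cumulative multiplier).
#' @export
lambda_transform <- function(cov, lambda, upper = 1) {
  stopifnot(inherits(cov, "phylo_covariance"))
  if (lambda < 0 || lambda > upper) {
    stop("lambda must lie in [0, ", upper, "]", call. = FALSE)
  }
  C <- cov$C * lambda
  diag(C) <- diag(cov$C)
  structure(list(taxa = cov$taxa, C = C, lambda = cov$lambda * lambda),
            class = "phylo_covariance")
}

# log-likelihood of iid-column Gaussian residuals with covariance C_lambda,
# rate profiled out per column
.lambda_loglik <- function(lambda, R, cov) {
  Cl <- lambda_transform(cov, lambda)$C
  n <- nrow(R)
  eg <- eigen(Cl, symmetric = TRUE)
  if (min(eg$values) <= 0) return(-Inf)
  W <- eg$vectors %*% (t(eg$vectors) / sqrt(eg$values)) # C^{-1/2}
  logdet <- sum(log(eg$values))
  Rt <- W %*% R
  s2 <- colSums(Rt^2) / n
  s2 <- pmax(s2, 1e-300)
  sum(-n / 2 * (log(2 * pi) + 1) - n / 2 * log(s2) - logdet / 2)
}

#' Maximum-likelihood Pagel's lambda for multivariate residuals
#'
#' Maximizes, over a common `lambda` in `[0, 1]`, the sum across response
#' columns of the Gaussian log-likelihood with covariance
#' `lambda_transform(C, lambda)` and a per-column rate profiled out.
#' Deterministic bounded scalar optimization (tolerance 1e-6), with the
#' interval ends checked explicitly.
#'
#' @param residuals n x q matrix of residuals (rows matched to `cov$taxa`),
#'   typically from a non-phylogenetic fit of the full model.
#' @param cov A `phylo_covariance` (untransformed, `lambda = 1`).
#' @return The ML lambda in `[0, 1]`, with the attained log-likelihood as
#'   attribute `"logLik"`.
#' @export
estimate_lambda <- function(residuals, cov) {
  stopifnot(inherits(cov, "phylo_covariance"))
  R <- as.matrix(residuals)
  if (nrow(R) != length(cov$taxa)) {
    stop("residual rows must match cov taxa", call. = FALSE)
  }
  opt <- stats::optimize(.lambda_loglik, c(0, 1), R = R, cov = cov,
                         maximum = TRUE, tol = 1e-6)
  cand <- rbind(c(opt$maximum, opt$objective),
                c(0, .lambda_loglik(0, R, cov)),
                c(1, .lambda_loglik(1, R, cov)))
  best <- cand[which.max(cand[, 2]), ]
  structure(best[1], logLik = best[2])
}

# inverse square root of an SPD matrix
.inv_sqrt <- function(C) {
  eg <- eigen(C, symmetric = TRUE)
  if (min(eg$values) <= 1e-12 * max(eg$values)) {
    stop("covariance matrix is computationally singular", call. = FALSE)
  }
  eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
}

#' Procrustes phylogenetic generalized least squares with RRPP inference
#'
#' Fits a linear model to a multivariate response (Procrustes coordinates,
#' or a scalar such as log centroid size) after premultiplying response and
#' design by the inverse square root of the phylogenetic covariance.
#' Sums of squares are sequential (type I, terms in formula order), each
#' computed as the drop in summed squared residuals between nested models —
#' the distance-based (Procrustes) decomposition, identical to the summed
#' univariate decomposition over coordinates. Significance comes from
#' randomizing reduced-model residuals (RRPP): for each term, residuals of
#' its reduced model are permuted, added back to the reduced fit, and the
#' term's F recomputed; `p` is the proportion of the `n_perm` arrangements
#' (the observed one included) with `F` at least the observed, and `Z` is
#' the standard-normal position of `log F` within the permuted
#' distribution.
#'
#' @param response n x q numeric matrix (or vector), rows in `cov$taxa`
#'   order.
#' @param formula RHS-only formula over columns of `data`,
#'   e.g. `~ diet + size`.
#' @param data Tibble of predictors, rows in `cov$taxa` order.
#' @param cov A `phylo_covariance` (apply [lambda_transform()] first for a
#'   lambda-rescaled fit); `NULL` for a non-phylogenetic Procrustes ANOVA.
#' @param n_perm Number of permutations including the observed arrangement.
#' @param seed Optional integer seed for the permutations.
#' @return A `comparative_fit`: an ANOVA tibble (`term, df, SS, MS, r2, F,
#'   Z, p`) with Residuals and Total rows, plus fit internals used by
#'   downstream dispersion/allometry functions.
#' @export
pgls_fit <- function(response, formula, data, cov = NULL, n_perm = 1000,
                     seed = NULL) {
  Y <- as.matrix(response)
  n <- nrow(Y)
  data <- as.data.frame(data)
  data <- droplevels(data)
  if (!is.null(cov)) {
    stopifnot(inherits(cov, "phylo_covariance"))
    if (n != length(cov$taxa)) stop("response rows must match cov taxa",
                                    call. = FALSE)
    P <- .inv_sqrt(cov$C)
  } else {
    P <- diag(n)
  }
  if (n_perm < 99) warning("n_perm < 99 gives coarse p-values")
  trm <- stats::terms(formula, data = data)
  labels <- attr(trm, "term.labels")
  if (!length(labels)) stop("formula must contain at least one term",
                            call. = FALSE)
  X_full <- stats::model.matrix(trm, data)
  if (qr(X_full)$rank < ncol(X_full)) {
    stop("design is rank deficient after encoding", call. = FALSE)
  }
  Yt <- P %*% Y
  # nested model sequence: intercept, then terms added in formula order
  Qs <- vector("list", length(labels) + 1)
  dfs <- integer(length(labels) + 1)
  asg <- attr(X_full, "assign")
  for (i in 0:length(labels)) {
    Xi <- P %*% X_full[, asg <= i, drop = FALSE]
    qri <- qr(Xi)
    Qs[[i + 1]] <- qr.Q(qri)[, seq_len(qri$rank), drop = FALSE]
    dfs[i + 1] <- qri$rank
  }
  rss <- function(Q, Y) sum(Y^2) - sum(crossprod(Q, Y)^2)
  nt <- length(labels)
  df_term <- diff(dfs)
  df_res <- n - dfs[nt + 1]
  rss_obs <- vapply(Qs, rss, numeric(1), Y = Yt)
  SS <- -diff(rss_obs)
  SS_res <- rss_obs[nt + 1]
  SS_tot <- rss_obs[1]
  if (df_res <= 0 || SS_res <= 1e-300 * max(SS_tot, 1)) {
    F_obs <- rep(NA_real_, nt)
    flagged <- TRUE
  } else {
    F_obs <- (SS / df_term) / (SS_res / df_res)
    flagged <- FALSE
  }
  # RRPP permutations (first arrangement = observed)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  perms <- cbind(seq_len(n),
                 replicate(n_perm - 1, sample.int(n)))
  Fperm <- matrix(NA_real_, n_perm, nt)
  if (!flagged) {
    for (i in seq_len(nt)) {
      Qr <- Qs[[i]]
      fit_red <- Qr %*% crossprod(Qr, Yt)
      res_red <- Yt - fit_red
      for (r in seq_len(n_perm)) {
        Yp <- fit_red + res_red[perms[, r], , drop = FALSE]
        ss_i <- rss(Qs[[i]], Yp) - rss(Qs[[i + 1]], Yp)
        ss_e <- rss(Qs[[nt + 1]], Yp)
        Fperm[r, i] <- (ss_i / df_term[i]) / (ss_e / df_res)
      }
    }
  }
  p <- Z <- rep(NA_real_, nt)
  if (!flagged) {
    for (i in seq_len(nt)) {
      p[i] <- mean(Fperm[, i] >= F_obs[i] - 1e-12)
      lf <- log(pmax(Fperm[, i], 1e-300))
      s <- stats::sd(lf)
      Z[i] <- if (s > 0) (log(max(F_obs[i], 1e-300)) - mean(lf)) / s else NA_real_
    }
  }
  col_df <- c(df_term, df_res, n - dfs[1])
  col_ss <- c(SS, SS_res, SS_tot)
  col_ms <- c(SS / df_term, SS_res / df_res, NA_real_)
  col_r2 <- c(SS / SS_tot, SS_res / SS_tot, 1)
  tab <- tibble::tibble(
    term = c(labels, "Residuals", "Total"),
    df = col_df, SS = col_ss, MS = col_ms, r2 = col_r2,
    F = c(F_obs, NA_real_, NA_real_),
    Z = c(Z, NA_real_, NA_real_),
    p = c(p, NA_real_, NA_real_)
  )
  coefs <- {
    Xt <- P %*% X_full
    qr.coef(qr(Xt), Yt)
  }
  structure(
    list(anova = tab, terms = labels, n = n, q = ncol(Y), n_perm = n_perm,
         lambda = if (is.null(cov)) NA_real_ else cov$lambda,
         coefficients = coefs, transformed = list(Y = Yt, X = P %*% X_full,
                                                  P = P),
         flagged = flagged, formula = formula),
    class = "comparative_fit"
  )
}

#' @export
print.comparative_fit <- function(x, ...) {
  cat(sprintf("<comparative_fit> n = %d, q = %d, %d permutations, lambda = %s\n",
              x$n, x$q, x$n_perm,
              ifelse(is.na(x$lambda), "none", format(x$lambda, digits = 4))))
  print(as.data.frame(x$anova), digits = 4)
  invisible(x)
}

#' Pairwise comparison of shape dispersion among groups
#'
#' Group dispersion is the mean Procrustes distance of group members to
#' their group mean, computed on residuals in the PGLS-transformed space
#' (so phylogenetic structure is removed first). For every pair of groups
#' the statistic is the absolute difference of dispersions `d`; `p` comes
#' from randomizing the residual vectors across species, and `Z` is the
#' standard-normal position of `d` in the permuted distribution.
#'
#' @param shapes n x q matrix of (flattened) aligned shapes, or an
#'   `aligned_shapes` object.
#' @param groups Factor of group labels (e.g. diet), length n.
#' @param cov Optional `phylo_covariance` for the PGLS transform.
#' @param n_perm Permutations, observed arrangement included.
#' @param seed Optional integer seed.
#' @param stat `"mean"` (mean distance, default) or `"rms"`
#'   (root-mean-square distance).
#' @return A tibble with one row per unordered group pair:
#'   `group1, group2, d, Z, p`, plus per-group dispersions as attribute
#'   `"dispersion"`. Singleton groups are dropped with a warning.
#' @export
pairwise_dispersion <- function(shapes, groups, cov = NULL, n_perm = 1000,
                                seed = NULL, stat = c("mean", "rms")) {
  stat <- match.arg(stat)
  if (inherits(shapes, "aligned_shapes")) shapes <- .flatten_shapes(shapes$coords)
  Y <- as.matrix(shapes)
  groups <- droplevels(factor(groups))
  n <- nrow(Y)
  stopifnot(length(groups) == n)
  sizes <- table(groups)
  if (any(sizes < 2)) {
    drop <- names(sizes)[sizes < 2]
    warning("dropping singleton group(s): ", paste(drop, collapse = ", "))
    keep <- !(groups %in% drop)
    Y <- Y[keep, , drop = FALSE]
    groups <- droplevels(groups[keep])
    if (!is.null(cov)) {
      cov <- structure(list(taxa = cov$taxa[keep],
                            C = cov$C[keep, keep, drop = FALSE],
                            lambda = cov$lambda), class = "phylo_covariance")
    }
    n <- nrow(Y)
  }
  if (nlevels(groups) < 2) stop("need at least 2 groups of size >= 2",
                                call. = FALSE)
  P <- if (is.null(cov)) diag(n) else .inv_sqrt(cov$C)
  Yt <- P %*% Y
  X <- P %*% stats::model.matrix(~ groups)
  Q <- qr.Q(qr(X))
  R <- Yt - Q %*% crossprod(Q, Yt)
  disp_of <- function(R) {
    d <- sqrt(rowSums(R^2))
    if (stat == "mean") tapply(d, groups, mean) else
      sqrt(tapply(d^2, groups, mean))
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  lv <- levels(groups)
  prs <- utils::combn(lv, 2)
  dmat <- matrix(NA_real_, n_perm, ncol(prs))
  for (r in seq_len(n_perm)) {
    idx <- if (r == 1) seq_len(n) else sample.int(n)
    dd <- disp_of(R[idx, , drop = FALSE])
    dmat[r, ] <- abs(dd[prs[1, ]] - dd[prs[2, ]])
  }
  d_obs <- dmat[1, ]
  p <- colMeans(sweep(dmat, 2, d_obs - 1e-12, `>=`))
  Z <- vapply(seq_len(ncol(prs)), function(j) {
    s <- stats::sd(dmat[, j])
    if (s > 0) (d_obs[j] - mean(dmat[, j])) / s else NA_real_
  }, numeric(1))
  out <- tibble::tibble(group1 = prs[1, ], group2 = prs[2, ],
                        d = d_obs, Z = Z, p = p)
  attr(out, "dispersion") <- disp_of(R)
  out
}

#' Allometric regression scores
#'
#' Fits a PGLS regression of shape on log centroid size and projects each
#' species' centered shape onto the GLS-estimated size-regression vector —
#' the common summary of multivariate allometry plotted against log size.
#' The phylogenetic transform enters through the estimated direction; the
#' projected shapes are the observed ones, so the scores are directly
#' comparable with the species' sizes.
#'
#' @param shapes n x q matrix of flattened aligned shapes, or an
#'   `aligned_shapes` object.
#' @param log_sizes Numeric vector of log centroid sizes, length n.
#' @param cov Optional `phylo_covariance`.
#' @return A tibble `species, log_size, score`; when the fitted regression
#'   vector is (numerically) zero the scores are all zero and the result
#'   carries attribute `"flagged" = TRUE`.
#' @export
allometry_scores <- function(shapes, log_sizes, cov = NULL) {
  labels <- NULL
  if (inherits(shapes, "aligned_shapes")) {
    labels <- dimnames(shapes$coords)[[1]]
    shapes <- .flatten_shapes(shapes$coords)
  }
  Y <- as.matrix(shapes)
  n <- nrow(Y)
  stopifnot(length(log_sizes) == n)
  fit <- pgls_fit(Y, ~ size, data = data.frame(size = log_sizes), cov = cov,
                  n_perm = 99, seed = 1)
  b <- fit$coefficients["size", ]
  nb <- sqrt(sum(b^2))
  flagged <- nb < 1e-10 * max(1, sqrt(mean(Y^2)))
  Yc <- sweep(Y, 2, colMeans(Y))
  score <- if (flagged) rep(0, n) else drop(Yc %*% b) / nb
  out <- tibble::tibble(
    species = labels %||% as.character(seq_len(n)),
    log_size = log_sizes, score = score
  )
  attr(out, "flagged") <- flagged
  out
}
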