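#' Build a regression design from genotype dosages
#'
#' Mean-imputes missing dosages, centres and scales each genotype column to
#' unit variance (zero-variance columns become all-zero), optionally appends
#' covariate columns, and prepends a constant intercept column. Per-sample
#' noise scales (the diagonal of the heteroscedastic error model) default to
#' one, i.e. homoscedastic errors.
#'
#' @param dosages Numeric matrix of additive dosages (samples x SNPs) or a
#'   [genotype_matrix()].
#' @param covariates Optional numeric matrix/data frame of extra columns
#'   (e.g. age, sex); these are carried in the fit but never ranked.
#' @param delta Optional positive per-sample noise scale vector.
#' @return A list of class `design_matrix` with `X` (intercept first),
#'   `delta`, `feature_cols` (column indices of the rankable SNP features in
#'   `X`) and `feature_ids`.
#' @export
build_design <- function(dosages, covariates = NULL, delta = NULL) {
  ids <- NULL
  if (inherits(dosages, "genotype_matrix")) {
    ids <- dosages$snps$id
    dosages <- dosages$values
  }
  dosages <- impute_dosages(as.matrix(dosages))
  if (is.null(ids)) {
    ids <- colnames(dosages) %||% paste0("f", seq_len(ncol(dosages)))
  }
  Xg <- scale(dosages)
  Xg[, attr(Xg, "scaled:scale") == 0] <- 0
  attributes(Xg)[c("scaled:center", "scaled:scale")] <- NULL
  n <- nrow(Xg)
  X <- cbind(`(intercept)` = rep(1, n), Xg)
  colnames(X) <- c("(intercept)", ids)
  feature_cols <- 1L + seq_len(ncol(Xg))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    X <- cbind(X, covariates)
  }
  if (is.null(delta)) delta <- rep(1, n)
  stopifnot(length(delta) == n, all(delta > 0))
  structure(
    list(X = X, delta = delta, feature_cols = feature_cols, feature_ids = ids),
    class = "design_matrix"
  )
}

#' Ridge regression with closed-form error propagation
#'
#' Fits the L2-penalized weighted linear model minimizing
#' \deqn{E^2(m) = (y - Xm)^T \Delta^{-2} (y - Xm) + C\, m^T m,}
#' where \eqn{\Delta} is the diagonal per-sample noise scale. The closed-form
#' minimizer is
#' \deqn{\bar m = (X^T \Delta^{-2} X + C I)^{-1} X^T \Delta^{-2} y,}
#' with coefficient covariance (sandwich form)
#' \deqn{\mathrm{cov}(\bar m) = A^{-1} X^T \Delta^{-2} X\, A^{-1},
#'   \quad A = X^T \Delta^{-2} X + C I,}
#' and residual error
#' \deqn{E^2_{res} = y^T \Delta^{-2} y - (X\bar m)^T \Delta^{-2} (X\bar m)
#'   - C\, \bar m^T \bar m.}
#' The weighted total sum of squares therefore decomposes exactly into the
#' residual, the explained (heritability) term, and the penalty term.
#'
#' When `p > n` the coefficients are computed through the mathematically
#' identical n x n dual system to avoid factorizing a rank-deficient p x p
#' matrix.
#'
#' @param design A [build_design()] object (or a plain numeric matrix, taken
#'   as the full design including any intercept).
#' @param y Numeric response vector (case/control status may be passed
#'   directly as 0/1).
#' @param C Ridge penalty; must be positive when the design is
#'   underdetermined (`p >= n`).
#' @param compute_cov Whether to form the p x p coefficient covariance
#'   (skipped in inner pipeline loops where only coefficients are needed).
#' @return An object of class `ridge_fit` with elements `m_bar`, `C`,
#'   `cov_m`, `e_res2`, `total_weighted_ss`, `fitted`, and `gram`
#'   (\eqn{X^T \Delta^{-2} X}, kept for the heritability scores).
#' @export
ridge_fit <- function(design, y, C = 1, compute_cov = TRUE) {
  if (is.matrix(design)) {
    design <- structure(
      list(
        X = design, delta = rep(1, nrow(design)),
        feature_cols = seq_len(ncol(design)),
        feature_ids = colnames(design) %||% paste0("f", seq_len(ncol(design)))
      ),
      class = "design_matrix"
    )
  }
  X <- design$X
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(length(y) == n, C >= 0)
  if (C == 0 && p >= n) {
    stop("underdetermined system: a positive ridge penalty C is required")
  }
  w <- 1 / design$delta^2
  Xw <- X * w                      # Delta^{-2} X, row-scaled
  xtwy <- drop(crossprod(Xw, y))
  gram <- crossprod(X, Xw)         # X^T Delta^{-2} X
  if (p <= n) {
    A <- gram
    diag(A) <- diag(A) + C
    m_bar <- tryCatch(
      drop(solve(A, xtwy)),
      error = function(e) stop(
        "singular normal equations; use a positive ridge penalty C"
      )
    )
  } else {
    # dual form: with Z = Delta^{-1} X, t = Delta^{-1} y,
    # m = Z^T (Z Z^T + C I)^{-1} t
    sw <- sqrt(w)
    Z <- X * sw
    K <- tcrossprod(Z)
    diag(K) <- diag(K) + C
    m_bar <- drop(crossprod(Z, solve(K, y * sw)))
  }
  names(m_bar) <- colnames(X)
  fitted <- drop(X %*% m_bar)
  total <- sum(w * y^2)
  explained <- sum(w * fitted^2)
  e_res2 <- total - explained - C * sum(m_bar^2)
  cov_m <- NULL
  if (compute_cov) {
    A <- gram
    diag(A) <- diag(A) + C
    Ainv <- solve(A)
    cov_m <- Ainv %*% gram %*% Ainv
    cov_m <- (cov_m + t(cov_m)) / 2
  }
  structure(
    list(
      m_bar = m_bar, C = C, cov_m = cov_m, e_res2 = e_res2,
      total_weighted_ss = total, explained_ss = explained,
      fitted = fitted, gram = gram, design = design, y = y
    ),
    class = "ridge_fit"
  )
}

#' @export
print.ridge_fit <- function(x, ...) {
  cat(
    "<ridge_fit> p = ", length(x$m_bar), ", C = ", x$C,
    ", residual = ", signif(x$e_res2, 4),
    " of total ", signif(x$total_weighted_ss, 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Penalized error of an arbitrary coefficient vector
#'
#' Evaluates \eqn{E^2(m) = (y - Xm)^T \Delta^{-2} (y - Xm) + C m^T m}.
#'
#' @param design A [build_design()] object or design matrix.
#' @param y Response vector.
#' @param m Coefficient vector.
#' @param C Ridge penalty.
#' @return The scalar penalized error.
#' @export
ridge_objective <- function(design, y, m, C) {
  X <- if (is.matrix(design)) design else design$X
  delta <- if (is.matrix(design)) rep(1, nrow(X)) else design$delta
  r <- y - drop(X %*% m)
  sum(r^2 / delta^2) + C * sum(m^2)
}

#' Check the exact quadratic error decomposition
#'
#' For any coefficient vector m, the penalized error decomposes around the
#' ridge minimizer as
#' \deqn{E^2(m) = E^2_{res} + (m - \bar m)^T (X^T \Delta^{-2} X + C I)
#'   (m - \bar m).}
#' Returns the absolute discrepancy of this identity, which should be at the
#' level of floating-point round-off relative to the magnitude of the terms.
#'
#' @param fit A [ridge_fit()].
#' @param m Any coefficient vector of matching length.
#' @return Absolute residual of the identity (a non-negative scalar).
#' @export
error_decomposition_check <- function(fit, m) {
  stopifnot(length(m) == length(fit$m_bar))
  lhs <- ridge_objective(fit$design, fit$y, m, fit$C)
  d <- m - fit$m_bar
  quad <- drop(crossprod(d, fit$gram %*% d)) + fit$C * sum(d^2)
  abs(lhs - (fit$e_res2 + quad))
}

#' Per-feature heritability scores from a ridge fit
#'
#' The explained weighted sum of squares \eqn{(X\bar m)^T \Delta^{-2}
#' (X\bar m)} expands as \eqn{\bar m^T (X^T \Delta^{-2} X) \bar m}; its
#' diagonal contributions
#' \deqn{h_j = \bar m_j^2 \; x_j^T \Delta^{-2} x_j}
#' are taken as each feature's share of the explained variation
#' ("heritability") and used for ranking. Off-diagonal cross terms between
#' correlated features are deliberately excluded — correlated features cannot
#' be credited independently, which is why LD pruning precedes ranking — but
#' can be included via `cross_terms = TRUE`, giving
#' \eqn{h_j = \bar m_j x_j^T \Delta^{-2} X \bar m}. The intercept (and any
#' covariate columns) never receives a score.
#'
#' @param fit A [ridge_fit()].
#' @param cross_terms Include off-diagonal LD cross terms in each feature's
#'   score (default `FALSE`).
#' @return Named numeric vector `h` over the rankable features.
#' @export
feature_heritability <- function(fit, cross_terms = FALSE) {
  cols <- fit$design$feature_cols
  m <- fit$m_bar
  if (cross_terms) {
    h <- m * drop(fit$gram %*% m)
  } else {
    h <- m^2 * diag(fit$gram)
  }
  h <- h[cols]
  names(h) <- fit$design$feature_ids
  h
}

#' Rank features by decreasing heritability score
#'
#' Produces the permutation placing the largest score first; ties keep the
#' original column order (stable sort).
#'
#' @param h Numeric vector of per-feature scores.
#' @return Integer vector `sigma_inv`: position k holds the index of the
#'   k-th ranked feature, with attribute `sigma` (each feature's rank).
#' @export
rank_features <- function(h) {
  if (any(is.na(h))) stop("NaN/NA heritability score; cannot rank")
  sigma_inv <- order(-h, seq_along(h))
  sigma <- integer(length(h))
  sigma[sigma_inv] <- seq_along(h)
  attr(sigma_inv, "sigma") <- sigma
  sigma_inv
}

#' Rank SNPs by fold-averaged heritability under balanced splits
#'
#' Draws `n_folds` class-balanced train/test splits of the working samples,
#' fits the ridge model on each training part (columns standardized within
#' the fold), computes per-fold heritability scores, averages them across
#' folds, and ranks SNPs by the averaged score.
#'
#' @param dosages Dosage matrix or [genotype_matrix()] of the working
#'   samples.
#' @param status 0/1 phenotype vector.
#' @param n_folds Number of ranking splits.
#' @param s_test Test fraction per split (the test part is unused by the
#'   ridge fit; splitting simply perturbs the training sample).
#' @param C Ridge penalty on the standardized design.
#' @param seed Integer seed.
#' @param covariates,cross_terms Passed through to [build_design()] and
#'   [feature_heritability()].
#' @return A tibble (class `snp_ranking`): `snp_id`, `mean_heritability`,
#'   `rank`, in original column order; attribute `sigma_inv` holds the
#'   ranked-order indices.
#' @export
rank_by_folds <- function(dosages, status, n_folds = 5, s_test = 0.2, C = 1,
                          seed = 1L, covariates = NULL, cross_terms = FALSE) {
  values <- if (inherits(dosages, "genotype_matrix")) dosages$values else dosages
  ids <- if (inherits(dosages, "genotype_matrix")) {
    dosages$snps$id
  } else {
    colnames(values) %||% paste0("f", seq_len(ncol(values)))
  }
  stopifnot(n_folds >= 1, s_test > 0, s_test < 1)
  local_rng(seed)
  scores <- matrix(0, n_folds, ncol(values))
  for (i in seq_len(n_folds)) {
    split <- balanced_split(status, s_test)
    tr <- split$train
    design <- build_design(
      values[tr, , drop = FALSE],
      covariates = if (is.null(covariates)) NULL else covariates[tr, , drop = FALSE]
    )
    design$feature_ids <- ids
    fit <- ridge_fit(design, status[tr], C = C, compute_cov = FALSE)
    scores[i, ] <- feature_heritability(fit, cross_terms = cross_terms)
  }
  c_j <- colMeans(scores)
  sigma_inv <- rank_features(c_j)
  out <- tibble::new_tibble(
    tibble::tibble(
      snp_id = ids,
      mean_heritability = c_j,
      rank = attr(sigma_inv, "sigma")
    ),
    class = "snp_ranking"
  )
  attr(out, "sigma_inv") <- as.integer(sigma_inv)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
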