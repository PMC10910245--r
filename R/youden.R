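#' Youden's J statistic from confusion counts
#'
#' \eqn{J = } sensitivity \eqn{-} false positive rate \eqn{=} sensitivity
#' \eqn{+} specificity \eqn{- 1}; the chance-corrected performance of a
#' classifier at a single operating point, in \eqn{[-1, 1]}.
#'
#' @param tp,fn,tn,fp Confusion counts (true/false positives/negatives).
#' @return The scalar J.
#' @export
youden_index <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  if (tp + fn == 0 || tn + fp == 0) {
    stop("youden_index requires at least one positive and one negative label")
  }
  tp / (tp + fn) + tn / (tn + fp) - 1
}

# Confusion counts of predicted vs true 0/1 labels.
confusion_counts <- function(truth, pred) {
  list(
    tp = sum(truth == 1 & pred == 1),
    fn = sum(truth == 1 & pred == 0),
    tn = sum(truth == 0 & pred == 0),
    fp = sum(truth == 0 & pred == 1)
  )
}

#' Class-balanced train/test split
#'
#' Samples the test set stratified by class so its case/control proportion
#' matches the full label vector up to rounding. Consumes the session RNG
#' stream (seed it with the caller's scheme).
#'
#' @param labels 0/1 vector.
#' @param test_fraction Fraction of samples assigned to the test part.
#' @return List of integer index vectors `train` and `test` (disjoint,
#'   covering).
#' @export
balanced_split <- function(labels, test_fraction) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  cases <- which(labels == 1)
  controls <- which(labels == 0)
  if (length(cases) == 0 || length(controls) == 0) {
    stop("balanced_split requires both classes")
  }
  n_tc <- round(length(cases) * test_fraction)
  n_tk <- round(length(controls) * test_fraction)
  if (n_tc < 1 || n_tk < 1 ||
      n_tc >= length(cases) || n_tk >= length(controls)) {
    stop("a class is too small to appear in both train and test parts")
  }
  test <- sort(c(sample(cases, n_tc), sample(controls, n_tk)))
  list(train = setdiff(seq_along(labels), test), test = test)
}

#' Nested feature subsets from a ranking
#'
#' With increment \eqn{\lfloor p / n_{steps} \rfloor}, subset i (1-based)
#' holds the top `i * increment` ranked features; the last subset is
#' completed to all features so nothing is dropped when p is not divisible
#' by the step count.
#'
#' @param sigma_inv Ranked-order feature indices (best first), e.g.
#'   `attr(rank_by_folds(...), "sigma_inv")` or a `snp_ranking` tibble.
#' @param n_steps Number of curve steps; at most the number of features.
#' @return List of integer vectors, each a prefix of the ranked order.
#' @export
build_nested_subsets <- function(sigma_inv, n_steps) {
  if (inherits(sigma_inv, "snp_ranking")) {
    sigma_inv <- attr(sigma_inv, "sigma_inv")
  }
  p <- length(sigma_inv)
  if (n_steps < 1 || n_steps > p) {
    stop("n_steps must be between 1 and the number of features")
  }
  inc <- p %/% n_steps
  sizes <- pmin(seq_len(n_steps) * inc, p)
  sizes[n_steps] <- p
  lapply(sizes, function(k) sigma_inv[seq_len(k)])
}

# Fit a linear-kernel maximum-margin classifier and return 0/1 predictions
# on newx, plus the signed decision values. Degenerate training columns are
# tolerated (design is pre-standardized; scale = FALSE). The KKT tolerance
# is loosened to 0.01: confusion counts are insensitive to decision-value
# shifts at that scale and the solver converges substantially faster.
svm_linear_predict <- function(x, y, newx, cost = 1) {
  fit <- e1071::svm(
    x = x, y = factor(y, levels = c(0, 1)),
    kernel = "linear", cost = cost, scale = FALSE, tolerance = 0.01
  )
  # linear kernel: predict through the primal weight vector w = SV' alpha,
  # avoiding the O(n_test x n_SV x d) kernel evaluation of predict()
  w <- drop(crossprod(fit$SV, fit$coefs))
  dv <- drop(newx %*% w) - fit$rho
  # libsvm orients the decision value toward the first training label
  first <- fit$levels[fit$labels[1]]
  cls <- ifelse(dv > 0, first, setdiff(fit$levels, first))
  if (first == "1") dv <- -dv  # flip so larger always means class "1"
  list(class = as.integer(cls), decision = -dv)
}

#' Score nested feature subsets with a Youden curve
#'
#' For each of `m_folds` class-balanced splits of the working samples and
#' each nested subset, fits a linear-kernel SVM on the training rows
#' restricted to the subset's columns, predicts the held-out rows at the
#' classifier's native decision threshold, and records the Youden J. The
#' curve is the fold-average at each step. A degenerate subset (all-constant
#' training columns) scores 0 for that fold with a warning.
#'
#' @param dosages Dosage matrix or [genotype_matrix()] of working samples.
#' @param status 0/1 labels.
#' @param subsets List of feature-index vectors from
#'   [build_nested_subsets()].
#' @param m_folds Number of scoring splits.
#' @param t_test Test fraction per split.
#' @param seed Integer seed (scoring splits are independent of ranking
#'   splits).
#' @param cost SVM regularization cost (library default 1).
#' @param splits Optional list of pre-drawn splits (each a list with `train`
#'   and `test` index vectors) overriding the seeded draw; its length
#'   overrides `m_folds`.
#' @return A tibble of class `youden_curve`: `step`, `subset_size`,
#'   `mean_J`, `is_cutoff`; attributes `fold_scores` (steps x folds matrix),
#'   `cutoff_index`, `selected_features`, `subsets`.
#' @export
score_subsets <- function(dosages, status, subsets, m_folds = 5, t_test = 0.2,
                          seed = 1L, cost = 1, splits = NULL) {
  values <- if (inherits(dosages, "genotype_matrix")) dosages$values else dosages
  stopifnot(m_folds >= 1, length(subsets) >= 1)
  local_rng(seed)
  if (!is.null(splits)) m_folds <- length(splits)
  X <- build_design(values)$X[, -1, drop = FALSE] # standardized, no intercept
  n_steps <- length(subsets)
  fold_scores <- matrix(NA_real_, n_steps, m_folds)
  for (r in seq_len(m_folds)) {
    split <- if (is.null(splits)) balanced_split(status, t_test) else splits[[r]]
    for (i in seq_len(n_steps)) {
      cols <- subsets[[i]]
      xtr <- X[split$train, cols, drop = FALSE]
      xte <- X[split$test, cols, drop = FALSE]
      fold_scores[i, r] <- tryCatch(
        {
          pred <- svm_linear_predict(xtr, status[split$train], xte, cost = cost)
          cc <- confusion_counts(status[split$test], pred$class)
          youden_index(cc$tp, cc$fn, cc$tn, cc$fp)
        },
        error = function(e) {
          warning(
            "degenerate subset at step ", i, ", fold ", r,
            ": scoring 0 (", conditionMessage(e), ")"
          )
          0
        }
      )
    }
  }
  mean_J <- rowMeans(fold_scores)
  cutoff <- first_local_maximum(mean_J)
  out <- tibble::new_tibble(
    tibble::tibble(
      step = seq_len(n_steps),
      subset_size = lengths(subsets),
      mean_J = mean_J,
      is_cutoff = seq_len(n_steps) == cutoff
    ),
    class = "youden_curve"
  )
  attr(out, "fold_scores") <- fold_scores
  attr(out, "cutoff_index") <- cutoff
  attr(out, "selected_features") <- subsets[[cutoff]]
  attr(out, "subsets") <- subsets
  out
}

#' First local maximum of a Youden curve
#'
#' Scans left to right for the smallest interior index j with
#' `K[j-1] <= K[j] >= K[j+1]` (the first index of a plateau wins). If no
#' interior local maximum exists — e.g. a monotone curve — the first global
#' argmax is returned.
#'
#' @param k Numeric vector of curve values (or a `youden_curve` tibble).
#' @return The 1-based cutoff index.
#' @export
first_local_maximum <- function(k) {
  if (inherits(k, "youden_curve")) k <- k$mean_J
  n <- length(k)
  if (n == 0) stop("empty curve")
  if (n >= 3) {
    for (j in 2:(n - 1)) {
      if (k[j - 1] <= k[j] && k[j] >= k[j + 1]) return(j)
    }
  }
  which.max(k)
}

#' Features selected at the curve cutoff
#'
#' The selected set is the nested subset at the cutoff step: all features
#' ranked at or before the first local maximum of the Youden curve.
#'
#' @param subsets List from [build_nested_subsets()], or a `youden_curve`.
#' @param cutoff_index Cutoff step (defaults to the curve's stored cutoff).
#' @return Integer vector of selected feature indices.
#' @export
selected_before_cutoff <- function(subsets, cutoff_index = NULL) {
  if (inherits(subsets, "youden_curve")) {
    if (is.null(cutoff_index)) cutoff_index <- attr(subsets, "cutoff_index")
    subsets <- attr(subsets, "subsets")
  }
  stopifnot(
    !is.null(cutoff_index),
    cutoff_index >= 1, cutoff_index <= length(subsets)
  )
  subsets[[cutoff_index]]
}
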