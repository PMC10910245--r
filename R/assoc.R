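#' Per-SNP logistic regression association test
#'
#' Maximum-likelihood logistic regression of case/control status on a single
#' SNP's additive dosage (plus optional covariates), with a Wald p-value on
#' the dosage coefficient and the odds ratio per alternate-allele copy.
#' Complete or quasi-complete separation is flagged: the result row carries
#' `converged = FALSE` and `p_value = NA`.
#'
#' @param dosage Numeric dosage vector for one SNP; must be non-constant.
#' @param status 0/1 phenotype vector; both classes must be present.
#' @param covariates Optional numeric matrix/data frame of adjustment
#'   columns.
#' @param snp_id Label carried into the result.
#' @return One-row tibble: `snp_id`, `odds_ratio`, `log_or`, `se_log_or`,
#'   `p_value`, `converged`, `method = "logistic"`.
#' @export
logistic_assoc <- function(dosage, status, covariates = NULL,
                           snp_id = "snp") {
  if (stats::var(dosage, na.rm = TRUE) == 0 || all(is.na(dosage))) {
    stop("constant dosage: logistic association is undefined")
  }
  if (length(unique(status)) < 2) stop("both classes must be present")
  df <- data.frame(status = status, g = dosage)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  fit <- suppressWarnings(
    stats::glm(status ~ ., data = df, family = stats::binomial())
  )
  co <- summary(fit)$coefficients
  est <- co["g", "Estimate"]
  se <- co["g", "Std. Error"]
  # quasi-separation: divergent estimate or exploding Wald SE
  converged <- fit$converged && is.finite(est) && is.finite(se) &&
    abs(est) < 15 && se < 100
  tibble::tibble(
    snp_id = snp_id,
    odds_ratio = exp(est),
    log_or = est,
    se_log_or = se,
    p_value = if (converged) co["g", "Pr(>|z|)"] else NA_real_,
    converged = converged,
    method = "logistic"
  )
}

#' Logistic association for every SNP in a matrix
#'
#' @param dosages Dosage matrix or [genotype_matrix()].
#' @param status 0/1 phenotype vector.
#' @param covariates Optional adjustment columns.
#' @return A tibble with one row per non-constant SNP (constant SNPs are
#'   skipped with a message).
#' @export
assoc_scan <- function(dosages, status, covariates = NULL) {
  values <- if (inherits(dosages, "genotype_matrix")) dosages$values else dosages
  ids <- if (inherits(dosages, "genotype_matrix")) {
    dosages$snps$id
  } else {
    colnames(values) %||% paste0("f", seq_len(ncol(values)))
  }
  values <- impute_dosages(values)
  keep <- apply(values, 2, stats::var) > 0
  if (any(!keep)) {
    message("assoc_scan: skipping ", sum(!keep), " constant SNP(s)")
  }
  purrr::map_dfr(which(keep), function(j) {
    logistic_assoc(values[, j], status, covariates, snp_id = ids[j])
  })
}

#' Odds-ratio inference from a 2x2 disease-by-exposure table
#'
#' The sampling distribution of the log odds ratio
#' \eqn{\log(n_{DE} n_{\bar D\bar E} / (n_{D\bar E} n_{\bar D E}))} is
#' approximately normal with variance
#' \eqn{\sigma^2 = 1/n_{DE} + 1/n_{\bar D\bar E} + 1/n_{D\bar E} +
#' 1/n_{\bar D E}}; the two-sided p-value is computed from the normal tail.
#' If any cell is zero, the Haldane-Anscombe correction adds 0.5 to all four
#' cells and the result is flagged.
#'
#' @param n_de Cases exposed. @param n_nde Controls unexposed.
#' @param n_dne Cases unexposed. @param n_nd_e Controls exposed.
#' @param snp_id Label carried into the result.
#' @return One-row tibble: `snp_id`, `odds_ratio`, `log_or`, `se_log_or`,
#'   `p_value`, `corrected` (whether the 0.5 correction was applied),
#'   `method = "contingency"`.
#' @export
contingency_or_test <- function(n_de, n_nde, n_dne, n_nd_e, snp_id = "snp") {
  cells <- c(n_de, n_nde, n_dne, n_nd_e)
  if (any(cells < 0)) stop("contingency cells must be non-negative")
  if (sum(cells) == 0) stop("empty contingency table")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  log_or <- log(cells[1] * cells[2] / (cells[3] * cells[4]))
  se <- sqrt(sum(1 / cells))
  p <- 2 * stats::pnorm(abs(log_or) / se, lower.tail = FALSE)
  tibble::tibble(
    snp_id = snp_id,
    odds_ratio = exp(log_or),
    log_or = log_or,
    se_log_or = se,
    p_value = p,
    corrected = corrected,
    method = "contingency"
  )
}

# AUC as the Mann-Whitney probability that a random case outranks a random
# control on the decision score.
rank_auc <- function(truth, score) {
  pos <- score[truth == 1]
  neg <- score[truth == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Predictivity of a feature set via linear-kernel SVM
#'
#' Over `m_folds` class-balanced splits, fits a linear-kernel SVM on the
#' training rows restricted to the selected columns and evaluates the
#' held-out rows, reporting fold-averaged precision, recall, F1 (harmonic
#' mean of precision and recall) and AUC (from the ranking of the
#' classifier's decision values).
#'
#' @param dosages Dosage matrix or [genotype_matrix()].
#' @param status 0/1 phenotype vector.
#' @param features Columns to use: integer indices or SNP ids; must be
#'   non-empty.
#' @param m_folds,t_test Scoring splits and test fraction.
#' @param seed Integer seed.
#' @param cost SVM regularization cost.
#' @return One-row tibble: `f1`, `auc`, `precision`, `recall`, `n_features`,
#'   `m_folds`.
#' @export
evaluate_predictivity <- function(dosages, status, features, m_folds = 5,
                                  t_test = 0.2, seed = 1L, cost = 1) {
  values <- if (inherits(dosages, "genotype_matrix")) dosages$values else dosages
  ids <- if (inherits(dosages, "genotype_matrix")) {
    dosages$snps$id
  } else {
    colnames(values) %||% paste0("f", seq_len(ncol(values)))
  }
  if (is.character(features)) features <- match(features, ids)
  features <- features[!is.na(features)]
  if (length(features) == 0) stop("empty feature selection")
  local_rng(seed)
  X <- build_design(values)$X[, -1, drop = FALSE][, features, drop = FALSE]
  prec <- rec <- f1 <- auc <- numeric(m_folds)
  for (r in seq_len(m_folds)) {
    split <- balanced_split(status, t_test)
    pred <- svm_linear_predict(
      X[split$train, , drop = FALSE], status[split$train],
      X[split$test, , drop = FALSE],
      cost = cost
    )
    truth <- status[split$test]
    cc <- confusion_counts(truth, pred$class)
    prec[r] <- if (cc$tp + cc$fp > 0) cc$tp / (cc$tp + cc$fp) else 0
    rec[r] <- if (cc$tp + cc$fn > 0) cc$tp / (cc$tp + cc$fn) else 0
    f1[r] <- if (prec[r] + rec[r] > 0) {
      2 * prec[r] * rec[r] / (prec[r] + rec[r])
    } else {
      0
    }
    auc[r] <- rank_auc(truth, pred$decision)
  }
  tibble::tibble(
    f1 = mean(f1), auc = mean(auc),
    precision = mean(prec), recall = mean(rec),
    n_features = length(features), m_folds = m_folds
  )
}

#' Subset SNPs by association significance
#'
#' @param assoc Tibble of association results (needs `snp_id`, `p_value`).
#' @param neg_log_p_min Keep SNPs with `-log10(p) > neg_log_p_min`.
#' @return Character vector of SNP ids.
#' @export
subset_by_significance <- function(assoc, neg_log_p_min) {
  keep <- !is.na(assoc$p_value) & -log10(assoc$p_value) > neg_log_p_min
  assoc$snp_id[keep]
}

#' Select non-neutral PRS weights by histogram occupancy
#'
#' Polygenic-score weight vectors concentrate in a large spike of
#' near-neutral effects around zero. Binning the weights into `n_bins`
#' equal-width bins over their range, the spike occupies a few heavily
#' populated bins while real effects sit in sparse tail bins; all SNPs in
#' bins holding less than `bin_fraction_max` of the SNPs are selected.
#'
#' @param weights Tibble/data frame with columns `snp_id` and `beta`, or a
#'   named numeric vector of weights.
#' @param n_bins Number of equal-width histogram bins (default 50).
#' @param bin_fraction_max Occupancy-fraction ceiling for a selected bin
#'   (default 2e-4).
#' @return Character vector of selected SNP ids (empty when no bin
#'   qualifies, e.g. a zero-width weight range).
#' @export
select_by_beta_histogram <- function(weights, n_bins = 50,
                                     bin_fraction_max = 2e-4) {
  if (is.numeric(weights)) {
    weights <- tibble::tibble(
      snp_id = names(weights) %||% as.character(seq_along(weights)),
      beta = unname(weights)
    )
  }
  beta <- weights$beta
  if (length(beta) == 0) stop("empty weight vector")
  if (any(!is.finite(beta))) stop("non-finite PRS weights")
  if (n_bins < 2) stop("n_bins must be at least 2")
  rng <- range(beta)
  if (rng[1] == rng[2]) return(character(0))
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(beta, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  frac <- tabulate(bin, nbins = n_bins) / length(beta)
  weights$snp_id[frac[bin] < bin_fraction_max]
}

#' Select PRS weights by absolute magnitude
#'
#' Alternative to the histogram rule: keep SNPs whose |weight| exceeds a
#' floor, discarding the near-neutral spike directly.
#'
#' @param weights As in [select_by_beta_histogram()].
#' @param beta_min Magnitude floor (default 2e-4).
#' @return Character vector of selected SNP ids.
#' @export
select_by_beta_magnitude <- function(weights, beta_min = 2e-4) {
  if (is.numeric(weights)) {
    weights <- tibble::tibble(
      snp_id = names(weights) %||% as.character(seq_along(weights)),
      beta = unname(weights)
    )
  }
  weights$snp_id[abs(weights$beta) > beta_min]
}
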