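#' Pipeline configuration for replicated selection
#'
#' @param n_folds Ranking fold count.
#' @param s_test Ranking test fraction.
#' @param m_folds Scoring fold count.
#' @param t_test Scoring test fraction.
#' @param n_steps Youden curve step count.
#' @param C Ridge penalty.
#' @param n_iterations Outer replication count N (support is counted out of
#'   N; default 50).
#' @param svm_cost Linear-SVM regularization cost.
#' @param seed Master seed; every replication derives its own ranking and
#'   scoring seeds from it by a fixed counter scheme.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_folds = 5, s_test = 0.2, m_folds = 5,
                            t_test = 0.2, n_steps = 100, C = 1,
                            n_iterations = 50, svm_cost = 1, seed = 1L) {
  stopifnot(
    n_folds >= 1, m_folds >= 1, n_steps >= 1, n_iterations >= 1,
    s_test > 0, s_test < 1, t_test > 0, t_test < 1, C >= 0, svm_cost > 0
  )
  structure(
    list(
      n_folds = as.integer(n_folds), s_test = s_test,
      m_folds = as.integer(m_folds), t_test = t_test,
      n_steps = as.integer(n_steps), C = C,
      n_iterations = as.integer(n_iterations), svm_cost = svm_cost,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Replicated feature selection with support counting
#'
#' Runs N independent replications of the inner pipeline on the working
#' samples — rank SNPs by fold-averaged ridge heritability, build nested
#' subsets, score them into a Youden curve, cut at the first local maximum —
#' and counts, for every SNP, the number of replications whose cutoff set
#' contained it ("support"). Replication r uses seeds derived from the
#' master seed and r, so the whole table is reproducible bit for bit.
#'
#' @param dosages Dosage matrix or [genotype_matrix()] of working samples.
#' @param status 0/1 phenotype vector for the same samples.
#' @param config A [pipeline_config()].
#' @param covariates Optional covariate matrix passed to the ranking stage.
#' @return A tibble of class `support_table`: `snp_id`, `support`,
#'   `n_iterations`, sorted by decreasing support (ties in SNP order);
#'   attributes `selected_sets` (list of per-replication index sets) and
#'   `cutoffs` (per-replication cutoff step).
#' @export
run_stability <- function(dosages, status, config = pipeline_config(),
                          covariates = NULL) {
  values <- if (inherits(dosages, "genotype_matrix")) dosages$values else dosages
  ids <- if (inherits(dosages, "genotype_matrix")) {
    dosages$snps$id
  } else {
    colnames(values) %||% paste0("f", seq_len(ncol(values)))
  }
  p <- ncol(values)
  n_steps <- min(config$n_steps, p)
  support <- integer(p)
  selected_sets <- vector("list", config$n_iterations)
  cutoffs <- integer(config$n_iterations)
  for (r in seq_len(config$n_iterations)) {
    res <- tryCatch(
      {
        ranking <- rank_by_folds(
          values, status,
          n_folds = config$n_folds, s_test = config$s_test, C = config$C,
          seed = derive_seed(config$seed, 2L * r),
          covariates = covariates
        )
        subsets <- build_nested_subsets(ranking, n_steps)
        curve <- score_subsets(
          values, status, subsets,
          m_folds = config$m_folds, t_test = config$t_test,
          seed = derive_seed(config$seed, 2L * r + 1L),
          cost = config$svm_cost
        )
        list(
          selected = selected_before_cutoff(curve),
          cutoff = attr(curve, "cutoff_index")
        )
      },
      error = function(e) {
        stop("replication ", r, " failed: ", conditionMessage(e))
      }
    )
    selected_sets[[r]] <- res$selected
    cutoffs[r] <- res$cutoff
    support[res$selected] <- support[res$selected] + 1L
  }
  out <- tibble::new_tibble(
    tibble::tibble(
      snp_id = ids, support = support,
      n_iterations = config$n_iterations
    )[order(-support, seq_len(p)), ],
    class = "support_table"
  )
  attr(out, "selected_sets") <- selected_sets
  attr(out, "cutoffs") <- cutoffs
  attr(out, "snp_index") <- stats::setNames(seq_len(p), ids)
  out
}

#' Stable SNP set at a support threshold
#'
#' @param support A `support_table` from [run_stability()].
#' @param threshold Minimum support, between 0 and the replication count N
#'   (the conventional cut is 0.8 N, e.g. 40 of 50).
#' @return Character vector of SNP ids with `support >= threshold`.
#' @export
stable_set <- function(support, threshold) {
  n_iter <- support$n_iterations[1]
  if (threshold < 0 || threshold > n_iter) {
    stop("threshold must be between 0 and n_iterations (", n_iter, ")")
  }
  support$snp_id[support$support >= threshold]
}

#' Expected fraction of true positives after N replications
#'
#' Under a two-type error model — a fraction f of SNPs is biologically
#' active, the per-replication selection falsely identifies an inactive SNP
#' with probability \eqn{\alpha} and rejects an active one with probability
#' \eqn{\beta} — the fraction of SNPs supported in all N replications that
#' are truly active is
#' \deqn{\frac{f (1-\beta)^N}{f (1-\beta)^N + (1-f)\,\alpha^N},}
#' which tends to 1 for large N whenever \eqn{1 - \beta > \alpha}.
#'
#' @param f Fraction of biologically active SNPs.
#' @param alpha Per-replication false-identification probability.
#' @param beta Per-replication rejection probability for an active SNP.
#' @param n_replications N.
#' @return The expected true-positive fraction, in [0, 1].
#' @export
expected_true_positive_fraction <- function(f, alpha, beta, n_replications) {
  stopifnot(
    f >= 0, f <= 1, alpha >= 0, alpha <= 1, beta >= 0, beta <= 1,
    n_replications >= 0
  )
  num <- f * (1 - beta)^n_replications
  den <- num + (1 - f) * alpha^n_replications
  if (den == 0) stop("degenerate 0/0: no SNP can survive all replications")
  num / den
}

#' Write a support table as TSV
#'
#' @param support A `support_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_support <- function(support, path) {
  utils::write.table(
    as.data.frame(support[, c("snp_id", "support", "n_iterations")]),
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
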