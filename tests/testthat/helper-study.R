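# Synthetic study harness shared by the recovery/null/contrast tests.
#
# Study scale (see the methods vignette): preset cohorts of 600 samples x
# 500 SNPs; ranking over 5 half-sample folds; scoring over 2 splits with
# 65% test parts; 20 curve steps; 20 replications (10 for the weak-signal
# contrast). Heavy runs are cached per (preset, seed, shuffle, N) so that
# different properties of the same study never recompute it.

study_config <- function(seed, n_iterations = 20) {
  pipeline_config(
    n_folds = 5, s_test = 0.5, m_folds = 2, t_test = 0.65,
    n_steps = 20, C = 1, n_iterations = n_iterations, seed = seed
  )
}

.study_cache <- new.env(parent = emptyenv())

# One full study: simulate the preset cohort, optionally shuffle phenotypes
# (the null control), optionally reserve a validation sixth, run replicated
# selection on the working samples.
study_run <- function(preset, seed, shuffle = FALSE, n_iterations = 20,
                      holdout = FALSE) {
  key <- paste(preset, seed, shuffle, n_iterations, holdout, sep = "|")
  if (!exists(key, envir = .study_cache)) {
    cohort <- simulate_cohort(
      cohort_preset(preset, n_samples = 600, n_snps = 500, seed = seed)
    )
    status <- cohort$phenotypes$status
    if (shuffle) {
      status <- shuffle_phenotypes(cohort$phenotypes, seed + 5000)$status
    }
    if (holdout) {
      split <- split_working_validation(status, 1 / 6, seed = seed + 6000)
    } else {
      split <- list(working = seq_along(status), validation = integer())
    }
    support <- run_stability(
      cohort$genotypes[split$working, ], status[split$working],
      study_config(seed + 77, n_iterations)
    )
    assign(key, list(
      cohort = cohort, status = status, split = split, support = support,
      n_iterations = n_iterations
    ), envir = .study_cache)
  }
  get(key, envir = .study_cache)
}

causal_support <- function(run) {
  run$support$support[match(run$cohort$truth$snp_id, run$support$snp_id)]
}

null_support <- function(run) {
  run$support$support[!(run$support$snp_id %in% run$cohort$truth$snp_id)]
}

# The replication-selected feature sets used in predictivity contrasts:
# everything that ever survived a cutoff, and the high-support subset
# (falling back to the most-supported SNPs when the threshold empties,
# the analogue of contrasting against the strongest available support).
selected_sets <- function(run, top_fraction = 0.9) {
  full <- stable_set(run$support, 1)
  thr <- ceiling(top_fraction * run$n_iterations)
  top <- stable_set(run$support, thr)
  if (length(top) == 0) {
    top <- stable_set(run$support, max(run$support$support))
  }
  list(full = full, top = top)
}

# Monte-Carlo 99% chance band for the held-out F1 of fixed predictions:
# permute the truth labels and recompute F1.
f1_chance_band <- function(truth, predicted, n_perm = 2000, seed = 1) {
  f1_of <- function(truth, pred) {
    tp <- sum(truth == 1 & pred == 1)
    fp <- sum(truth == 0 & pred == 1)
    fn <- sum(truth == 1 & pred == 0)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  sims <- withr::with_seed(seed, {
    replicate(n_perm, f1_of(sample(truth), predicted))
  })
  stats::quantile(sims, c(0.005, 0.995), names = FALSE)
}
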