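#' Final predictivity on a held-out split
#'
#' Fits the linear-kernel SVM once on the training rows and evaluates the
#' held-out rows — the single end-of-pipeline scoring of the untouched
#' validation samples (contrast with [evaluate_predictivity()], which
#' cross-validates inside the working set).
#'
#' @param dosages Dosage matrix or [genotype_matrix()] over all samples.
#' @param status 0/1 phenotype vector.
#' @param features Columns to use (indices or SNP ids), non-empty.
#' @param train_idx,test_idx Row index vectors (e.g. the working and
#'   validation parts of [split_working_validation()]).
#' @param cost SVM regularization cost.
#' @return One-row tibble: `f1`, `auc`, `precision`, `recall`,
#'   `n_features`, `n_train`, `n_test`; attribute `predictions` holds the
#'   per-sample held-out predictions.
#' @export
evaluate_holdout <- function(dosages, status, features, train_idx, test_idx,
                             cost = 1) {
  values <- if (inherits(dosages, "genotype_matrix")) dosages$values else dosages
  ids <- if (inherits(dosages, "genotype_matrix")) {
    dosages$snps$id
  } else {
    colnames(values) %||% paste0("f", seq_len(ncol(values)))
  }
  if (is.character(features)) features <- match(features, ids)
  features <- features[!is.na(features)]
  if (length(features) == 0) stop("empty feature selection")
  if (length(intersect(train_idx, test_idx)) > 0) {
    stop("train and test indices overlap")
  }
  X <- build_design(values)$X[, -1, drop = FALSE][, features, drop = FALSE]
  pred <- svm_linear_predict(
    X[train_idx, , drop = FALSE], status[train_idx],
    X[test_idx, , drop = FALSE],
    cost = cost
  )
  truth <- status[test_idx]
  cc <- confusion_counts(truth, pred$class)
  prec <- if (cc$tp + cc$fp > 0) cc$tp / (cc$tp + cc$fp) else 0
  rec <- if (cc$tp + cc$fn > 0) cc$tp / (cc$tp + cc$fn) else 0
  out <- tibble::tibble(
    f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0,
    auc = rank_auc(truth, pred$decision),
    precision = prec, recall = rec,
    n_features = length(features),
    n_train = length(train_idx), n_test = length(test_idx)
  )
  attr(out, "predictions") <- tibble::tibble(
    row = test_idx, truth = truth, predicted = pred$class,
    decision = pred$decision
  )
  out
}

# Resolve a config list against defaults, erring on unknown keys.
resolve_config <- function(cfg, defaults, where) {
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown ", where, " config key(s): ", paste(unknown, collapse = ", "))
  }
  utils::modifyList(defaults, cfg)
}

#' Run the whole selection workflow from a configuration
#'
#' Executes simulate/read, align, working/validation split, variant QC,
#' replicated selection with support counting, stable-set extraction,
#' per-SNP logistic association, and a single held-out validation
#' predictivity evaluation; writes TSV outputs and a YAML manifest
#' sufficient to reproduce every output byte-identically.
#'
#' The configuration (a YAML file or an equivalent named list) holds either
#' a `simulate:` block (`preset`, `n_samples`, `n_snps`) or an `input:`
#' block (`genotypes`, `format`, `phenotypes`), plus optional `qc:` and
#' `pipeline:` blocks mirroring [qc_config()] and [pipeline_config()]
#' arguments, `validation_fraction`, `support_threshold`, `shuffle`
#' (phenotype-shuffling null control) and `seed`.
#'
#' @param config Path to a YAML config file, or a named list.
#' @param out_dir Output directory (created if absent).
#' @param quiet Suppress per-stage progress messages.
#' @return A list with `support`, `stable`, `assoc`, `validation`,
#'   `qc_report`, `manifest` (invisibly written under `out_dir`).
#' @export
run_end_to_end <- function(config, out_dir, quiet = FALSE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  say <- function(...) if (!quiet) message("[stableselect] ", ...)

  vf <- cfg$validation_fraction %||% 0.2
  if (!(is.numeric(vf) && vf > 0 && vf < 1)) {
    stop("validation_fraction must be in (0, 1)")
  }
  seed <- as.integer(cfg$seed %||% 1L)
  support_threshold <- cfg$support_threshold

  t0 <- Sys.time()
  if (!is.null(cfg$simulate)) {
    sim <- resolve_config(
      cfg$simulate,
      list(preset = "ad-like", n_samples = 600L, n_snps = 500L),
      "simulate"
    )
    cohort <- simulate_cohort(cohort_preset(
      sim$preset,
      n_samples = sim$n_samples, n_snps = sim$n_snps,
      seed = derive_seed(seed, 100L)
    ))
    g <- cohort$genotypes
    pheno <- cohort$phenotypes
    say("simulate: ", nrow(g$values), " samples x ", ncol(g$values), " SNPs")
  } else if (!is.null(cfg$input)) {
    g <- read_genotypes(
      cfg$input$genotypes,
      format = cfg$input$format %||% "raw",
      map_path = cfg$input$map
    )
    pheno <- read_phenotypes(cfg$input$phenotypes)
    say("read: ", nrow(g$values), " samples x ", ncol(g$values), " SNPs")
  } else {
    stop("config must contain a 'simulate' or an 'input' block")
  }

  if (isTRUE(cfg$shuffle)) {
    pheno <- shuffle_phenotypes(pheno, derive_seed(seed, 101L))
    say("null control: phenotypes shuffled")
  }

  aligned <- align_cohort(g, pheno)
  g <- aligned$genotypes
  status <- aligned$phenotypes$status
  say("align: ", length(status), " shared samples")

  qc_cfg <- do.call(qc_config, resolve_config(
    cfg$qc %||% list(),
    list(
      max_missing_rate = 0.05, maf_min = 0.05, hwe_p_min = 1e-12,
      ld_window_kb = 50L, ld_step = 5L, ld_r2_max = 0.5
    ),
    "qc"
  ))
  qc <- run_qc(g, qc_cfg)
  g <- qc$genotypes
  say(
    "qc: ", qc$report$n_surviving, " of ", qc$report$n_input, " SNPs survive"
  )
  if (ncol(g$values) == 0) stop("no SNPs survive QC")

  split <- split_working_validation(status, vf, seed = derive_seed(seed, 102L))
  say(
    "split: ", length(split$working), " working / ",
    length(split$validation), " validation"
  )

  pl <- cfg$pipeline %||% list()
  pl$seed <- derive_seed(seed, 103L)
  pcfg <- do.call(pipeline_config, resolve_config(
    pl,
    list(
      n_folds = 5, s_test = 0.2, m_folds = 5, t_test = 0.2, n_steps = 100,
      C = 1, n_iterations = 50, svm_cost = 1, seed = pl$seed
    ),
    "pipeline"
  ))
  support <- run_stability(g[split$working, ], status[split$working], pcfg)
  say("stability: N = ", pcfg$n_iterations, " replications done")

  if (is.null(support_threshold)) {
    support_threshold <- ceiling(0.8 * pcfg$n_iterations)
  }
  stable <- stable_set(support, support_threshold)
  selected_any <- stable_set(support, 1)
  say(
    "stable set: ", length(stable), " SNPs at support >= ", support_threshold,
    " (", length(selected_any), " selected at least once)"
  )

  assoc <- if (length(selected_any) > 0) {
    assoc_scan(g[, match(selected_any, g$snps$id)], status)
  } else {
    tibble::tibble()
  }

  eval_set <- if (length(stable) > 0) stable else selected_any
  validation <- if (length(eval_set) > 0) {
    evaluate_holdout(
      g, status, eval_set, split$working, split$validation,
      cost = pcfg$svm_cost
    )
  } else {
    tibble::tibble()
  }
  if (nrow(validation) > 0) {
    say("validation F1 = ", round(validation$f1, 3))
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    support = file.path(out_dir, "support.tsv"),
    assoc = file.path(out_dir, "assoc.tsv"),
    pred = file.path(out_dir, "pred.tsv"),
    qc = file.path(out_dir, "qc_report.tsv"),
    manifest = file.path(out_dir, "manifest.yaml")
  )
  write_support(support, paths$support)
  utils::write.table(
    as.data.frame(assoc), paths$assoc,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    as.data.frame(validation), paths$pred,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    as.data.frame(qc$report[, -ncol(qc$report)]), paths$qc,
    sep = "\t", quote = FALSE, row.names = FALSE
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("stableselect")),
    master_seed = seed,
    validation_fraction = vf,
    support_threshold = support_threshold,
    shuffle = isTRUE(cfg$shuffle),
    simulate = cfg$simulate,
    input = if (!is.null(cfg$input)) {
      c(cfg$input, list(digests = as.list(tools::md5sum(unlist(
        cfg$input[names(cfg$input) %in% c("genotypes", "phenotypes", "map")]
      )))))
    },
    qc = unclass(qc_cfg),
    pipeline = unclass(pcfg),
    outputs = lapply(paths, normalizePath, mustWork = FALSE),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  yaml::write_yaml(manifest, paths$manifest)
  say("done in ", round(manifest$elapsed_s, 1), " s -> ", out_dir)

  invisible(list(
    support = support, stable = stable, assoc = assoc,
    validation = validation, qc_report = qc$report, manifest = manifest
  ))
}
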