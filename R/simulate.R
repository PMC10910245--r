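#' Simulation configuration for synthetic case/control cohorts
#'
#' Describes a cohort with binomial genotypes under a configurable minor
#' allele frequency spectrum, optional block-wise linkage disequilibrium, and
#' a sparse causal architecture of log-odds effects on a binary disease
#' phenotype.
#'
#' @param n_samples,n_snps Cohort and panel sizes.
#' @param maf_low,maf_high Per-SNP allele frequencies are drawn uniformly in
#'   this interval; bounds in (0, 0.5].
#' @param ld_block_size SNPs per LD block (1 = independent SNPs).
#' @param ld_rho Latent within-block correlation in [0, 1); allele draws in a
#'   block share a Gaussian copula with this correlation, inducing positive
#'   dosage correlation.
#' @param causal_indices Integer column indices of causal SNPs.
#' @param causal_betas Per-causal log-odds effect per alternate-allele copy.
#' @param causal_maf Optional fixed allele frequency for the causal SNPs
#'   (scalar or one per causal); `NULL` draws them from the same spectrum as
#'   the rest. Strong reproducible GWAS hits are common variants, so presets
#'   pin causal MAF rather than risk drawing a near-rare causal.
#' @param intercept Log-odds intercept of the disease model; with centred
#'   dosages this sets the expected prevalence at `plogis(intercept)`.
#' @param seed Integer RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples, n_snps, maf_low = 0.05, maf_high = 0.5,
                       ld_block_size = 1L, ld_rho = 0,
                       causal_indices = integer(), causal_betas = numeric(),
                       causal_maf = NULL, intercept = 0, seed = 1L) {
  stopifnot(
    n_samples >= 1, n_snps >= 1,
    maf_low > 0, maf_high <= 0.5, maf_low <= maf_high,
    ld_block_size >= 1, ld_rho >= 0, ld_rho < 1,
    length(causal_indices) == length(causal_betas),
    all(causal_indices >= 1), all(causal_indices <= n_snps),
    is.null(causal_maf) ||
      (all(causal_maf > 0) && all(causal_maf <= 0.5) &&
         length(causal_maf) %in% c(1L, length(causal_indices)))
  )
  structure(
    list(
      n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
      maf_low = maf_low, maf_high = maf_high,
      ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
      causal_indices = as.integer(causal_indices),
      causal_betas = as.numeric(causal_betas),
      causal_maf = causal_maf,
      intercept = intercept, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Preset simulation configurations
#'
#' `"ad-like"` emulates the association profile of a late-onset dementia
#' chromosome pair: a handful of strong effects (3 causals at an odds ratio
#' of 2.5 per allele) over a background of many weak ones (12 causals at an
#' odds ratio of 1.15) among 500 common SNPs. `"strong"` keeps only the 3
#' strong causals; `"weak"` keeps only the 12 weak ones.
#'
#' @param preset One of `"ad-like"`, `"strong"`, `"weak"`, `"null"`.
#' @param n_samples Cohort size (default 600).
#' @param n_snps Panel size (default 500).
#' @param seed RNG seed.
#' @return A [sim_config()].
#' @export
cohort_preset <- function(preset = c("ad-like", "strong", "weak", "null"),
                          n_samples = 600L, n_snps = 500L, seed = 1L) {
  preset <- match.arg(preset)
  strong_idx <- seq_len(3L)
  weak_idx <- 3L + seq_len(12L)
  causal <- switch(preset,
    "ad-like" = list(
      idx = c(strong_idx, weak_idx),
      beta = c(rep(log(2.5), 3), rep(log(1.15), 12))
    ),
    "strong" = list(idx = strong_idx, beta = rep(log(2.5), 3)),
    "weak" = list(idx = weak_idx, beta = rep(log(1.15), 12)),
    "null" = list(idx = integer(), beta = numeric())
  )
  sim_config(
    n_samples = n_samples, n_snps = n_snps,
    causal_indices = causal$idx, causal_betas = causal$beta,
    causal_maf = 0.3, intercept = 0, seed = seed
  )
}

#' Simulate additive genotypes
#'
#' Each SNP j gets an allele frequency q_j drawn uniformly in
#' `[maf_low, maf_high]`; a genotype is the sum of two independent allele
#' draws, so dosages are Binomial(2, q_j) and satisfy Hardy-Weinberg
#' proportions when `ld_rho = 0`. Within an LD block the two allele draws
#' share a latent equicorrelated Gaussian (copula thresholding at
#' `qnorm(q_j)`), giving positive between-SNP dosage correlation. SNPs are
#' placed 1 kb apart on one synthetic chromosome.
#'
#' @param cfg A [sim_config()].
#' @return A [genotype_matrix()] with attribute `maf`, the drawn q_j.
#' @export
simulate_genotypes <- function(cfg) {
  local_rng(cfg$seed)
  n <- cfg$n_samples
  p <- cfg$n_snps
  q <- stats::runif(p, cfg$maf_low, cfg$maf_high)
  if (!is.null(cfg$causal_maf) && length(cfg$causal_indices) > 0) {
    q[cfg$causal_indices] <- cfg$causal_maf
  }
  b <- cfg$ld_block_size
  rho <- cfg$ld_rho
  draw_alleles <- function() {
    # latent n x p Gaussian with equicorrelation rho inside each block
    z <- matrix(stats::rnorm(n * p), n, p)
    if (b > 1 && rho > 0) {
      blocks <- split(seq_len(p), ceiling(seq_len(p) / b))
      for (blk in blocks) {
        shared <- stats::rnorm(n)
        z[, blk] <- sqrt(rho) * shared + sqrt(1 - rho) * z[, blk]
      }
    }
    # threshold: allele present iff latent below the q_j quantile
    sweep(z, 2, stats::qnorm(q), `<`) * 1
  }
  values <- draw_alleles() + draw_alleles()
  snps <- tibble::tibble(
    id = sprintf("snp%04d", seq_len(p)),
    chrom = "1",
    pos_bp = seq_len(p) * 1000L,
    ref_allele = "A",
    alt_allele = "G"
  )
  g <- genotype_matrix(values, sprintf("sample%05d", seq_len(n)), snps)
  attr(g, "maf") <- q
  g
}

#' Simulate a binary disease phenotype
#'
#' Case/control status is Bernoulli with
#' `logit P(case) = intercept + sum_c beta_c * (g_c - 2 q_c)`, the dosage of
#' each causal SNP centred at its expectation so the intercept directly sets
#' the expected prevalence. A liability-threshold variant is available: a
#' standard-normal liability is added to the genetic score and cases are the
#' samples above the quantile matching `plogis(intercept)` prevalence.
#'
#' @param g A [genotype_matrix()] from [simulate_genotypes()].
#' @param causal_indices,causal_betas Causal columns and their log-odds
#'   effects per allele copy.
#' @param intercept Log-odds intercept.
#' @param seed RNG seed.
#' @param model `"logistic"` (default) or `"liability"`.
#' @return A phenotype tibble (`sample_id`, `status`) with attribute
#'   `prevalence`.
#' @export
simulate_phenotypes <- function(g, causal_indices, causal_betas,
                                intercept = 0, seed = 1L,
                                model = c("logistic", "liability")) {
  model <- match.arg(model)
  stopifnot(length(causal_indices) == length(causal_betas))
  local_rng(seed)
  n <- nrow(g$values)
  score <- rep(0, n)
  if (length(causal_indices) > 0) {
    dos <- g$values[, causal_indices, drop = FALSE]
    dos <- scale(dos, center = TRUE, scale = FALSE)
    score <- drop(dos %*% causal_betas)
  }
  status <- if (model == "logistic") {
    stats::rbinom(n, 1, stats::plogis(intercept + score))
  } else {
    liab <- score + stats::rnorm(n)
    as.integer(liab > stats::quantile(liab, 1 - stats::plogis(intercept)))
  }
  out <- tibble::tibble(sample_id = g$sample_ids, status = as.integer(status))
  attr(out, "prevalence") <- mean(status)
  out
}

#' Simulate a full cohort from a configuration
#'
#' @param cfg A [sim_config()], e.g. from [cohort_preset()].
#' @return A list with `genotypes`, `phenotypes`, and `truth` (a tibble of
#'   causal SNP ids, indices and betas plus the realized prevalence).
#' @export
simulate_cohort <- function(cfg) {
  g <- simulate_genotypes(cfg)
  pheno <- simulate_phenotypes(
    g, cfg$causal_indices, cfg$causal_betas,
    intercept = cfg$intercept, seed = derive_seed(cfg$seed, 1L)
  )
  truth <- tibble::tibble(
    snp_id = g$snps$id[cfg$causal_indices],
    index = cfg$causal_indices,
    beta = cfg$causal_betas
  )
  attr(truth, "prevalence") <- attr(pheno, "prevalence")
  list(genotypes = g, phenotypes = pheno, truth = truth)
}

#' Shuffle phenotype-to-subject assignments
#'
#' Permutes case/control labels over samples, conserving the case and
#' control counts while destroying any genotype-phenotype association. Used
#' as the negative control for the whole pipeline.
#'
#' @param pheno A phenotype tibble.
#' @param seed RNG seed.
#' @return The tibble with `status` permuted.
#' @export
shuffle_phenotypes <- function(pheno, seed) {
  local_rng(seed)
  pheno$status <- sample(pheno$status)
  pheno
}
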