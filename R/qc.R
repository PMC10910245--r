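#' Variant QC configuration
#'
#' Collects the thresholds for the pre-analysis variant filters. Defaults
#' follow common GWAS practice for common-variant analyses: missingness 0.05,
#' MAF 0.05, Hardy-Weinberg p-value floor 1e-12, LD pruning in 50 kb windows
#' sliding by 5 SNPs at an r-squared ceiling of 0.5.
#'
#' @param max_missing_rate Maximum per-SNP missing-call fraction.
#' @param maf_min Minimum minor allele frequency.
#' @param hwe_p_min SNPs with Hardy-Weinberg goodness-of-fit p below this are
#'   removed.
#' @param ld_window_kb LD pruning window width in kilobases.
#' @param ld_step Number of SNPs the window slides by.
#' @param ld_r2_max Squared-correlation ceiling above which the
#'   later-positioned SNP of a pair is pruned.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(max_missing_rate = 0.05, maf_min = 0.05,
                      hwe_p_min = 1e-12, ld_window_kb = 50L, ld_step = 5L,
                      ld_r2_max = 0.5) {
  stopifnot(
    max_missing_rate >= 0, max_missing_rate <= 1,
    maf_min >= 0, maf_min <= 1,
    hwe_p_min >= 0, hwe_p_min <= 1,
    ld_window_kb > 0, ld_step > 0,
    ld_r2_max >= 0, ld_r2_max <= 1
  )
  structure(
    list(
      max_missing_rate = max_missing_rate, maf_min = maf_min,
      hwe_p_min = hwe_p_min, ld_window_kb = as.integer(ld_window_kb),
      ld_step = as.integer(ld_step), ld_r2_max = ld_r2_max
    ),
    class = "qc_config"
  )
}

#' Remove SNPs with excessive missingness
#'
#' @param g A [genotype_matrix()].
#' @param max_missing_rate SNPs whose fraction of missing calls exceeds this
#'   are dropped; survivors keep their order.
#' @return A filtered `genotype_matrix`.
#' @export
filter_missingness <- function(g, max_missing_rate) {
  miss <- colMeans(is.na(g$values))
  g[, miss <= max_missing_rate]
}

#' Per-SNP minor allele frequency
#'
#' Allele counts are taken over non-missing genotypes only.
#'
#' @param g A [genotype_matrix()].
#' @return Numeric vector of MAFs, one per SNP.
#' @export
snp_maf <- function(g) {
  alt_freq <- colMeans(g$values, na.rm = TRUE) / 2
  pmin(alt_freq, 1 - alt_freq)
}

#' Remove SNPs below a minor allele frequency floor
#'
#' @param g A [genotype_matrix()].
#' @param maf_min SNPs with MAF strictly below this are dropped.
#' @return A filtered `genotype_matrix`.
#' @export
filter_maf <- function(g, maf_min) {
  g[, snp_maf(g) >= maf_min]
}

#' Hardy-Weinberg equilibrium p-values
#'
#' One-degree-of-freedom chi-square goodness of fit of the observed genotype
#' counts (hom-ref, het, hom-alt) against the proportions p^2, 2pq, q^2
#' implied by the observed allele frequency, computed over all samples.
#' Monomorphic SNPs carry no test and return p = 1.
#'
#' @param g A [genotype_matrix()].
#' @return Numeric vector of p-values, one per SNP.
#' @export
snp_hwe_p <- function(g) {
  apply(g$values, 2, function(x) {
    x <- x[!is.na(x)]
    n <- length(x)
    if (n == 0) return(1)
    obs <- c(sum(x == 0), sum(x == 1), sum(x == 2))
    q <- (obs[2] + 2 * obs[3]) / (2 * n)
    if (q == 0 || q == 1) return(1)
    expd <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
    stat <- sum((obs - expd)^2 / expd)
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  })
}

#' Remove SNPs violating Hardy-Weinberg equilibrium
#'
#' @param g A [genotype_matrix()].
#' @param p_min SNPs with HWE p-value strictly below this are dropped.
#' @return A filtered `genotype_matrix`.
#' @export
filter_hwe <- function(g, p_min) {
  g[, snp_hwe_p(g) >= p_min]
}

# Mean-impute missing dosages per SNP; columns with all calls missing get 0.
impute_dosages <- function(values) {
  mu <- colMeans(values, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(values), arr.ind = TRUE)
  if (nrow(idx) > 0) values[idx] <- mu[idx[, 2]]
  values
}

#' Greedy windowed LD pruning
#'
#' Slides a base-pair window along each chromosome (SNPs must be sorted by
#' chromosome then position). Within a window, for every pair of surviving
#' SNPs whose squared Pearson correlation of mean-imputed dosages exceeds
#' `r2_max`, the later-positioned SNP is removed; the window then advances by
#' `step` SNPs. Zero-variance columns are treated as uncorrelated with
#' everything.
#'
#' @param g A [genotype_matrix()] sorted by (chrom, pos_bp).
#' @param window_kb Window width in kilobases.
#' @param step SNP count the window slides by.
#' @param r2_max Squared-correlation ceiling.
#' @return A pruned `genotype_matrix`, survivors in input order.
#' @export
ld_prune <- function(g, window_kb = 50, step = 5, r2_max = 0.5) {
  ord <- order(g$snps$chrom, g$snps$pos_bp)
  if (!identical(ord, seq_len(ncol(g$values)))) {
    stop("SNPs must be sorted by (chrom, pos_bp) before LD pruning")
  }
  p <- ncol(g$values)
  if (p <= 1) return(g)
  x <- impute_dosages(g$values)
  sds <- apply(x, 2, stats::sd)
  alive <- rep(TRUE, p)
  chrom <- g$snps$chrom
  pos <- g$snps$pos_bp
  start <- 1L
  while (start <= p) {
    # window: SNPs on start's chromosome within window_kb of its position
    in_win <- which(
      chrom == chrom[start] &
        pos >= pos[start] & pos <= pos[start] + window_kb * 1000
    )
    in_win <- in_win[in_win >= start]
    live <- in_win[alive[in_win]]
    if (length(live) >= 2) {
      for (a in seq_len(length(live) - 1)) {
        i <- live[a]
        if (!alive[i]) next
        for (b in seq((a + 1), length(live))) {
          j <- live[b]
          if (!alive[j]) next
          if (sds[i] == 0 || sds[j] == 0) next
          r <- stats::cor(x[, i], x[, j])
          if (r^2 > r2_max) alive[j] <- FALSE
        }
      }
    }
    start <- start + step
  }
  g[, alive]
}

#' Run the full variant QC stack
#'
#' Applies the four filters in the fixed order missingness, MAF,
#' Hardy-Weinberg, LD pruning, and tallies how many SNPs each step removed.
#'
#' @param g A [genotype_matrix()].
#' @param config A [qc_config()].
#' @return A list with `genotypes` (the survivors) and `report`, a one-row
#'   tibble of input/removal/survivor counts plus the surviving SNP ids.
#' @export
run_qc <- function(g, config = qc_config()) {
  n0 <- ncol(g$values)
  g1 <- filter_missingness(g, config$max_missing_rate)
  g2 <- filter_maf(g1, config$maf_min)
  g3 <- filter_hwe(g2, config$hwe_p_min)
  g4 <- ld_prune(g3, config$ld_window_kb, config$ld_step, config$ld_r2_max)
  report <- tibble::tibble(
    n_input = n0,
    n_removed_missing = n0 - ncol(g1$values),
    n_removed_maf = ncol(g1$values) - ncol(g2$values),
    n_removed_hwe = ncol(g2$values) - ncol(g3$values),
    n_removed_ld = ncol(g3$values) - ncol(g4$values),
    n_surviving = ncol(g4$values),
    surviving_ids = list(g4$snps$id)
  )
  list(genotypes = g4, report = report)
}
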