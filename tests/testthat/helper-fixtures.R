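# Small in-code fixtures shared across test files.

toy_genotypes <- function(values = NULL, n = 4, p = 3, chrom = "1",
                          pos = NULL) {
  if (is.null(values)) {
    values <- matrix(c(
      0, 1, 2,
      1, 1, 0,
      2, 0, 1,
      0, 2, 2
    ), nrow = n, byrow = TRUE)[seq_len(n), seq_len(p), drop = FALSE]
  }
  n <- nrow(values)
  p <- ncol(values)
  genotype_matrix(
    values,
    sample_ids = paste0("s", seq_len(n)),
    snps = tibble::tibble(
      id = paste0("rs", seq_len(p)),
      chrom = rep_len(chrom, p),
      pos_bp = pos %||% (seq_len(p) * 1000L),
      ref_allele = "A",
      alt_allele = "G"
    )
  )
}

random_genotypes <- function(n, p, seed = 1, maf = NULL, missing_rate = 0) {
  set.seed(seed)
  q <- maf %||% runif(p, 0.1, 0.5)
  values <- sapply(q, function(qq) rbinom(n, 2, qq))
  if (missing_rate > 0) {
    values[runif(length(values)) < missing_rate] <- NA
  }
  toy_genotypes(values)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent ridge oracle: minimize the penalized weighted least-squares
# objective numerically (BFGS with analytic gradient), never touching the
# closed form under test.
ridge_oracle <- function(X, y, C, delta = rep(1, nrow(X))) {
  w <- 1 / delta^2
  fn <- function(m) {
    r <- y - drop(X %*% m)
    sum(w * r^2) + C * sum(m^2)
  }
  gr <- function(m) {
    r <- y - drop(X %*% m)
    -2 * drop(crossprod(X, w * r)) + 2 * C * m
  }
  opt <- optim(
    rep(0, ncol(X)), fn, gr,
    method = "BFGS",
    control = list(maxit = 5000, reltol = 1e-16)
  )
  opt$par
}
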