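test_that("identity-design ridge matches hand arithmetic", {
  X <- diag(3)
  fit <- ridge_fit(X, y = c(1, 2, 3), C = 1)
  expect_equal(unname(fit$m_bar), c(0.5, 1.0, 1.5))
  # residual: y'y - (Xm)'(Xm) - C m'm = 14 - 3.5 - 3.5 = 7
  expect_equal(fit$e_res2, 7)
  expect_equal(fit$total_weighted_ss, 14)
})

test_that("closed form matches the numerical minimizer oracle", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 20; p <- 5
    X <- matrix(rnorm(n * p), n)
    y <- rnorm(n)
    C <- 0.7
    fit <- ridge_fit(X, y, C = C)
    oracle <- ridge_oracle(X, y, C)
    expect_lt(max(abs(fit$m_bar - oracle)), 1e-6)
  }
})

test_that("heteroscedastic weights enter the fit correctly", {
  set.seed(32)
  n <- 25; p <- 4
  X <- matrix(rnorm(n * p), n)
  delta <- runif(n, 0.5, 2)
  y <- rnorm(n)
  design <- structure(
    list(X = X, delta = delta, feature_cols = 1:p,
         feature_ids = paste0("f", 1:p)),
    class = "design_matrix"
  )
  fit <- ridge_fit(design, y, C = 1.3)
  oracle <- ridge_oracle(X, y, 1.3, delta = delta)
  expect_lt(max(abs(fit$m_bar - oracle)), 1e-6)
  expect_equal(fit$total_weighted_ss, sum(y^2 / delta^2))
})

test_that("primal and dual solution paths agree", {
  set.seed(33)
  X <- matrix(rnorm(30 * 12), 30)
  y <- rnorm(30)
  primal <- ridge_fit(X, y, C = 0.9)$m_bar
  # force the dual branch by transposed-shape data: p > n
  Xu <- matrix(rnorm(10 * 25), 10)
  yu <- rnorm(10)
  dual <- ridge_fit(Xu, yu, C = 0.9)$m_bar
  A <- crossprod(Xu) + 0.9 * diag(25)
  expect_lt(max(abs(dual - drop(solve(A, crossprod(Xu, yu))))), 1e-8)
  # and the primal case against plain dense algebra
  Ap <- crossprod(X) + 0.9 * diag(12)
  expect_lt(max(abs(primal - drop(solve(Ap, crossprod(X, y))))), 1e-10)
})

test_that("weighted sum of squares conserves across its three components", {
  set.seed(34)
  for (rep in 1:10) {
    n <- sample(10:40, 1)
    p <- sample(3:15, 1)
    X <- matrix(rnorm(n * p), n)
    delta <- runif(n, 0.5, 2)
    design <- structure(
      list(X = X, delta = delta, feature_cols = seq_len(p),
           feature_ids = paste0("f", seq_len(p))),
      class = "design_matrix"
    )
    y <- rnorm(n)
    fit <- ridge_fit(design, y, C = runif(1, 0.1, 5))
    lhs <- sum(y^2 / delta^2)
    rhs <- fit$e_res2 + fit$explained_ss + fit$C * sum(fit$m_bar^2)
    expect_lt(abs(lhs - rhs) / lhs, 1e-10)
  }
})

test_that("quadratic error decomposition holds for arbitrary coefficients", {
  set.seed(35)
  X <- matrix(rnorm(30 * 10), 30)
  y <- rnorm(30)
  fit <- ridge_fit(X, y, C = 2)
  scale <- fit$total_weighted_ss
  for (rep in 1:100) {
    m <- rnorm(10, sd = 2)
    expect_lt(error_decomposition_check(fit, m) / scale, 1e-10)
  }
  # at the minimizer, E^2 equals the residual exactly
  expect_equal(ridge_objective(fit$design, y, fit$m_bar, 2), fit$e_res2,
               tolerance = 1e-12)
})

test_that("vanishing penalty recovers ordinary least squares", {
  set.seed(36)
  X <- cbind(1, matrix(rnorm(40 * 6), 40))
  y <- rnorm(40)
  fit <- ridge_fit(X, y, C = 1e-10)
  ols <- qr.solve(X, y)
  expect_lt(max(abs(fit$m_bar - ols)), 1e-6)
})

test_that("coefficient norm shrinks monotonically as C grows", {
  set.seed(37)
  X <- matrix(rnorm(25 * 8), 25)
  y <- rnorm(25)
  norms <- sapply(c(0.01, 0.1, 1, 10, 100, 1e4), function(C) {
    sqrt(sum(ridge_fit(X, y, C = C)$m_bar^2))
  })
  expect_true(all(diff(norms) < 0))
})

test_that("covariance equals the naive sandwich formula", {
  set.seed(38)
  X <- matrix(rnorm(20 * 6), 20)
  y <- rnorm(20)
  C <- 1.7
  fit <- ridge_fit(X, y, C = C)
  A <- solve(crossprod(X) + C * diag(6))
  sandwich <- A %*% crossprod(X) %*% A
  expect_lt(max(abs(fit$cov_m - sandwich)), 1e-10)
  ev <- eigen(fit$cov_m, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-12)
})

test_that("singular unpenalized systems are rejected with advice", {
  X <- cbind(c(1, 1, 1), c(2, 2, 2))  # rank 1
  expect_error(ridge_fit(X, c(1, 2, 3), C = 0), "penalty")
  expect_error(ridge_fit(matrix(1, 2, 5), c(1, 0), C = 0), "penalty")
})

test_that("heritability scores decompose the explained sum of squares", {
  # orthonormal columns: h_j = m_j^2 and sum h = ||Xm||^2
  Q <- qr.Q(qr(matrix(rnorm(30 * 5), 30)))
  design <- build_design(matrix(0, 30, 1))  # placeholder to get the class
  design$X <- cbind(1, Q)
  design$delta <- rep(1, 30)
  design$feature_cols <- 2:6
  design$feature_ids <- paste0("f", 1:5)
  y <- rnorm(30)
  fit <- ridge_fit(design, y, C = 0.5)
  h <- feature_heritability(fit)
  m_feat <- fit$m_bar[2:6]
  expect_equal(unname(h), unname(m_feat^2), tolerance = 1e-10)

  # correlated columns: the gap to ||Xm||^2 is exactly the cross term
  set.seed(39)
  z <- rnorm(40)
  X2 <- cbind(z + rnorm(40, sd = 0.3), z + rnorm(40, sd = 0.3))
  fit2 <- ridge_fit(X2, rnorm(40), C = 1)
  h2 <- fit2$m_bar^2 * diag(crossprod(X2))
  cross <- 2 * fit2$m_bar[1] * fit2$m_bar[2] * crossprod(X2)[1, 2]
  expect_equal(sum(h2) + drop(cross), fit2$explained_ss, tolerance = 1e-10)

  # zero coefficients give zero scores
  fit3 <- ridge_fit(matrix(rnorm(20), 10), rep(0, 10), C = 1)
  expect_equal(unname(feature_heritability(fit3)), c(0, 0))
})

test_that("ranking is a stable decreasing sort", {
  expect_equal(rank_features(c(0.1, 0.5, 0.3))[1:3], c(2L, 3L, 1L))
  expect_equal(rank_features(rep(1, 4))[1:4], 1:4)  # ties keep column order
  expect_error(rank_features(c(1, NaN)), "NaN")

  set.seed(40)
  h <- sample(rep(runif(20), 2))  # duplicated values force ties
  sigma_inv <- rank_features(h)
  brute <- order(-h, seq_along(h))  # decorate-sort oracle
  expect_equal(as.integer(sigma_inv), brute)
  sigma <- attr(sigma_inv, "sigma")
  expect_equal(sort(sigma), seq_along(h))  # bijection
  expect_true(all(diff(h[sigma_inv]) <= 0))
})

test_that("fold-averaged ranking recovers a planted strong causal", {
  hits <- sapply(1:8, function(s) {
    g <- simulate_genotypes(sim_config(500, 100, seed = s, causal_maf = 0.3,
                                       causal_indices = 7L,
                                       causal_betas = log(3)))
    pheno <- simulate_phenotypes(g, 7L, log(3), seed = s + 100)
    rk <- rank_by_folds(g, pheno$status, n_folds = 3, s_test = 0.5, C = 1,
                        seed = s + 200)
    rk$rank[7]
  })
  expect_gte(mean(hits <= 5), 0.9)
})

test_that("rank_by_folds is seed-deterministic and degenerates correctly", {
  g <- simulate_genotypes(sim_config(80, 30, seed = 41))
  status <- simulate_phenotypes(g, 1L, log(2), seed = 42)$status
  r1 <- rank_by_folds(g, status, n_folds = 3, s_test = 0.3, seed = 9)
  r2 <- rank_by_folds(g, status, n_folds = 3, s_test = 0.3, seed = 9)
  expect_identical(r1, r2)

  # single fold with a sliver test set approaches the full-data ranking
  r3 <- rank_by_folds(g, status, n_folds = 1, s_test = 0.02, seed = 10)
  design <- build_design(g)
  full_fit <- ridge_fit(design, status, C = 1, compute_cov = FALSE)
  full_rank <- rank_features(feature_heritability(full_fit))
  # rankings computed on 98% vs 100% of samples should largely agree at the top
  expect_true(r3$snp_id[match(1:5, r3$rank)][1] %in%
                g$snps$id[full_rank[1:3]])
})
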