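test_that("logistic association rejects degenerate inputs", {
  expect_error(logistic_assoc(rep(1, 50), rep(0:1, 25)), "constant")
  expect_error(logistic_assoc(rbinom(50, 2, 0.4), rep(1L, 50)), "classes")
})

test_that("logistic null p-values are uniform and type-I error is nominal", {
  set.seed(70)
  p_vals <- replicate(400, {
    g <- rbinom(250, 2, 0.3)
    y <- rbinom(250, 1, 0.5)
    logistic_assoc(g, y)$p_value
  })
  expect_gt(ks.test(p_vals, "punif")$p.value, 0.01)
  expect_gt(mean(p_vals < 0.05), 0.02)
  expect_lt(mean(p_vals < 0.05), 0.08)
})

test_that("Wald and contingency inference agree asymptotically", {
  set.seed(71)
  n <- 4000
  e <- rbinom(n, 1, 0.4)                       # binary-coded exposure
  y <- rbinom(n, 1, plogis(-0.3 + 0.8 * e))
  wald <- logistic_assoc(e, y)
  tab <- contingency_or_test(
    n_de = sum(y == 1 & e == 1), n_nde = sum(y == 0 & e == 0),
    n_dne = sum(y == 1 & e == 0), n_nd_e = sum(y == 0 & e == 1)
  )
  expect_equal(wald$log_or, tab$log_or, tolerance = 0.1)
  expect_equal(wald$se_log_or, tab$se_log_or, tolerance = 0.1)
})

test_that("complete separation is flagged, not reported as significant", {
  g <- c(rep(0, 20), rep(2, 20))
  y <- c(rep(0L, 20), rep(1L, 20))
  res <- logistic_assoc(g, y)
  expect_false(res$converged)
  expect_true(is.na(res$p_value))
})

test_that("contingency OR test matches the normal-CDF oracle", {
  sym <- contingency_or_test(10, 10, 10, 10)
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p_value, 1)

  res <- contingency_or_test(20, 20, 5, 5)
  expect_equal(res$odds_ratio, 16)
  expect_equal(res$se_log_or, sqrt(0.5), tolerance = 1e-12)
  z <- log(16) / sqrt(0.5)
  expect_equal(z, 3.921, tolerance = 1e-3)
  expect_equal(res$p_value, 2 * pnorm(-z), tolerance = 1e-10)
  expect_equal(res$p_value, 8.8e-5, tolerance = 0.01)
})

test_that("zero cells trigger the flagged Haldane-Anscombe correction", {
  res <- contingency_or_test(10, 10, 0, 5)
  expect_true(res$corrected)
  expect_equal(res$log_or, log(10.5 * 10.5 / (0.5 * 5.5)))
  expect_error(contingency_or_test(-1, 2, 3, 4), "non-negative")
})

test_that("contingency inference has the table symmetries", {
  base <- contingency_or_test(12, 30, 7, 19)
  swapped_both <- contingency_or_test(30, 12, 19, 7)   # D<->Dbar, E<->Ebar
  expect_equal(swapped_both$odds_ratio, base$odds_ratio)
  expect_equal(swapped_both$p_value, base$p_value)

  swapped_exposure <- contingency_or_test(7, 19, 12, 30)
  expect_equal(swapped_exposure$odds_ratio, 1 / base$odds_ratio)
  expect_equal(swapped_exposure$p_value, base$p_value)
})

test_that("a perfectly separating feature yields F1 = 1", {
  status <- rep(c(1L, 0L), each = 40)
  X <- cbind(sep = status * 3 + rnorm(80, sd = 0.1),
             noise = rnorm(80))
  res <- evaluate_predictivity(X, status, 1L, m_folds = 2, t_test = 0.25,
                               seed = 72)
  expect_equal(res$f1, 1)
  expect_equal(res$auc, 1)
  expect_error(evaluate_predictivity(X, status, integer(), seed = 1), "empty")
})

test_that("F1 is the harmonic mean of precision and recall", {
  # constructed predictions with precision = recall = 0.5:
  # 10 true positives of 20 predicted positive, 20 actual positives
  truth <- rep(c(1L, 0L), c(20, 20))
  pred <- c(rep(1L, 10), rep(0L, 10), rep(1L, 10), rep(0L, 10))
  cc <- stableselect:::confusion_counts(truth, pred)
  prec <- cc$tp / (cc$tp + cc$fp)
  rec <- cc$tp / (cc$tp + cc$fn)
  expect_equal(prec, 0.5)
  expect_equal(rec, 0.5)
  expect_equal(2 * prec * rec / (prec + rec), 0.5)
})

test_that("noise features on shuffled labels score near chance", {
  set.seed(73)
  n <- 500
  X <- matrix(rnorm(n * 10), n)
  status <- sample(rep(c(1L, 0L), each = n / 2))
  res <- evaluate_predictivity(X, status, 1:10, m_folds = 3, t_test = 0.4,
                               seed = 74)
  # chance F1 for balanced classes is ~0.5; allow a generous binomial band
  expect_lt(abs(res$f1 - 0.5), 0.15)
  expect_lt(abs(res$auc - 0.5), 0.1)
})

test_that("significance subsetting matches a brute-force filter", {
  assoc <- tibble::tibble(
    snp_id = paste0("rs", 1:6),
    p_value = c(1e-31, 1e-29, 0.5, 1, 1e-40, NA)
  )
  expect_setequal(subset_by_significance(assoc, 30), c("rs1", "rs5"))
  expect_setequal(subset_by_significance(assoc, 0),
                  assoc$snp_id[!is.na(assoc$p_value) & assoc$p_value < 1])
  brute <- assoc$snp_id[which(-log10(assoc$p_value) > 28)]
  expect_setequal(subset_by_significance(assoc, 28), brute)
})

test_that("beta histogram rule selects sparse tail bins only", {
  set.seed(75)
  # spike at ~0 plus 10 strong outliers among 100,000
  w <- tibble::tibble(
    snp_id = paste0("rs", 1:100000),
    beta = c(rnorm(99990, 0, 1e-5), rep(0.5, 10))
  )
  sel <- select_by_beta_histogram(w, n_bins = 50, bin_fraction_max = 2e-4)
  expect_setequal(sel, paste0("rs", 99991:100000))

  # uniform weights: every bin holds ~2% >> 2e-4
  u <- tibble::tibble(snp_id = paste0("u", 1:1000), beta = runif(1000))
  expect_length(select_by_beta_histogram(u), 0L)

  # all-equal weights: zero-width range, nothing selected
  expect_length(
    select_by_beta_histogram(tibble::tibble(snp_id = "a", beta = 1)), 0L
  )
  expect_error(select_by_beta_histogram(numeric()), "empty")
})

test_that("magnitude rule is the |beta| cut", {
  w <- tibble::tibble(snp_id = c("a", "b", "c"),
                      beta = c(1e-5, -0.01, 2e-4))
  expect_setequal(select_by_beta_magnitude(w, 2e-4), "b")
})
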