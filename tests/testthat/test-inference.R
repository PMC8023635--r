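test_that("CCA reduces to |Pearson r| for single variables and is affine invariant", {
  set.seed(1)
  x <- matrix(rnorm(50), ncol = 1)
  y <- matrix(0.6 * x + rnorm(50, 0, 0.8), ncol = 1)
  res <- fit_cca(x, y)
  expect_equal(res$canonical_correlations, abs(cor(x, y)[1, 1]), tolerance = 1e-10)

  X <- matrix(rnorm(40 * 3), 40)
  res_self <- fit_cca(X, X + 0)
  expect_equal(res_self$canonical_correlations, rep(1, 3), tolerance = 1e-8)

  Y <- matrix(rnorm(40 * 3), 40)
  A <- matrix(c(2, 0.5, 0, -1, 3, 1, 0.2, 0, 1), 3)  # invertible
  r1 <- fit_cca(X, Y)$canonical_correlations
  r2 <- fit_cca(X %*% A, Y)$canonical_correlations
  expect_equal(r1, r2, tolerance = 1e-8)

  # maximality: first canonical correlation >= any single-pair |r|
  pairwise <- abs(cor(X, Y))
  expect_gte(r1[1] + 1e-8, max(pairwise))
})

test_that("CCA agrees with the base-R cancor cross-check", {
  set.seed(2)
  X <- matrix(rnorm(30 * 3), 30)
  Y <- matrix(rnorm(30 * 2), 30)
  mine <- fit_cca(X, Y)$canonical_correlations
  ref <- cancor(scale(X), scale(Y))$cor
  expect_equal(mine, ref, tolerance = 1e-10)
})

test_that("CCA rejects rank-deficient and undersized inputs", {
  set.seed(3)
  X <- matrix(rnorm(20 * 2), 20)
  Xbad <- cbind(X, X[, 1] * 2)
  colnames(Xbad) <- c("a", "b", "a_copy")
  expect_error(fit_cca(Xbad, matrix(rnorm(20 * 2), 20)),
               class = "eegprog_collinear", regexp = "a_copy")
  expect_error(fit_cca(matrix(rnorm(8), 4), matrix(rnorm(12), 4)),
               class = "eegprog_invalid")
})

test_that("max-statistic permutation p-values behave as specified", {
  set.seed(4)
  X <- matrix(rnorm(50 * 3), 50)
  res <- permutation_test_cca(X, X + 0, n_perm = 200, seed = 1)
  expect_equal(res$p_values[1], 0)
  expect_true(all(diff(res$p_values) >= 0))

  res2 <- permutation_test_cca(X, X + 0, n_perm = 200, seed = 1)
  expect_identical(res$p_values, res2$p_values)
})

test_that("variate loadings behave like correlations with the first variate", {
  set.seed(5)
  X <- matrix(rnorm(200 * 2), 200, dimnames = list(NULL, c("a", "b")))
  Y <- cbind(v1 = X[, 1] + rnorm(200, 0, 0.1), v2 = rnorm(200))
  res <- fit_cca(X, Y)
  ld <- variate_loadings(res, X, Y)
  # a variable that nearly equals the variate loads near 1 in magnitude
  expect_gt(max(abs(ld$y$loading[ld$y$variable == "v1"])), 0.9)
  # an orthogonal noise variable loads near 0
  expect_lt(abs(ld$y$loading[ld$y$variable == "v2"]), 0.2)
  # loadings invariant to rescaling of the original variable
  Y2 <- Y; Y2[, "v1"] <- Y[, "v1"] * 100
  ld2 <- variate_loadings(res, X, Y2)
  expect_equal(ld2$y$loading, ld$y$loading, tolerance = 1e-12)
})

test_that("rank inverse normal transform matches the Blom formula", {
  got <- rank_inverse_normal(c(10, 20, 30))
  want <- qnorm((c(1, 2, 3) - 3 / 8) / (3 + 1 / 4))
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(round(got, 4), c(-0.8694, 0, 0.8694))

  set.seed(6)
  v <- rnorm(25)
  expect_equal(rank_inverse_normal(rev(v)), -rev(rank_inverse_normal(-v)),
               tolerance = 1e-12)
  expect_equal(order(rank_inverse_normal(v)), order(v))
  expect_lt(abs(mean(rank_inverse_normal(v))), 0.05)
  expect_error(rank_inverse_normal(rep(1, 5)), class = "eegprog_invalid")
})

test_that("stepwise regression finds a perfect predictor and reports sane stats", {
  set.seed(7)
  x1 <- rnorm(40); x2 <- rnorm(40)
  res <- stepwise_regression(x1, data.frame(x1 = x1, x2 = x2))
  expect_equal(res$selected, "x1")
  expect_equal(unname(res$beta["x1"]), 1, tolerance = 1e-8)
  expect_lte(res$adj_r_squared, res$r_squared)

  # no candidate enters
  res0 <- stepwise_regression(rnorm(30), data.frame(z = rnorm(30)))
  expect_true(res0$empty || res0$p_values[1] < 0.05)
})

test_that("stepwise agrees with an independent partial-F implementation", {
  set.seed(8)
  agree <- sapply(1:20, function(s) {
    set.seed(1000 + s)
    n <- 60
    X <- as.data.frame(matrix(rnorm(n * 5), n))
    names(X) <- paste0("v", 1:5)
    y <- 0.8 * X$v1 - 0.6 * X$v3 + rnorm(n)
    mine <- sort(stepwise_regression(y, X)$selected)
    ref <- oracle_stepwise(y, X)
    identical(mine, ref)
  })
  expect_true(all(agree))
})

test_that("stepwise with thresholds at 1 reproduces full-set OLS", {
  set.seed(9)
  n <- 50
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- X$a + rnorm(n)
  res <- stepwise_regression(y, X, entry_p = 1, removal_p = 1.000001)
  expect_setequal(res$selected, c("a", "b", "c"))
  ols <- lm(y ~ a + b + c, data = X)
  expect_equal(sort(res$beta_raw), sort(coef(ols)[-1]), tolerance = 1e-10)
  expect_equal(res$r_squared, summary(ols)$r.squared, tolerance = 1e-12)
})

test_that("r2_change matches direct computation and nesting rules", {
  set.seed(10)
  n <- 60
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- X$a + 0.5 * X$b + rnorm(n, 0, 0.5)
  res <- stepwise_regression(y, X)
  expect_setequal(res$selected, c("a", "b"))
  expect_equal(r2_change(res, res$selected), 0)
  direct <- summary(lm(y ~ a + b, X))$r.squared - summary(lm(y ~ a, X))$r.squared
  expect_equal(r2_change(res, "a"), direct, tolerance = 1e-12)
  expect_error(r2_change(res, "zzz"), class = "eegprog_invalid")
})

test_that("adding pure noise changes R^2 only marginally at large n", {
  set.seed(11)
  deltas <- replicate(20, {
    n <- 200
    X <- data.frame(sig = rnorm(n), noise = rnorm(n))
    y <- X$sig + rnorm(n)
    full <- stepwise_regression(y, X, entry_p = 1, removal_p = 1.000001)
    r2_change(full, "sig")
  })
  expect_true(all(deltas >= 0))
  expect_lt(mean(deltas), 0.05)
})

test_that("listwise deletion is applied and logged", {
  set.seed(12)
  n <- 30
  X <- data.frame(a = rnorm(n))
  y <- X$a + rnorm(n, 0, 0.3)
  y[c(3, 7)] <- NA
  res <- stepwise_regression(y, X)
  expect_equal(res$n_used, 28)
  expect_equal(res$dropped_cases, c(3L, 7L))
  expect_match(res$steps[1], "listwise")
})
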