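test_that("single-column response is fit perfectly by one component", {
  # with in-sample orthogonal predictors the first weight vector points
  # exactly along the driving column
  set.seed(1)
  X <- qr.Q(qr(scale(matrix(rnorm(30), 10, 3))))  # centred orthonormal columns
  y <- 3.2 * X[, 2]
  fit <- fit_pls(X, y, ncomp = 1, scaling = "center")
  expect_gt(fit$r2y_cum[1], 1 - 1e-10)
  expect_equal(unname(fit$coefficients[2]), 1, tolerance = 1e-8)
})

test_that("full-rank PLS reproduces OLS training predictions", {
  for (s in 1:10) {
    inst <- random_instance(20, 5, seed = s)
    fit <- fit_pls(inst$X, inst$y, ncomp = 5)
    ols <- lm(inst$y ~ inst$X)
    expect_equal(unname(fit$fitted), unname(fitted(ols)), tolerance = 1e-8)
    # standardized coefficients agree with standardized OLS at full rank
    bstd_ols <- coef(ols)[-1] * apply(inst$X, 2, sd) / sd(inst$y)
    expect_equal(unname(fit$coefficients), unname(bstd_ols), tolerance = 1e-6)
  }
})

test_that("fit matches an independent PLS implementation", {
  set.seed(42)
  X <- matrix(rnorm(120), 20, 6, dimnames = list(NULL, paste0("x", 1:6)))
  y <- drop(X %*% c(1, 0.5, 0, 0, -0.3, 0) + rnorm(20, 0, 0.3))
  fit <- fit_pls(X, y, ncomp = 3)
  ref <- mixOmics::pls(X, y, ncomp = 3, mode = "regression", scale = TRUE)
  expect_equal(unname(fit$fitted),
               unname(predict(ref, X)$predict[, 1, 3]), tolerance = 1e-6)
  expect_equal(unname(fit$vip), unname(mixOmics::vip(ref)[, 3]), tolerance = 1e-6)
})

test_that("VIP normalization and preprocessing guards hold", {
  # p = 1: VIP identically 1
  set.seed(3)
  x1 <- matrix(rnorm(12), 12, 1)
  f1 <- fit_pls(x1, 2 * x1[, 1] + rnorm(12, 0, 0.1), ncomp = 1)
  expect_equal(unname(f1$vip), 1)

  # the truly driving column has the largest VIP, above 1
  set.seed(4)
  X <- matrix(rnorm(25 * 6), 25, 6)
  y <- X[, 1] + rnorm(25, 0, 0.05)
  f <- fit_pls(X, y, ncomp = 1)
  expect_identical(unname(which.max(f$vip)), 1L)
  expect_gt(f$vip[1], 1)

  # mean(VIP^2) = 1 for any fitted model
  for (s in 1:15) {
    inst <- random_instance(15, 8, seed = 100 + s, noise = 1)
    fit <- fit_pls(inst$X, inst$y, ncomp = sample(1:4, 1))
    expect_equal(mean(fit$vip^2), 1, tolerance = 1e-8)
  }

  Xz <- cbind(rnorm(10), rep(2, 10))
  colnames(Xz) <- c("a", "zv")
  expect_error(fit_pls(Xz, rnorm(10), 1), "zero-variance compound column 'zv'")
})

test_that("coefficient sign flips with its predictor and scores are orthogonal", {
  inst <- random_instance(18, 5, seed = 77)
  f1 <- fit_pls(inst$X, inst$y, ncomp = 3)
  Xf <- inst$X; Xf[, 2] <- -Xf[, 2]
  f2 <- fit_pls(Xf, inst$y, ncomp = 3)
  expect_equal(unname(f2$coefficients[2]), -unname(f1$coefficients[2]),
               tolerance = 1e-10)
  expect_equal(unname(f2$coefficients[-2]), unname(f1$coefficients[-2]),
               tolerance = 1e-10)
  G <- crossprod(f1$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
})

test_that("cross-validated Q2 matches a leave-one-out brute-force oracle", {
  set.seed(5)
  X <- matrix(rnorm(15), 5, 3)
  y <- drop(X %*% c(1, -0.5, 0.2)) + rnorm(5, 0, 0.2)
  q2 <- cross_validate_q2(X, y, max_A = 1, folds = 5, seed = 1)
  press <- 0
  for (i in 1:5)
    press <- press + (y[i] - pls1_predict_oracle(X[-i, , drop = FALSE], y[-i],
                                                 X[i, , drop = FALSE]))^2
  expect_equal(unname(q2[1]), 1 - press / sum((y - mean(y))^2), tolerance = 1e-10)
})

test_that("Q2 separates signal from noise and never exceeds R2Y", {
  # null: median Q2(1) near or below zero
  q2_null <- vapply(1:20, function(s) {
    inst <- random_instance(100, 5, seed = 200 + s)
    y <- rnorm(100)  # response unrelated to X
    unname(cross_validate_q2(inst$X, y, max_A = 1, folds = 7, seed = s)[1])
  }, numeric(1))
  expect_lte(median(q2_null), 0.1)

  # noiseless one-factor signal: Q2(1) near 1
  set.seed(6)
  t_lat <- rnorm(40)
  X <- outer(t_lat, c(1, 0.8, -0.5, 0.3)) + matrix(rnorm(160, 0, 0.01), 40, 4)
  y <- 2 * t_lat
  expect_gte(unname(cross_validate_q2(X, y, max_A = 1, folds = 7, seed = 1)[1]), 0.95)

  # Q2(A) <= R2Y(A) on the same data
  for (s in 1:8) {
    inst <- random_instance(20, 6, seed = 300 + s, noise = 1)
    q2 <- cross_validate_q2(inst$X, inst$y, max_A = 3, folds = 7, seed = s)
    fit <- fit_pls(inst$X, inst$y, ncomp = 3)
    expect_true(all(q2 <= fit$r2y_cum + 1e-10))
  }

  expect_error(cross_validate_q2(matrix(rnorm(20), 10, 2), rnorm(10),
                                 max_A = 1, folds = 1), "folds")
})

test_that("component selection rules behave as documented", {
  expect_identical(select_components(c(0.4, 0.7, 0.71, 0.70)), 2L)
  expect_identical(select_components(c(0.1, 0.3, 0.5, 0.7)), 4L)  # monotone
  expect_warning(a <- select_components(c(-0.2, -0.1)), "no predictive component")
  expect_identical(a, 1L)
  expect_identical(select_components(c(0.4, 0.7, 0.71, 0.70),
                                     rule = "gain_threshold"), 2L)
})

test_that("permutation test is deterministic and detects real signal", {
  d <- generate_dataset(synthetic_config(seed = 13))
  X <- d$peaks$values; y <- d$acts$values[, "DPPH"]
  p1 <- permutation_test(X, y, A = 2, n_perm = 20, seed = 99)
  p2 <- permutation_test(X, y, A = 2, n_perm = 20, seed = 99)
  expect_identical(p1[c("permuted_r2", "permuted_q2", "empirical_p_q2")],
                   p2[c("permuted_r2", "permuted_q2", "empirical_p_q2")])
  expect_lte(p1$empirical_p_q2, 0.05)
  expect_gt(p1$observed_q2, max(p1$permuted_q2))
  expect_lt(p1$q2_intercept, p1$observed_q2)
  expect_error(permutation_test(X, rep(1, nrow(X)), A = 1, n_perm = 20),
               "constant response")
})

test_that("predict and residuals are coherent with the stored fit", {
  inst <- random_instance(20, 6, seed = 8)
  fit <- fit_pls(inst$X, inst$y, ncomp = 2)
  expect_equal(predict(fit, inst$X), fit$fitted, tolerance = 1e-12)
  expect_equal(residuals(fit), inst$y - fit$fitted, tolerance = 1e-12)
  # ncomp = 1 predictions differ from ncomp = 2 in general
  expect_false(isTRUE(all.equal(predict(fit, inst$X, ncomp = 1), fit$fitted)))
  # raw coefficients + intercept reproduce predictions
  b <- coef(fit, type = "raw")
  expect_equal(drop(inst$X %*% b) + attr(b, "intercept"), unname(fit$fitted),
               tolerance = 1e-10)
})
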