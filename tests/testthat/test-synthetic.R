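test_that("generator is deterministic and respects degenerate configs", {
  cfg <- synthetic_config(seed = 11)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$peaks$values, d2$peaks$values)
  expect_identical(d1$acts$values, d2$acts$values)

  # zero log-sd: all rows within a group identical
  cfg0 <- synthetic_config(n_samples = 8, n_compounds = 4,
                           group_labels = factor(rep(c("A", "B"), each = 4)),
                           active_sets = list(), noise_sd = numeric(0),
                           abundance_log_sd = rep(0, 4),
                           abundance_log_mean = rep(1, 4),
                           group_shift = c(0, 0, 0.5, 0))
  p0 <- generate_peaks(cfg0)
  expect_true(all(apply(p0$values[1:4, ], 2, function(x) diff(range(x)) == 0)))
  expect_true(all(apply(p0$values[5:8, ], 2, function(x) diff(range(x)) == 0)))
  expect_gt(p0$values[5, 3], p0$values[1, 3])  # group shift applied on log scale

  expect_error(synthetic_config(n_samples = 0), "degenerate")
  expect_error(synthetic_config(n_compounds = 3,
                                active_sets = list(A = c(1, 9)),
                                noise_sd = c(A = 0)), "out of 1..n_compounds")
  expect_error(synthetic_config(n_compounds = 3,
                                active_sets = list(A = 1:2),
                                effect_weights = list(A = 1),
                                noise_sd = c(A = 0)), "length mismatch")
})

test_that("abundance log-means are recovered at large n", {
  mu <- c(2, 4, 6)
  cfg <- synthetic_config(n_samples = 10000, n_compounds = 3, group_labels = NULL,
                          active_sets = list(), noise_sd = numeric(0),
                          abundance_log_mean = mu, abundance_log_sd = rep(0.4, 3),
                          group_shift = rep(0, 3), seed = 5)
  pk <- generate_peaks(cfg)
  lm_hat <- colMeans(log(pk$values))
  se <- 0.4 / sqrt(10000)
  expect_true(all(abs(lm_hat - mu) < 3 * se))
})

test_that("activities follow the configured linear model", {
  # noise-free single active compound with unit weight reproduces the
  # autoscaled column exactly
  cfg <- synthetic_config(n_samples = 20, n_compounds = 5, group_labels = NULL,
                          active_sets = list(A = 3),
                          effect_weights = list(A = 1), noise_sd = c(A = 0),
                          abundance_log_mean = rep(1, 5),
                          abundance_log_sd = rep(0.5, 5),
                          group_shift = rep(0, 5), seed = 2)
  pk <- generate_peaks(cfg)
  ac <- generate_activities(pk, cfg)
  z3 <- as.numeric(scale(pk$values[, 3]))
  expect_equal(unname(ac$values[, "A"]), z3, tolerance = 1e-12)
  gt <- attr(ac, "ground_truth")
  expect_identical(gt$active_sets$A, "3")

  # empty active set: activity independent of every compound
  cfg0 <- synthetic_config(n_samples = 5000, n_compounds = 6, group_labels = NULL,
                           active_sets = list(N = integer(0)),
                           effect_weights = list(N = numeric(0)),
                           noise_sd = c(N = 1),
                           abundance_log_mean = rep(0, 6),
                           abundance_log_sd = rep(0.3, 6),
                           group_shift = rep(0, 6), seed = 3)
  p0 <- generate_peaks(cfg0)
  a0 <- generate_activities(p0, cfg0)
  r <- abs(cor(p0$values, a0$values[, 1]))
  expect_lt(max(r), 0.05)

  # a strongly-weighted compound shared by two assays tops both correlations
  cfg2 <- synthetic_config(n_samples = 500, n_compounds = 6, group_labels = NULL,
                           active_sets = list(A = 2, B = 2),
                           effect_weights = list(A = 3, B = 3),
                           noise_sd = c(A = 0.3, B = 0.3),
                           abundance_log_mean = rep(0, 6),
                           abundance_log_sd = rep(0.3, 6),
                           group_shift = rep(0, 6), block_correlation = 0,
                           seed = 4)
  p2 <- generate_peaks(cfg2)
  a2 <- generate_activities(p2, cfg2)
  r2 <- abs(cor(p2$values, a2$values))
  expect_equal(unname(apply(r2, 2, which.max)), c(2, 2))
})

test_that("noise-free data with orthogonalized inactives needs one component", {
  cfg <- synthetic_config(n_samples = 15, n_compounds = 4, group_labels = NULL,
                          active_sets = list(A = 2), effect_weights = list(A = 1.5),
                          noise_sd = c(A = 0), abundance_log_mean = rep(0, 4),
                          abundance_log_sd = rep(0.4, 4), group_shift = rep(0, 4),
                          block_correlation = 0, seed = 9)
  pk <- generate_peaks(cfg)
  a <- generate_activities(pk, cfg)
  X <- pk$values
  # orthogonalize the inactive columns against the active one
  for (j in c(1, 3, 4)) X[, j] <- resid(lm(X[, j] ~ X[, 2]))
  fit <- fit_pls(X, a$values[, 1], ncomp = 1, scaling = "center")
  expect_gt(fit$r2y_cum[1], 1 - 1e-8)
})
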