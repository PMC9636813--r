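#' @title NIPALS partial least squares regression
#'
#' @description
#' Fits a single-response PLS regression by the NIPALS algorithm with
#' deflation, the latent-variable workhorse for spectrum-effect modelling
#' where predictors (peak areas) are many, collinear and noisy. Returns a
#' classed model object with `print`, `summary`, `coef`, `predict`,
#' `fitted`, `residuals` and `plot` methods.
#'
#' Preprocessing defaults to autoscaling (centring to mean 0 and scaling to
#' unit variance) of both X and y — the convention of the commercial
#' chemometrics suites this mirrors, and the scale on which the
#' coefficient-threshold screening rule (> 0.1) is meaningful. With a single
#' response, NIPALS needs no inner iteration: each component's weight vector
#' is obtained in closed form and X (and y) are deflated before the next.
#'
#' @param X numeric matrix (samples x compounds) or a [peak_table].
#' @param y numeric response vector, or an [activity_table] column given as
#'   `acts$values[, assay]`.
#' @param ncomp number of latent components `A <= min(n - 1, p)`.
#' @param scaling `"autoscale"` (default), `"center"` or `"none"`.
#' @return Object of class `pls_fit` with components `x_weights` (W, columns
#'   unit-norm), `x_loadings` (P), `y_loadings` (q), `scores` (T),
#'   `r2y_cum` (per-component cumulative R2Y on the training data),
#'   `vip`, `coefficients` (standardized scale), preprocessing records and
#'   the training data.
#' @examples
#' d <- generate_dataset(synthetic_config(seed = 7))
#' fit <- fit_pls(d$peaks, d$acts$values[, "DPPH"], ncomp = 2)
#' fit
#' head(sort(fit$vip, decreasing = TRUE))
#' @export
fit_pls <- function(X, y, ncomp = 2, scaling = c("autoscale", "center", "none")) {
  scaling <- match.arg(scaling)
  if (inherits(X, "peak_table")) {
    ids <- X$compound_ids
    X <- X$values
  } else {
    X <- as.matrix(X)
    ids <- colnames(X)
    if (is.null(ids)) ids <- as.character(seq_len(ncol(X)))
  }
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("fit_pls: X and y not aligned", call. = FALSE)
  if (n < 3) stop("fit_pls: need at least 3 samples", call. = FALSE)
  if (p < 1) stop("fit_pls: need at least 1 predictor", call. = FALSE)
  if (ncomp < 1 || ncomp > min(n - 1, p))
    stop("fit_pls: ncomp must be in 1..min(n - 1, p)", call. = FALSE)
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("fit_pls: non-finite values in X or y", call. = FALSE)

  pre <- pls_preprocess(X, y, scaling, ids)
  core <- nipals_core(pre$Xs, pre$ys, ncomp)

  # regression vector on the preprocessed scale, per cumulative A
  b <- pls_beta(core$W, core$P, core$q, core$A)
  sstot <- sum((y - mean(y))^2)
  fitted_pre <- core$T %*% diag(core$q, nrow = core$A)  # componentwise contributions
  r2y_cum <- vapply(seq_len(core$A), function(a) {
    yhat <- pre$y_center + pre$y_scale * rowSums(fitted_pre[, seq_len(a), drop = FALSE])
    1 - sum((y - yhat)^2) / sstot
  }, numeric(1))

  fitted <- pre$y_center + pre$y_scale * drop(core$T %*% core$q)
  obj <- structure(list(
    n_components = core$A, x_weights = core$W, x_loadings = core$P,
    y_loadings = core$q, scores = core$T, tss_scores = core$tt,
    r2y_cum = r2y_cum, scaling = scaling,
    x_means = pre$x_means, x_sds = pre$x_sds,
    y_mean = pre$y_mean, y_sd = pre$y_sd,
    x_center = pre$x_center, x_scale = pre$x_scale,
    y_center = pre$y_center, y_scale = pre$y_scale,
    b_pre = b, compound_ids = ids, y = y, fitted = fitted,
    call = match.call()), class = "pls_fit")
  obj$vip <- vip_scores(obj)
  obj$coefficients <- standardized_coefficients(obj)
  obj
}

pls_preprocess <- function(X, y, scaling, ids) {
  x_means <- colMeans(X); x_sds <- apply(X, 2, stats::sd)
  y_mean <- mean(y); y_sd <- stats::sd(y)
  if (scaling == "autoscale" && any(x_sds == 0))
    stop(sprintf("fit_pls: zero-variance compound column '%s' cannot be autoscaled",
                 ids[which(x_sds == 0)[1]]), call. = FALSE)
  if (y_sd == 0) stop("fit_pls: constant response", call. = FALSE)
  x_center <- if (scaling == "none") rep(0, ncol(X)) else x_means
  x_scale <- if (scaling == "autoscale") x_sds else rep(1, ncol(X))
  y_center <- if (scaling == "none") 0 else y_mean
  y_scale <- if (scaling == "autoscale") y_sd else 1
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, `/`)
  ys <- (y - y_center) / y_scale
  list(Xs = Xs, ys = ys, x_means = x_means, x_sds = x_sds,
       y_mean = y_mean, y_sd = y_sd, x_center = x_center, x_scale = x_scale,
       y_center = y_center, y_scale = y_scale)
}

# Single-y NIPALS with X and y deflation. Stops early (A reduced) if the
# residual X block is numerically exhausted.
nipals_core <- function(Xs, ys, ncomp) {
  n <- nrow(Xs); p <- ncol(Xs)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp); tt <- numeric(ncomp)
  Xd <- Xs; yd <- ys
  A <- 0
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) break
    w <- w / nw
    t_a <- drop(Xd %*% w)
    tta <- sum(t_a^2)
    if (tta < 1e-14) break
    p_a <- drop(crossprod(Xd, t_a)) / tta
    q_a <- sum(yd * t_a) / tta
    Xd <- Xd - tcrossprod(t_a, p_a)
    yd <- yd - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; q[a] <- q_a; tt[a] <- tta
    A <- a
  }
  if (A == 0) stop("fit_pls: X carries no covariance with y", call. = FALSE)
  list(W = W[, seq_len(A), drop = FALSE], P = P[, seq_len(A), drop = FALSE],
       T = Tm[, seq_len(A), drop = FALSE], q = q[seq_len(A)],
       tt = tt[seq_len(A)], A = A)
}

pls_beta <- function(W, P, q, A) {
  Wa <- W[, seq_len(A), drop = FALSE]
  M <- crossprod(P[, seq_len(A), drop = FALSE], Wa)
  sol <- tryCatch(solve(M, q[seq_len(A)]),
                  error = function(e) stop("fit_pls: singular (P'W); reduce ncomp",
                                           call. = FALSE))
  drop(Wa %*% sol)
}

#' Variable importance in the projection
#'
#' `VIP_j = sqrt(p * sum_a SSY_a * w_ja^2 / sum_a SSY_a)` with unit-norm
#' weight vectors `w_a` and `SSY_a` the y-variance explained by component
#' `a`. The squared scores average to 1 over predictors
#' (`mean(VIP^2) = 1`), so VIP > 1 flags above-average importance.
#'
#' @param model a [fit_pls()] object.
#' @return Named non-negative numeric vector, one per compound.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "pls_fit"))
  ssy <- model$y_loadings^2 * model$tss_scores
  if (sum(ssy) <= 0) stop("vip_scores: model explains no y-variance", call. = FALSE)
  p <- nrow(model$x_weights)
  v <- sqrt(p * drop(model$x_weights^2 %*% ssy) / sum(ssy))
  names(v) <- model$compound_ids
  v
}

#' Standardized PLS regression coefficients
#'
#' Coefficients mapping autoscaled predictors to the autoscaled response
#' (`b = W (P'W)^{-1} q` on that metric) — the scale on which the screening
#' threshold (coefficient > 0.1) is interpreted, comparable across
#' compounds regardless of raw abundance magnitude.
#'
#' @param model a [fit_pls()] object.
#' @return Named numeric vector, one per compound.
#' @export
standardized_coefficients <- function(model) {
  stopifnot(inherits(model, "pls_fit"))
  b <- model$b_pre  # preprocessed-X -> preprocessed-y scale
  # convert to the autoscaled metric whatever scaling was used in the fit
  b_std <- b * (model$x_sds / model$x_scale) * (model$y_scale / model$y_sd)
  names(b_std) <- model$compound_ids
  b_std
}

#' @export
coef.pls_fit <- function(object, type = c("standardized", "raw"), ...) {
  type <- match.arg(type)
  if (type == "standardized") return(object$coefficients)
  b_raw <- object$b_pre / object$x_scale * object$y_scale
  names(b_raw) <- object$compound_ids
  attr(b_raw, "intercept") <- object$y_center - sum(b_raw * object$x_center)
  b_raw
}

#' @export
predict.pls_fit <- function(object, newdata, ncomp = object$n_components, ...) {
  if (inherits(newdata, "peak_table")) newdata <- newdata$values
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$x_weights))
    stop("predict.pls_fit: newdata has wrong number of compounds", call. = FALSE)
  if (ncomp < 1 || ncomp > object$n_components)
    stop("predict.pls_fit: ncomp out of fitted range", call. = FALSE)
  b <- pls_beta(object$x_weights, object$x_loadings, object$y_loadings, ncomp)
  Xs <- sweep(sweep(newdata, 2, object$x_center), 2, object$x_scale, `/`)
  drop(object$y_center + object$y_scale * (Xs %*% b))
}

#' @export
fitted.pls_fit <- function(object, ...) object$fitted

#' @export
residuals.pls_fit <- function(object, ...) object$y - object$fitted

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("NIPALS PLS regression: %d component(s), %d samples x %d compounds (%s scaling)\n",
              x$n_components, nrow(x$scores), length(x$compound_ids), x$scaling))
  cat(sprintf("  R2Y(cum) = %.3f\n", x$r2y_cum[x$n_components]))
  invisible(x)
}

#' @export
summary.pls_fit <- function(object, ...) {
  out <- list(n_components = object$n_components, r2y_cum = object$r2y_cum,
              vip = object$vip, coefficients = object$coefficients,
              scaling = object$scaling)
  class(out) <- "summary.pls_fit"
  out
}

#' @export
print.summary.pls_fit <- function(x, digits = 3, ...) {
  cat(sprintf("PLS model with %d component(s), %s scaling\n", x$n_components, x$scaling))
  cat("Cumulative R2Y by component:",
      paste(round(x$r2y_cum, digits), collapse = ", "), "\n\n")
  tab <- data.frame(VIP = round(x$vip, digits),
                    coefficient = round(x$coefficients, digits))
  print(tab[order(-tab$VIP), ])
  invisible(x)
}

#' @export
plot.pls_fit <- function(x, type = c("scores", "vip"), ...) {
  type <- match.arg(type)
  if (type == "scores") {
    if (x$n_components >= 2) {
      graphics::plot(x$scores[, 1], x$scores[, 2], xlab = "t[1]", ylab = "t[2]",
                     main = "PLS score plot", ...)
    } else {
      graphics::plot(x$scores[, 1], x$y, xlab = "t[1]", ylab = "y",
                     main = "PLS score vs response", ...)
    }
  } else {
    ord <- order(x$vip, decreasing = TRUE)
    graphics::barplot(x$vip[ord], las = 2, ylab = "VIP",
                      main = "Variable importance in projection", ...)
    graphics::abline(h = 1, lty = 2)
  }
  invisible(x)
}

#' Cross-validated predictive ability Q2 by component count
#'
#' K-fold cross-validation of a NIPALS PLS model:
#' `Q2(A) = 1 - PRESS(A) / TSS` where `PRESS(A)` accumulates squared
#' prediction errors of held-out samples from models with `A` components
#' (preprocessing re-estimated inside every training fold) and `TSS` is the
#' total sum of squares of `y` about its overall mean. Fold membership is a
#' seeded shuffle followed by contiguous-block assignment (the convention of
#' the commercial suites); `folds = n` gives leave-one-out.
#'
#' @param X predictor matrix or [peak_table].
#' @param y response vector.
#' @param max_A largest component count to evaluate.
#' @param folds number of folds in `[2, n]` (default 7).
#' @param seed integer seed for the fold shuffle.
#' @param scaling passed to the inner fits.
#' @return Named numeric vector `Q2[1..max_A]`.
#' @export
cross_validate_q2 <- function(X, y, max_A, folds = 7, seed = 1,
                              scaling = c("autoscale", "center", "none")) {
  scaling <- match.arg(scaling)
  if (inherits(X, "peak_table")) X <- X$values
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (folds < 2 || folds > n)
    stop("cross_validate_q2: folds must be in [2, n]", call. = FALSE)
  if (max_A > min(n - ceiling(n / folds) - 1, ncol(X)))
    stop("cross_validate_q2: max_A too large for the training-fold size", call. = FALSE)
  set.seed(seed)
  ord <- sample.int(n)
  # contiguous blocks over the shuffled order
  fold_id <- integer(n)
  fold_id[ord] <- cut(seq_len(n), folds, labels = FALSE)
  press <- numeric(max_A)
  ids <- colnames(X); if (is.null(ids)) ids <- as.character(seq_len(ncol(X)))
  for (k in seq_len(folds)) {
    test <- which(fold_id == k)
    train <- setdiff(seq_len(n), test)
    if (length(train) < 2)
      stop("cross_validate_q2: a training fold has fewer than 2 samples", call. = FALSE)
    pre <- pls_preprocess(X[train, , drop = FALSE], y[train], scaling, ids)
    core <- nipals_core(pre$Xs, pre$ys, max_A)
    Xs_test <- sweep(sweep(X[test, , drop = FALSE], 2, pre$x_center), 2,
                     pre$x_scale, `/`)
    for (a in seq_len(max_A)) {
      b <- pls_beta(core$W, core$P, core$q, min(a, core$A))
      pred <- pre$y_center + pre$y_scale * drop(Xs_test %*% b)
      press[a] <- press[a] + sum((y[test] - pred)^2)
    }
  }
  tss <- sum((y - mean(y))^2)
  stats::setNames(1 - press / tss, paste0("A", seq_len(max_A)))
}

#' Choose the number of PLS components from a Q2 profile
#'
#' @param q2_by_A numeric vector of Q2 values indexed by component count.
#' @param rule `"max_q2"` (default): the smallest A whose Q2 is within `tol`
#'   of the maximum; `"gain_threshold"`: grow while the Q2 gain exceeds
#'   `gain`.
#' @param tol closeness to the maximum for `"max_q2"` (default 0.01).
#' @param gain minimum per-component improvement for `"gain_threshold"`
#'   (default 0.05).
#' @return Integer component count. If every Q2 is negative, returns 1 with
#'   a "no predictive component" warning.
#' @export
select_components <- function(q2_by_A, rule = c("max_q2", "gain_threshold"),
                              tol = 0.01, gain = 0.05) {
  rule <- match.arg(rule)
  if (length(q2_by_A) == 0) stop("select_components: empty Q2 profile", call. = FALSE)
  if (all(q2_by_A < 0)) {
    warning("select_components: no predictive component (all Q2 < 0); using A = 1")
    return(1L)
  }
  if (rule == "max_q2") {
    return(as.integer(which(q2_by_A >= max(q2_by_A) - tol)[1]))
  }
  A <- 1L
  while (A < length(q2_by_A) && (q2_by_A[A + 1] - q2_by_A[A]) > gain) A <- A + 1L
  A
}

#' Y-permutation validation of a PLS model
#'
#' Refits the model `n_perm` times with the response permuted uniformly at
#' random, recording R2Y and cross-validated Q2 each time. Overfitting shows
#' up as permuted statistics rivalling the observed ones. The regression
#' intercepts follow the chemometric validation-plot convention: each
#' statistic is regressed on the absolute correlation between the permuted
#' and original response (the observed model sits at correlation 1), and the
#' value of that line at correlation 0 is reported. The one-sided empirical
#' p-value for Q2 uses the add-one rule,
#' `p = (1 + #{Q2_perm >= Q2_obs}) / (n_perm + 1)`.
#'
#' @param X predictor matrix or [peak_table].
#' @param y response vector.
#' @param A number of components (fixed across refits).
#' @param n_perm number of permutations, `>= 20` (default 199, giving p
#'   resolution 0.005).
#' @param seed integer seed; permutations and inner CV folds derive from it.
#' @param folds CV folds for the Q2 of each refit.
#' @param scaling passed to the fits.
#' @return Object of class `pls_permutation` with the permuted and observed
#'   statistics, the correlation-axis intercepts and `empirical_p_q2`.
#' @export
permutation_test <- function(X, y, A, n_perm = 199, seed = 1, folds = 7,
                             scaling = "autoscale") {
  if (inherits(X, "peak_table")) X <- X$values
  X <- as.matrix(X); y <- as.numeric(y)
  if (n_perm < 20) stop("permutation_test: n_perm must be >= 20", call. = FALSE)
  if (stats::sd(y) == 0)
    stop("permutation_test: constant response cannot be permuted meaningfully",
         call. = FALSE)
  obs_fit <- fit_pls(X, y, ncomp = A, scaling = scaling)
  obs_r2 <- obs_fit$r2y_cum[A]
  obs_q2 <- cross_validate_q2(X, y, max_A = A, folds = folds,
                              seed = substream_seed(seed, "cv"),
                              scaling = scaling)[A]
  set.seed(substream_seed(seed, "perm"))
  perm_seeds <- sample.int(2147480000, n_perm)
  perm_r2 <- perm_q2 <- abscor <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    set.seed(perm_seeds[i])
    yp <- sample(y)
    abscor[i] <- abs(stats::cor(yp, y))
    fit_i <- fit_pls(X, yp, ncomp = A, scaling = scaling)
    perm_r2[i] <- fit_i$r2y_cum[fit_i$n_components]
    perm_q2[i] <- cross_validate_q2(X, yp, max_A = A, folds = folds,
                                    seed = perm_seeds[i], scaling = scaling)[A]
  }
  r2_int <- unname(stats::coef(stats::lm(c(perm_r2, obs_r2) ~ c(abscor, 1)))[1])
  q2_int <- unname(stats::coef(stats::lm(c(perm_q2, obs_q2) ~ c(abscor, 1)))[1])
  structure(list(n_permutations = n_perm, permuted_r2 = perm_r2,
                 permuted_q2 = perm_q2, abs_correlation = abscor,
                 observed_r2 = unname(obs_r2), observed_q2 = unname(obs_q2),
                 r2_intercept = r2_int, q2_intercept = q2_int,
                 empirical_p_q2 = (1 + sum(perm_q2 >= obs_q2)) / (n_perm + 1),
                 A = A, seed = seed),
            class = "pls_permutation")
}

#' @export
print.pls_permutation <- function(x, ...) {
  cat(sprintf("Y-permutation test (%d permutations, A = %d)\n", x$n_permutations, x$A))
  cat(sprintf("  observed  R2Y = %.3f, Q2 = %.3f\n", x$observed_r2, x$observed_q2))
  cat(sprintf("  intercepts at cor = 0: R2 %.3f, Q2 %.3f\n",
              x$r2_intercept, x$q2_intercept))
  cat(sprintf("  empirical p (Q2) = %.4f\n", x$empirical_p_q2))
  invisible(x)
}

#' @export
plot.pls_permutation <- function(x, ...) {
  xs <- c(x$abs_correlation, 1)
  graphics::plot(x$abs_correlation, x$permuted_r2, pch = 1, col = "grey40",
                 xlim = c(0, 1), ylim = range(c(x$permuted_q2, x$permuted_r2,
                                                x$observed_r2, x$observed_q2)),
                 xlab = "|cor(permuted y, y)|", ylab = "statistic",
                 main = "Permutation validation", ...)
  graphics::points(x$abs_correlation, x$permuted_q2, pch = 2, col = "grey60")
  graphics::points(c(1, 1), c(x$observed_r2, x$observed_q2),
                   pch = c(16, 17), col = c("black", "blue"))
  graphics::abline(stats::lm(c(x$permuted_r2, x$observed_r2) ~ xs), lty = 2)
  graphics::abline(stats::lm(c(x$permuted_q2, x$observed_q2) ~ xs), lty = 3, col = "blue")
  graphics::legend("bottomright", c("R2 (perm)", "Q2 (perm)", "R2 (obs)", "Q2 (obs)"),
                   pch = c(1, 2, 16, 17), col = c("grey40", "grey60", "black", "blue"),
                   bty = "n")
  invisible(x)
}
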