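# Independent oracles, written from the definitions and kept free of the
# package's vectorized code paths.

# Naive loop evaluation of Deng's grey relational degree: per assay, form
# every deviation |x0'(k) - xi'(k)| with explicit loops, then the
# coefficient and its mean.
gra_oracle <- function(peak_mat, act_mat, rho = 0.5,
                       norm = function(x) x / mean(x)) {
  p <- ncol(peak_mat); n <- nrow(peak_mat); m <- ncol(act_mat)
  grd <- matrix(NA_real_, p, m)
  Xn <- apply(peak_mat, 2, norm)
  for (a in seq_len(m)) {
    x0 <- norm(act_mat[, a])
    delta <- matrix(NA_real_, n, p)
    for (i in seq_len(p)) for (k in seq_len(n)) delta[k, i] <- abs(x0[k] - Xn[k, i])
    dmin <- min(delta); dmax <- max(delta)
    for (i in seq_len(p)) {
      xi <- numeric(n)
      for (k in seq_len(n)) xi[k] <- (dmin + rho * dmax) / (delta[k, i] + rho * dmax)
      grd[i, a] <- mean(xi)
    }
  }
  grd
}

# One-component PLS prediction from the definition (autoscaled metric),
# used as the brute-force oracle for leave-one-out PRESS.
pls1_predict_oracle <- function(Xtr, ytr, Xte) {
  xm <- colMeans(Xtr); xs <- apply(Xtr, 2, sd)
  ym <- mean(ytr); ys <- sd(ytr)
  Zs <- sweep(sweep(Xtr, 2, xm), 2, xs, `/`)
  zy <- (ytr - ym) / ys
  w <- drop(crossprod(Zs, zy)); w <- w / sqrt(sum(w^2))
  t1 <- drop(Zs %*% w)
  q1 <- sum(zy * t1) / sum(t1^2)
  Zte <- sweep(sweep(Xte, 2, xm), 2, xs, `/`)
  ym + ys * q1 * drop(Zte %*% w)
}

random_instance <- function(n, p, seed, noise = 0.5) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  beta <- rnorm(p)
  y <- drop(X %*% beta + rnorm(n, 0, noise))
  list(X = X, y = y)
}
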