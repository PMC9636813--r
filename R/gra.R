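#' Grey relational analysis configuration
#'
#' @param rho distinguishing coefficient in `(0, 1]` (conventionally 0.5);
#'   larger values compress the relational coefficients towards 1.
#' @param normalization series preprocessing: `"mean"` (divide by the series
#'   mean; default — robust to arbitrary sample ordering), `"initial_value"`
#'   (divide by the first element), `"min_max"` (rescale to `[0, 1]`) or
#'   `"none"`.
#' @return List of class `gra_config`.
#' @export
gra_config <- function(rho = 0.5,
                       normalization = c("mean", "initial_value", "min_max", "none")) {
  if (!is.numeric(rho) || rho <= 0)
    stop("gra_config: rho must be > 0", call. = FALSE)
  structure(list(rho = rho, normalization = match.arg(normalization)),
            class = "gra_config")
}

#' Normalize a series for grey relational analysis
#'
#' @param series finite numeric vector.
#' @param method one of `"mean"`, `"initial_value"`, `"min_max"`, `"none"`.
#' @param label series name used in error messages.
#' @return The normalized vector.
#' @examples
#' normalize_series(c(2, 4, 6), "mean")  # 0.5 1.0 1.5
#' @export
normalize_series <- function(series, method = "mean", label = "series") {
  if (any(!is.finite(series)))
    stop(sprintf("normalize_series: non-finite value in %s", label), call. = FALSE)
  switch(method,
    mean = {
      m <- mean(series)
      if (m == 0) stop(sprintf("normalize_series: zero mean in %s", label), call. = FALSE)
      series / m
    },
    initial_value = {
      if (series[1] == 0)
        stop(sprintf("normalize_series: zero initial value in %s", label), call. = FALSE)
      series / series[1]
    },
    min_max = {
      r <- range(series)
      if (r[1] == r[2]) rep(0, length(series)) else (series - r[1]) / (r[2] - r[1])
    },
    none = series,
    stop(sprintf("normalize_series: unknown method '%s'", method), call. = FALSE))
}

#' Grey relational degree between compounds and activities
#'
#' Deng-style grey relational analysis: each assay column of `acts` is the
#' reference series `x0`, each compound column of `peaks` a comparison
#' series `xi`. After per-series normalization, the absolute deviations
#' `Delta_i(k) = |x0'(k) - xi'(k)|` are formed; with `Dmin`/`Dmax` the
#' extremes of `Delta` over all compounds and samples jointly for that assay
#' (the global convention; a per-compound variant also exists in the
#' literature), the relational coefficient is
#' `xi_i(k) = (Dmin + rho * Dmax) / (Delta_i(k) + rho * Dmax)` and the grey
#' relational degree (GRD) is its mean over samples. Every coefficient and
#' degree lies in `(0, 1]`, with GRD = 1 exactly when the normalized series
#' coincide. When all normalized series are identical (`Dmax = 0`) the
#' coefficients are defined as 1.
#'
#' @param peaks a [peak_table].
#' @param acts an aligned [activity_table] (same samples, same order; use
#'   [align_tables()] first).
#' @param config a [gra_config()].
#' @param keep_coefficients if `TRUE`, attach the per-sample coefficient
#'   arrays.
#' @return Object of class `gra_result`: `grd` is a compounds x assays
#'   matrix.
#' @export
grey_relational_degree <- function(peaks, acts, config = gra_config(),
                                   keep_coefficients = FALSE) {
  stopifnot(inherits(peaks, "peak_table"), inherits(acts, "activity_table"),
            inherits(config, "gra_config"))
  if (!identical(peaks$sample_ids, acts$sample_ids))
    stop("grey_relational_degree: tables not aligned; run align_tables() first",
         call. = FALSE)
  n <- length(peaks$sample_ids)
  if (n < 2) stop("grey_relational_degree: need at least 2 samples", call. = FALSE)
  p <- length(peaks$compound_ids)
  rho <- config$rho
  Xn <- sapply(seq_len(p), function(j)
    normalize_series(peaks$values[, j], config$normalization,
                     paste0("compound '", peaks$compound_ids[j], "'")))
  Xn <- matrix(Xn, nrow = n)
  grd <- matrix(NA_real_, p, length(acts$assay_ids),
                dimnames = list(peaks$compound_ids, acts$assay_ids))
  coefs <- if (keep_coefficients)
    array(NA_real_, c(p, length(acts$assay_ids), n),
          dimnames = list(peaks$compound_ids, acts$assay_ids, peaks$sample_ids))
  for (a in seq_along(acts$assay_ids)) {
    x0 <- normalize_series(acts$values[, a], config$normalization,
                           paste0("assay '", acts$assay_ids[a], "'"))
    delta <- abs(Xn - x0)            # n x p deviations
    dmin <- min(delta); dmax <- max(delta)
    xi <- if (dmax == 0) matrix(1, n, p) else (dmin + rho * dmax) / (delta + rho * dmax)
    grd[, a] <- colMeans(xi)
    if (keep_coefficients) coefs[, a, ] <- t(xi)
  }
  structure(list(grd = grd, config = config,
                 per_sample_coefficients = coefs),
            class = "gra_result")
}

#' @export
print.gra_result <- function(x, digits = 3, ...) {
  cat(sprintf("Grey relational degrees (rho = %g, %s normalization):\n",
              x$config$rho, x$config$normalization))
  print(round(x$grd, digits))
  invisible(x)
}

#' Rank compounds by grey relational degree
#'
#' @param result a [grey_relational_degree()] result.
#' @param assay assay id to rank by.
#' @return Character vector of compound ids, descending GRD; ties broken by
#'   compound id ascending (so equal degrees list in id order).
#' @export
rank_by_grd <- function(result, assay) {
  stopifnot(inherits(result, "gra_result"))
  if (!assay %in% colnames(result$grd))
    stop(sprintf("rank_by_grd: unknown assay '%s'", assay), call. = FALSE)
  ids <- rownames(result$grd)
  g <- result$grd[, assay]
  # numeric-aware tie-break so "2" sorts before "10"
  idnum <- suppressWarnings(as.numeric(ids))
  tie <- if (anyNA(idnum)) order(ids) else order(idnum)
  ids[tie][order(-g[tie])]
}
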