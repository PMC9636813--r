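#' Configuration for the synthetic spectrum-effect data generator
#'
#' Builds the parameter set from which [generate_peaks()] and
#' [generate_activities()] draw reproducible synthetic datasets with known
#' ground-truth active compounds. The defaults emulate the study conditions
#' this pipeline was designed around: 31 herb batches (17 + 14 from two
#' *Taraxacum* species), 22 phenolic peaks (9 phenylpropionic acids, 13
#' flavonoids), two correlated antioxidant assays (DPPH, FRAP) driven by a
#' shared 5-compound active set, and one anti-inflammatory assay
#' (NO-inhibition) driven by 8 mostly-flavonoid actives. Effect weights
#' default to the magnitudes of the standardized coefficients the study
#' reported, and per-assay noise is fixed so that fitted PLS models land near
#' R2Y of 0.90 (DPPH), 0.86 (FRAP) and 0.62 (NO-inhibition).
#'
#' Abundances are log-normal; compounds of the same chemical class share a
#' latent factor with loading `sqrt(block_correlation)`, and group-2 samples
#' receive `group_shift` on the log scale (the defaults give the second
#' species less caftaric/caffeic/cichoric acid and more luteolin).
#'
#' @param n_samples number of samples (default 31).
#' @param n_compounds number of compounds (default 22).
#' @param group_labels optional two-level factor of length `n_samples`.
#' @param compound_class character vector of length `n_compounds`
#'   (`"phenylpropionic_acid"` or `"flavonoid"`); same-class compounds share
#'   the latent abundance factor.
#' @param active_sets named list: assay id -> integer indices of active
#'   compounds.
#' @param effect_weights named list: assay id -> numeric weights, one per
#'   active compound (standardized scale: per unit of autoscaled abundance).
#' @param noise_sd named numeric: assay id -> residual SD on the
#'   standardized scale.
#' @param abundance_log_mean,abundance_log_sd per-compound log-scale mean and
#'   SD of peak areas.
#' @param group_shift per-compound log-scale offset added to group-2 samples.
#' @param block_correlation within-class abundance correlation in `[0, 1)`.
#' @param assay_intercept,assay_scale named numerics mapping the standardized
#'   activity onto the assay's reporting scale
#'   (`value = intercept + scale * standardized`); assays not named default
#'   to intercept 0, scale 1.
#' @param seed integer master seed; per-stage substreams are derived from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 31,
                             n_compounds = 22,
                             group_labels = NULL,
                             compound_class = NULL,
                             active_sets = NULL,
                             effect_weights = NULL,
                             noise_sd = NULL,
                             abundance_log_mean = NULL,
                             abundance_log_sd = NULL,
                             group_shift = NULL,
                             block_correlation = 0.3,
                             assay_intercept = c(DPPH = 36, FRAP = 70, NO_inhibition = 42),
                             assay_scale = c(DPPH = 18, FRAP = 22, NO_inhibition = 10),
                             seed = 1L) {
  if (n_samples < 1 || n_compounds < 1)
    stop("synthetic_config: degenerate dimensions", call. = FALSE)
  if (is.null(group_labels) && n_samples == 31)
    group_labels <- factor(rep(c("TAM", "TAO"), c(17, 14)))
  if (!is.null(group_labels)) {
    group_labels <- as.factor(group_labels)
    if (length(group_labels) != n_samples)
      stop("synthetic_config: group_labels length mismatch", call. = FALSE)
    if (nlevels(group_labels) > 2)
      stop("synthetic_config: at most two groups supported", call. = FALSE)
  }
  if (is.null(compound_class)) {
    compound_class <- rep("flavonoid", n_compounds)
    acids <- intersect(c(1, 2, 3, 4, 5, 7, 8, 11, 14), seq_len(n_compounds))
    compound_class[acids] <- "phenylpropionic_acid"
  }
  if (length(compound_class) != n_compounds)
    stop("synthetic_config: compound_class length mismatch", call. = FALSE)
  if (is.null(active_sets) && n_compounds == 22) {
    active_sets <- list(DPPH = c(1, 3, 5, 7, 18), FRAP = c(1, 3, 5, 7, 18),
                        NO_inhibition = c(8, 9, 13, 17, 18, 19, 20, 21))
  }
  if (is.null(active_sets)) active_sets <- list()
  if (is.null(effect_weights) && identical(names(active_sets),
                                           c("DPPH", "FRAP", "NO_inhibition"))) {
    effect_weights <- list(DPPH = c(0.40, 0.29, 0.28, 0.19, 0.24),
                           FRAP = c(0.35, 0.26, 0.43, 0.12, 0.31),
                           NO_inhibition = c(0.13, 0.12, 0.13, 0.11, 0.13, 0.21, 0.16, 0.17))
  }
  if (is.null(effect_weights))
    effect_weights <- lapply(active_sets, function(s) rep(1, length(s)))
  if (is.null(noise_sd))
    noise_sd <- c(DPPH = 0.32, FRAP = 0.39, NO_inhibition = 0.60)[names(active_sets)]
  noise_sd <- unlist(noise_sd)
  if (is.null(names(noise_sd)) && length(noise_sd) == length(active_sets))
    names(noise_sd) <- names(active_sets)
  for (a in names(active_sets)) {
    s <- active_sets[[a]]
    if (length(s) > 0 && (any(s < 1) || any(s > n_compounds)))
      stop(sprintf("synthetic_config: active set for '%s' out of 1..n_compounds", a),
           call. = FALSE)
    if (length(effect_weights[[a]]) != length(s))
      stop(sprintf("synthetic_config: weight vector length mismatch for '%s'", a),
           call. = FALSE)
    if (is.na(noise_sd[a]) || noise_sd[a] < 0)
      stop(sprintf("synthetic_config: noise_sd for '%s' must be >= 0", a), call. = FALSE)
  }
  if (is.null(abundance_log_mean))
    abundance_log_mean <- seq(11, 12, length.out = n_compounds) +
      ifelse(seq_len(n_compounds) == 7, log(25), 0)
  if (is.null(abundance_log_sd)) abundance_log_sd <- rep(0.4, n_compounds)
  if (is.null(group_shift)) {
    group_shift <- rep(0, n_compounds)
    group_shift[intersect(c(1, 5, 7), seq_len(n_compounds))] <- -0.5
    if (n_compounds >= 18) group_shift[18] <- 0.4
  }
  stopifnot(length(abundance_log_mean) == n_compounds,
            length(abundance_log_sd) == n_compounds,
            length(group_shift) == n_compounds)
  if (any(abundance_log_sd < 0))
    stop("synthetic_config: abundance_log_sd must be >= 0", call. = FALSE)
  if (block_correlation < 0 || block_correlation >= 1)
    stop("synthetic_config: block_correlation must be in [0, 1)", call. = FALSE)
  structure(list(n_samples = n_samples, n_compounds = n_compounds,
                 group_labels = group_labels, compound_class = compound_class,
                 active_sets = active_sets, effect_weights = effect_weights,
                 noise_sd = noise_sd,
                 abundance_log_mean = abundance_log_mean,
                 abundance_log_sd = abundance_log_sd,
                 group_shift = group_shift,
                 block_correlation = block_correlation,
                 assay_intercept = assay_intercept, assay_scale = assay_scale,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Deterministic per-stage substream: keeps every stage independently
# reproducible from one master seed. Kept below 2^31.
substream_seed <- function(seed, stage) {
  offset <- c(peaks = 11L, activities = 23L, cv = 37L, perm = 53L)[[stage]]
  as.integer((as.numeric(seed) * 101 + offset) %% 2147483629)
}

#' Generate a synthetic peak-area table
#'
#' Draws log-normal abundances under the configured per-compound log means
#' and SDs; compounds of the same class share a latent sample factor with
#' loading `sqrt(block_correlation)`, and group-2 samples receive the
#' configured log-scale shift. Fully reproducible from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return A [peak_table] with compound ids `"1"..."p"`, sample ids
#'   `"S01"...`, and compound classes in `compound_meta`. The group factor is
#'   attached as attribute `"group"`.
#' @export
generate_peaks <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_samples; p <- config$n_compounds
  set.seed(substream_seed(config$seed, "peaks"))
  classes <- factor(config$compound_class)
  bc <- config$block_correlation
  # latent per-sample factor per compound class + independent residual
  fac <- matrix(stats::rnorm(n * nlevels(classes)), n, nlevels(classes))
  eps <- matrix(stats::rnorm(n * p), n, p)
  z <- sqrt(bc) * fac[, as.integer(classes), drop = FALSE] + sqrt(1 - bc) * eps
  logv <- sweep(sweep(z, 2, config$abundance_log_sd, `*`), 2,
                config$abundance_log_mean, `+`)
  if (!is.null(config$group_labels)) {
    g2 <- as.integer(config$group_labels) == 2
    logv[g2, ] <- sweep(logv[g2, , drop = FALSE], 2, config$group_shift, `+`)
  }
  meta <- data.frame(name = paste0("compound_", seq_len(p)),
                     class = config$compound_class,
                     stringsAsFactors = FALSE)
  pt <- peak_table(exp(logv), sprintf("S%02d", seq_len(n)),
                   as.character(seq_len(p)), meta)
  attr(pt, "group") <- config$group_labels
  pt
}

#' Generate synthetic bioactivities from a peak table
#'
#' For each configured assay, the standardized activity is
#' `sum(w_j * z_j) + eps` over the assay's active compounds, where `z_j` is
#' the autoscaled (z-scored) abundance of compound `j` and
#' `eps ~ Normal(0, noise_sd^2)`; the reported value is
#' `intercept + scale * standardized` on the assay's unit scale. The
#' ground-truth active sets, weights and noise are attached as attribute
#' `"ground_truth"`.
#'
#' @param peaks a [peak_table], typically from [generate_peaks()].
#' @param config the same [synthetic_config()].
#' @return An [activity_table] with one column per configured assay.
#' @export
generate_activities <- function(peaks, config) {
  stopifnot(inherits(peaks, "peak_table"), inherits(config, "synthetic_config"))
  if (length(peaks$compound_ids) != config$n_compounds)
    stop("generate_activities: peaks incompatible with config dimensions", call. = FALSE)
  n <- nrow(peaks$values)
  assays <- names(config$active_sets)
  if (length(assays) == 0)
    stop("generate_activities: config declares no assays", call. = FALSE)
  sds <- apply(peaks$values, 2, stats::sd)
  z <- scale(peaks$values)
  z[, sds == 0] <- 0  # constant columns carry no signal
  set.seed(substream_seed(config$seed, "activities"))
  vals <- matrix(NA_real_, n, length(assays), dimnames = list(NULL, assays))
  for (a in assays) {
    act <- config$active_sets[[a]]
    w <- config$effect_weights[[a]]
    lin <- if (length(act) > 0) drop(z[, act, drop = FALSE] %*% w) else rep(0, n)
    std <- lin + stats::rnorm(n, 0, config$noise_sd[[a]])
    icpt <- if (a %in% names(config$assay_intercept)) config$assay_intercept[[a]] else 0
    scl <- if (a %in% names(config$assay_scale)) config$assay_scale[[a]] else 1
    vals[, a] <- icpt + scl * std
  }
  at <- activity_table(vals, peaks$sample_ids, assays)
  attr(at, "ground_truth") <- list(active_sets = lapply(config$active_sets,
                                                        function(s) peaks$compound_ids[s]),
                                   effect_weights = config$effect_weights,
                                   noise_sd = config$noise_sd, seed = config$seed)
  at
}

#' Generate a paired synthetic dataset
#'
#' Convenience wrapper running [generate_peaks()] then
#' [generate_activities()] under one configuration.
#'
#' @param config a [synthetic_config()]; default is the paper-like scenario.
#' @return List with `peaks`, `acts`, `config`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  peaks <- generate_peaks(config)
  acts <- generate_activities(peaks, config)
  list(peaks = peaks, acts = acts, config = config)
}
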