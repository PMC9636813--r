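#' PCA sample scores of a quantitation table
#'
#' Autoscales the matrix, drops zero-variance columns with a warning, and
#' takes the singular value decomposition. The sign of each component is
#' fixed so that its largest-magnitude loading is positive, making scores
#' reproducible across platforms.
#'
#' @param table a [peak_table] or numeric matrix (samples x variables).
#' @param n_components number of components to return (default 2).
#' @return Matrix of sample scores with attributes `"loadings"` and
#'   `"explained_variance"` (proportions).
#' @export
pca_scores <- function(table, n_components = 2) {
  X <- if (inherits(table, "peak_table")) table$values else as.matrix(table)
  if (nrow(X) < 2 || ncol(X) < 2)
    stop("pca_scores: need at least 2 samples and 2 variables", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("pca_scores: dropping %d zero-variance column(s)", sum(sds == 0)))
    X <- X[, sds > 0, drop = FALSE]
    if (ncol(X) < 2) stop("pca_scores: fewer than 2 informative columns", call. = FALSE)
  }
  Z <- scale(X)
  n_components <- min(n_components, nrow(X) - 1, ncol(X))
  sv <- svd(Z, nu = n_components, nv = n_components)
  for (k in seq_len(n_components)) {
    j <- which.max(abs(sv$v[, k]))
    if (sv$v[j, k] < 0) { sv$v[, k] <- -sv$v[, k]; sv$u[, k] <- -sv$u[, k] }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], nrow = n_components)
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(n_components)))
  attr(scores, "loadings") <- sv$v
  attr(scores, "explained_variance") <- sv$d^2 / sum(svd(Z)$d^2)
  scores
}

#' Compound-activity Pearson correlation matrix
#'
#' The data behind a chemical-activity correlation heatmap: Pearson
#' correlation of each compound's abundances with each assay's readouts
#' across samples. A constant series yields `NA` (recorded as undefined,
#' never coerced to 0).
#'
#' @param peaks a [peak_table].
#' @param acts an aligned [activity_table].
#' @return Compounds x assays numeric matrix.
#' @export
correlation_heatmap_data <- function(peaks, acts) {
  stopifnot(inherits(peaks, "peak_table"), inherits(acts, "activity_table"))
  if (!identical(peaks$sample_ids, acts$sample_ids))
    stop("correlation_heatmap_data: tables not aligned", call. = FALSE)
  suppressWarnings(stats::cor(peaks$values, acts$values))
}

#' Plot a compound-activity correlation heatmap
#'
#' Base-graphics rendering of [correlation_heatmap_data()]; figures are side
#' artifacts — analyses should assert on the returned matrix, not the image.
#'
#' @param peaks a [peak_table].
#' @param acts an aligned [activity_table].
#' @param ... passed to [graphics::image()].
#' @return The correlation matrix, invisibly.
#' @export
plot_correlation_heatmap <- function(peaks, acts, ...) {
  cm <- correlation_heatmap_data(peaks, acts)
  pal <- grDevices::hcl.colors(64, "Blue-Red 2")
  graphics::image(seq_len(nrow(cm)), seq_len(ncol(cm)), cm, col = pal,
                  zlim = c(-1, 1), xlab = "compound", ylab = "", axes = FALSE, ...)
  graphics::axis(1, seq_len(nrow(cm)), rownames(cm), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(ncol(cm)), colnames(cm), las = 1, cex.axis = 0.8)
  invisible(cm)
}

#' Run the complete discovery pipeline and write a report bundle
#'
#' End-to-end driver: reads (or accepts) the peak and activity tables, runs
#' [screen_pipeline()], applies the drug-likeness admission stage to
#' candidates with descriptors available, and writes the evidence CSV, GRD
#' CSV, admission CSV, a JSON summary and a plain-text log into
#' `output_dir`. Every artifact embeds the package version, the seed and an
#' MD5 hash of the effective configuration, so two runs with the same
#' inputs produce byte-identical summaries.
#'
#' @param peaks a [peak_table] or path to a peak CSV.
#' @param acts an [activity_table] or path to an activity CSV.
#' @param descriptors optional descriptor data frame or CSV path for the
#'   admission stage.
#' @param contents optional named numeric vector of relative contents
#'   (see [druglikeness_report()]).
#' @param output_dir directory for the report bundle (created if missing).
#' @param gra_cfg,screen_cfg,adm_cfg stage configurations.
#' @param seed integer seed recorded in every output.
#' @param n_perm permutations per assay model (0 skips).
#' @param verbose emit per-stage log lines to the console as well.
#' @return The summary list, invisibly; side effect: files in `output_dir`.
#' @export
run_full <- function(peaks, acts, descriptors = NULL, contents = NULL,
                     output_dir = "qmarker_report", gra_cfg = gra_config(),
                     screen_cfg = screening_config(),
                     adm_cfg = admission_config(), seed = 1, n_perm = 0,
                     verbose = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  log_lines <- character(0)
  log_stage <- function(fmt, ...) {
    line <- sprintf("[%7.2fs] %s", proc.time()[["elapsed"]] - t0, sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    if (verbose) message(line)
  }
  if (is.character(peaks)) {
    if (!file.exists(peaks)) stop(sprintf("[input] peak table not found: '%s'", peaks),
                                  call. = FALSE)
    peaks <- read_peak_table(peaks)
  }
  if (is.character(acts)) {
    if (!file.exists(acts)) stop(sprintf("[input] activity table not found: '%s'", acts),
                                 call. = FALSE)
    acts <- read_activity_table(acts)
  }
  if (is.character(descriptors)) descriptors <- read_descriptors(descriptors)
  log_stage("input: %d x %d peak table, %d x %d activity table",
            length(peaks$sample_ids), length(peaks$compound_ids),
            length(acts$sample_ids), length(acts$assay_ids))

  res <- screen_pipeline(peaks, acts, gra_cfg = gra_cfg, screen_cfg = screen_cfg,
                         n_perm = n_perm, seed = seed)
  log_stage("screening: groups %s",
            paste(sprintf("%s={%s}", names(res$groups),
                          vapply(res$groups, paste, "", collapse = ",")),
                  collapse = " "))

  admission <- NULL
  if (!is.null(descriptors)) {
    cand <- unique(unlist(res$groups, use.names = FALSE))
    have <- descriptors$compound_id %in% cand
    if (any(have)) {
      admission <- druglikeness_report(descriptors[have, , drop = FALSE],
                                       contents = contents, config = adm_cfg)
      log_stage("admission: %d candidate(s) with descriptors, %d admissible",
                sum(have), sum(admission$admissible))
    } else {
      log_stage("admission: no descriptors match candidates; stage skipped")
    }
  }

  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(gra = unclass(gra_cfg), screening = unclass(screen_cfg),
              admission = unclass(adm_cfg), seed = seed, n_perm = n_perm)
  cfg_file <- file.path(output_dir, "config.json")
  jsonlite::write_json(cfg, cfg_file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  header <- list(package_version = as.character(utils::packageVersion("qmarker")),
                 seed = seed, config_hash = unname(tools::md5sum(cfg_file)))

  utils::write.csv(res$evidence, file.path(output_dir, "evidence.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(compound = rownames(res$gra$grd), res$gra$grd,
                              check.names = FALSE),
                   file.path(output_dir, "grd.csv"), row.names = FALSE)
  if (!is.null(admission))
    utils::write.csv(admission, file.path(output_dir, "admission.csv"),
                     row.names = FALSE)

  summary_obj <- list(
    header = header,
    models = lapply(res$per_assay, function(pa)
      list(A = pa$A, r2y_cum = pa$r2y_cum, q2_cum = pa$q2_cum,
           selected = as.list(pa$selected),
           permutation = if (!is.null(pa$permutation))
             list(p_q2 = pa$permutation$empirical_p_q2,
                  r2_intercept = pa$permutation$r2_intercept,
                  q2_intercept = pa$permutation$q2_intercept))),
    candidate_groups = lapply(res$groups, as.list),
    admitted = if (!is.null(admission))
      as.list(admission$compound_id[admission$admissible]))
  jsonlite::write_json(summary_obj, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(output_dir, "log.txt"))
  log_stage("report bundle written to %s", output_dir)
  invisible(summary_obj)
}
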