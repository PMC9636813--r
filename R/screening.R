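#' Candidate-screening configuration
#'
#' Thresholds and grouping for turning per-assay PLS statistics into
#' candidate marker sets. Selection uses strict inequalities: a compound is
#' a candidate for an assay when `VIP > vip_threshold` and
#' `coefficient > coef_threshold` (standardized scale). Assays within a
#' group are combined by set union to reduce false negatives from
#' assay-specific sensitivity. The grey-relational floor is annotation only:
#' a GRD below it flags a candidate but never removes it, since GRA serves
#' as corroborating, not exclusionary, evidence.
#'
#' @param vip_threshold VIP cut-off (default 1.0; strict `>`).
#' @param coef_threshold standardized-coefficient cut-off (default 0.1;
#'   strict `>`).
#' @param grd_floor annotation floor for grey relational degrees
#'   (default 0.9).
#' @param union_assays named list: activity-group name -> assay ids to
#'   union (default `antioxidant = c("DPPH", "FRAP")`,
#'   `antiinflammatory = "NO_inhibition"`).
#' @param coef_mode `"signed"` (default: coefficient itself must exceed the
#'   threshold) or `"absolute"` (its magnitude must).
#' @return List of class `screening_config`.
#' @export
screening_config <- function(vip_threshold = 1.0, coef_threshold = 0.1,
                             grd_floor = 0.9,
                             union_assays = list(antioxidant = c("DPPH", "FRAP"),
                                                 antiinflammatory = "NO_inhibition"),
                             coef_mode = c("signed", "absolute")) {
  stopifnot(is.finite(vip_threshold), is.finite(coef_threshold), is.finite(grd_floor))
  structure(list(vip_threshold = vip_threshold, coef_threshold = coef_threshold,
                 grd_floor = grd_floor, union_assays = union_assays,
                 coef_mode = match.arg(coef_mode)),
            class = "screening_config")
}

#' Select candidate compounds for one assay
#'
#' Applies the joint rule `VIP > vip_threshold AND coefficient >
#' coef_threshold` (both strict; in `"absolute"` mode the coefficient's
#' magnitude is compared).
#'
#' @param vip named numeric vector of VIP scores.
#' @param coef named numeric vector of standardized coefficients, same
#'   compounds in the same order.
#' @param config a [screening_config()].
#' @return Character vector of selected compound ids.
#' @export
select_by_assay <- function(vip, coef, config = screening_config()) {
  if (length(vip) != length(coef))
    stop("select_by_assay: vip and coef lengths differ", call. = FALSE)
  ids <- names(vip)
  if (is.null(ids)) ids <- as.character(seq_along(vip))
  if (!is.null(names(coef)) && !identical(names(coef), ids))
    stop("select_by_assay: vip and coef name mismatch", call. = FALSE)
  cval <- if (config$coef_mode == "absolute") abs(coef) else coef
  ids[vip > config$vip_threshold & cval > config$coef_threshold]
}

#' Union candidate sets across the assays of an activity group
#'
#' @param per_assay_sets named list: assay id -> character vector of
#'   selected compound ids.
#' @param group activity-group name present in `config$union_assays`.
#' @param config a [screening_config()].
#' @return Character vector (the union, in numeric-aware id order) with
#'   attribute `"provenance"`: a named list giving, per compound, the
#'   assay(s) that selected it.
#' @export
union_candidates <- function(per_assay_sets, group, config = screening_config()) {
  assays <- config$union_assays[[group]]
  if (is.null(assays) || length(assays) == 0)
    stop(sprintf("union_candidates: group '%s' is not configured", group), call. = FALSE)
  missing <- setdiff(assays, names(per_assay_sets))
  if (length(missing) > 0)
    stop(sprintf("union_candidates: no selection for assay(s) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  members <- unique(unlist(per_assay_sets[assays], use.names = FALSE))
  idnum <- suppressWarnings(as.numeric(members))
  members <- if (anyNA(idnum)) sort(members) else members[order(idnum)]
  prov <- lapply(members, function(id)
    assays[vapply(assays, function(a) id %in% per_assay_sets[[a]], logical(1))])
  names(prov) <- members
  attr(members, "provenance") <- prov
  members
}

#' Annotate candidates with grey relational degrees
#'
#' Attaches each candidate's GRDs for the relevant assays and flags (without
#' removing) any candidate whose GRD falls below the configured floor.
#'
#' @param candidates character vector of compound ids.
#' @param gra a [grey_relational_degree()] result covering those compounds.
#' @param config a [screening_config()].
#' @param assays assay columns to annotate with (default: all in `gra`).
#' @return Data frame: one row per candidate, GRD columns, and
#'   `below_grd_floor` logical.
#' @export
annotate_with_grd <- function(candidates, gra, config = screening_config(),
                              assays = colnames(gra$grd)) {
  stopifnot(inherits(gra, "gra_result"))
  missing <- setdiff(candidates, rownames(gra$grd))
  if (length(missing) > 0)
    stop(sprintf("annotate_with_grd: compound(s) %s absent from GRA result",
                 paste(missing, collapse = ", ")), call. = FALSE)
  g <- gra$grd[candidates, assays, drop = FALSE]
  out <- data.frame(compound = candidates, stringsAsFactors = FALSE)
  for (a in assays) out[[paste0("grd_", a)]] <- g[, a]
  out$below_grd_floor <- apply(g < config$grd_floor, 1, any)
  rownames(out) <- NULL
  out
}

#' Run the full spectrum-effect screening pipeline
#'
#' Aligns the tables, computes grey relational degrees, fits one PLS model
#' per assay (component count chosen by cross-validated Q2, optional
#' Y-permutation validation), applies the VIP/coefficient selection rule,
#' unions candidate sets within each activity group and annotates the
#' result with GRD evidence.
#'
#' @param peaks a [peak_table].
#' @param acts an [activity_table] (aligned by sample id internally).
#' @param gra_cfg a [gra_config()].
#' @param screen_cfg a [screening_config()]; groups referencing assays not
#'   present in `acts` are dropped with a message.
#' @param max_A largest component count tried (default
#'   `min(5, n - ceiling(n / folds) - 1, p)`).
#' @param folds CV folds (default 7).
#' @param n_perm permutations for model validation; `0` (default) skips the
#'   permutation test, which is the expensive step and is usually run
#'   separately via [permutation_test()].
#' @param seed integer seed controlling CV folds and permutations.
#' @param scaling PLS preprocessing (default autoscaling).
#' @return Object of class `screening_result`: per-assay models and
#'   selections, per-group unions, an evidence data frame (VIP, coefficient
#'   and GRD per compound and assay, pass flags) and a model-quality block.
#' @examples
#' d <- generate_dataset(synthetic_config(seed = 3))
#' res <- screen_pipeline(d$peaks, d$acts, seed = 3)
#' res
#' @export
screen_pipeline <- function(peaks, acts, gra_cfg = gra_config(),
                            screen_cfg = screening_config(),
                            max_A = NULL, folds = 7, n_perm = 0, seed = 1,
                            scaling = "autoscale") {
  stopifnot(inherits(peaks, "peak_table"), inherits(acts, "activity_table"))
  if (length(peaks$compound_ids) < 2)
    stop("screen_pipeline: need at least 2 compounds", call. = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  al <- stage("align", align_tables(peaks, acts))
  peaks <- al$peaks; acts <- al$acts
  n <- length(peaks$sample_ids); p <- length(peaks$compound_ids)
  if (n < 3) stop("screen_pipeline: need at least 3 aligned samples", call. = FALSE)
  if (is.null(max_A)) max_A <- max(1, min(5, n - ceiling(n / folds) - 1, p))

  gra <- stage("gra", grey_relational_degree(peaks, acts, gra_cfg))

  assays <- acts$assay_ids
  per_assay <- list()
  for (a in assays) {
    per_assay[[a]] <- stage(paste0("pls:", a), {
      y <- acts$values[, a]
      q2 <- cross_validate_q2(peaks$values, y, max_A = max_A, folds = folds,
                              seed = substream_seed(seed, "cv"), scaling = scaling)
      A <- select_components(q2)
      fit <- fit_pls(peaks$values, y, ncomp = A, scaling = scaling)
      perm <- if (n_perm > 0)
        permutation_test(peaks$values, y, A = A, n_perm = n_perm, seed = seed,
                         folds = folds, scaling = scaling)
      selected <- select_by_assay(fit$vip, fit$coefficients, screen_cfg)
      list(assay = a, fit = fit, q2_profile = q2, A = A,
           r2y_cum = unname(fit$r2y_cum[fit$n_components]),
           q2_cum = unname(q2[A]), permutation = perm, selected = selected)
    })
  }

  groups <- screen_cfg$union_assays
  usable <- vapply(groups, function(g) all(g %in% assays), logical(1))
  if (any(!usable))
    message("screen_pipeline: dropping group(s) without matching assays: ",
            paste(names(groups)[!usable], collapse = ", "))
  groups <- groups[usable]
  sets <- lapply(per_assay, `[[`, "selected")
  cfg_used <- screen_cfg; cfg_used$union_assays <- groups
  unions <- lapply(names(groups), function(g) union_candidates(sets, g, cfg_used))
  names(unions) <- names(groups)

  evidence <- stage("evidence", {
    ev <- data.frame(compound = peaks$compound_ids, stringsAsFactors = FALSE)
    for (a in assays) {
      ev[[paste0("vip_", a)]] <- unname(per_assay[[a]]$fit$vip)
      ev[[paste0("coef_", a)]] <- unname(per_assay[[a]]$fit$coefficients)
      ev[[paste0("selected_", a)]] <- ev$compound %in% per_assay[[a]]$selected
      ev[[paste0("grd_", a)]] <- gra$grd[ev$compound, a]
    }
    ev$below_grd_floor <- apply(gra$grd[ev$compound, , drop = FALSE] <
                                  screen_cfg$grd_floor, 1, any)
    rownames(ev) <- NULL
    ev
  })

  structure(list(per_assay = per_assay, groups = unions, gra = gra,
                 evidence = evidence, config = screen_cfg, gra_config = gra_cfg,
                 seed = seed, n_samples = n, n_compounds = p),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("Spectrum-effect screening: %d samples x %d compounds, %d assay(s)\n",
              x$n_samples, x$n_compounds, length(x$per_assay)))
  for (a in names(x$per_assay)) {
    pa <- x$per_assay[[a]]
    cat(sprintf("  %s: A = %d, R2Y = %.3f, Q2 = %.3f, selected {%s}\n",
                a, pa$A, pa$r2y_cum, pa$q2_cum,
                paste(pa$selected, collapse = ",")))
  }
  for (g in names(x$groups))
    cat(sprintf("  group %s: union {%s}\n", g, paste(x$groups[[g]], collapse = ",")))
  invisible(x)
}

#' @export
summary.screening_result <- function(object, ...) {
  object$evidence
}
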