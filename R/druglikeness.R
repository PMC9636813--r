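#' Default drug-likeness rule thresholds
#'
#' One editable table of the five published rule sets used to judge oral
#' drug-likeness, transcribed from the original publications:
#'
#' * Lipinski (Adv. Drug Deliv. Rev. 1997/2001, "rule of five"): MW <= 500,
#'   H-bond donors <= 5, H-bond acceptors <= 10, MLOGP <= 4.15; a single
#'   violation is tolerated.
#' * Ghose (J. Comb. Chem. 1999): 160 <= MW <= 480, -0.4 <= WLOGP <= 5.6,
#'   40 <= molar refractivity <= 130, 20 <= heavy atoms <= 70.
#' * Veber (J. Med. Chem. 2002): rotatable bonds <= 10 and TPSA <= 140.
#' * Egan (J. Med. Chem. 2000): WLOGP <= 5.88 and TPSA <= 131.6.
#' * Muegge (J. Med. Chem. 2001): 200 <= MW <= 600, -2 <= XLOGP <= 5,
#'   TPSA <= 150, rings <= 7, carbons > 4, heteroatoms > 1, rotatable
#'   bonds <= 15, HBA <= 10, HBD <= 5.
#'
#' The rule engine never computes descriptors; they arrive from a
#' user-supplied CSV (see [read_descriptors()]), keeping the module testable
#' with hand-written records. Distinct logP estimators feed different rules
#' (Moriguchi for Lipinski, Wildman-Crippen for Ghose/Egan, XLOGP for
#' Muegge); the descriptor source should record which estimator filled each
#' field.
#'
#' @return A nested list, one element per rule, giving each condition as
#'   `list(field, min, max)` plus `max_violations`.
#' @export
rule_thresholds <- function() {
  cond <- function(field, min = -Inf, max = Inf) list(field = field, min = min, max = max)
  list(
    lipinski = list(max_violations = 1, conditions = list(
      cond("mw", max = 500), cond("hbd", max = 5), cond("hba", max = 10),
      cond("logp_mlogp", max = 4.15))),
    ghose = list(max_violations = 0, conditions = list(
      cond("mw", 160, 480), cond("logp_wlogp", -0.4, 5.6),
      cond("molar_refractivity", 40, 130), cond("heavy_atoms", 20, 70))),
    veber = list(max_violations = 0, conditions = list(
      cond("rotatable_bonds", max = 10), cond("tpsa", max = 140))),
    egan = list(max_violations = 0, conditions = list(
      cond("logp_wlogp", max = 5.88), cond("tpsa", max = 131.6))),
    muegge = list(max_violations = 0, conditions = list(
      cond("mw", 200, 600), cond("logp_xlogp", -2, 5), cond("tpsa", max = 150),
      cond("rings", max = 7), cond("carbons", min = 5),  # "> 4" on an integer count
      cond("heteroatoms", min = 2), cond("rotatable_bonds", max = 15),
      cond("hba", max = 10), cond("hbd", max = 5)))
  )
}

#' Evaluate the five drug-likeness rules for one descriptor record
#'
#' A rule passes when its violations do not exceed its tolerance (only
#' Lipinski tolerates one). A rule whose required descriptors are missing
#' (`NA` or absent) is reported `evaluable = FALSE` with a warning and is
#' excluded from the pass count denominator.
#'
#' @param d a named list or one-row data frame of descriptors (fields as in
#'   [rule_thresholds()]).
#' @param thresholds rule table (default [rule_thresholds()]).
#' @return Named list per rule: `pass`, `evaluable`, `violations`
#'   (character descriptions naming the failing descriptor and bound).
#' @export
evaluate_rules <- function(d, thresholds = rule_thresholds()) {
  d <- as.list(d)
  out <- list()
  for (rule in names(thresholds)) {
    spec <- thresholds[[rule]]
    fields <- vapply(spec$conditions, `[[`, character(1), "field")
    have <- vapply(fields, function(f) !is.null(d[[f]]) && !is.na(d[[f]]), logical(1))
    if (!all(have)) {
      warning(sprintf("rule '%s' not evaluable: missing descriptor(s) %s",
                      rule, paste(fields[!have], collapse = ", ")))
      out[[rule]] <- list(pass = NA, evaluable = FALSE, violations = character(0))
      next
    }
    viol <- character(0)
    for (cn in spec$conditions) {
      v <- as.numeric(d[[cn$field]])
      if (v > cn$max) viol <- c(viol, sprintf("%s > %g", cn$field, cn$max))
      if (v < cn$min) viol <- c(viol, sprintf("%s < %g", cn$field, cn$min))
    }
    out[[rule]] <- list(pass = length(viol) <= spec$max_violations,
                        evaluable = TRUE, violations = viol)
  }
  out
}

#' Default gastrointestinal-absorption ellipse
#'
#' The published high-GI-absorption region in the (TPSA, WLOGP) plane used
#' by the "boiled-egg" bioavailability model: a rotated ellipse enclosing
#' the well-absorbed chemical space (TPSA roughly 0-142 A^2, WLOGP roughly
#' -2.4 to 7). Parameters are configuration, not code constants; replace
#' them to recalibrate the classifier.
#'
#' @return List with `center` (tpsa, wlogp), semi-axes `a` (TPSA direction)
#'   and `b` (WLOGP direction) and rotation `theta` (radians).
#' @export
ga_ellipse <- function() {
  list(center = c(tpsa = 71.051, wlogp = 2.292),
       a = 71.304, b = 4.702, theta = -0.00545)
}

#' Classify gastrointestinal absorption from TPSA and WLOGP
#'
#' Point-in-rotated-ellipse test: `"high"` when the compound lies inside or
#' on the configured ellipse (the region is closed: boundary points are
#' `"high"`), else `"low"`.
#'
#' @param tpsa topological polar surface area (A^2).
#' @param wlogp Wildman-Crippen logP.
#' @param ellipse parameters as from [ga_ellipse()].
#' @return `"high"` or `"low"` (vectorized).
#' @export
classify_ga <- function(tpsa, wlogp, ellipse = ga_ellipse()) {
  if (!is.finite(ellipse$a) || !is.finite(ellipse$b) ||
      ellipse$a <= 0 || ellipse$b <= 0)
    stop("classify_ga: degenerate ellipse axes", call. = FALSE)
  if (any(!is.finite(tpsa)) || any(!is.finite(wlogp)))
    stop("classify_ga: tpsa and wlogp must be finite", call. = FALSE)
  dx <- tpsa - ellipse$center[["tpsa"]]
  dy <- wlogp - ellipse$center[["wlogp"]]
  u <- dx * cos(ellipse$theta) + dy * sin(ellipse$theta)
  v <- -dx * sin(ellipse$theta) + dy * cos(ellipse$theta)
  ifelse((u / ellipse$a)^2 + (v / ellipse$b)^2 <= 1 + 1e-12, "high", "low")
}

#' Admission configuration for quality markers
#'
#' @param min_rules_passed minimum number of passing drug-likeness rule sets
#'   (default 3, reading "over two" strictly).
#' @param content_override_fold content ratio (compound vs the median of the
#'   others) above which a compound is admitted regardless of its ADME
#'   profile (default 20) — the high-content exception under which an
#'   abundant constituent is detectable in vivo despite low predicted
#'   absorption.
#' @param ellipse GI-absorption ellipse (default [ga_ellipse()]).
#' @return List of class `admission_config`.
#' @export
admission_config <- function(min_rules_passed = 3, content_override_fold = 20,
                             ellipse = ga_ellipse()) {
  if (content_override_fold <= 1)
    stop("admission_config: content_override_fold must be > 1", call. = FALSE)
  structure(list(min_rules_passed = min_rules_passed,
                 content_override_fold = content_override_fold,
                 ellipse = ellipse),
            class = "admission_config")
}

#' Apply the marker-admission rule to one compound
#'
#' A compound is admissible as a quality marker when its predicted
#' gastrointestinal absorption is `"high"` and at least `min_rules_passed`
#' drug-likeness rule sets pass, or — regardless of either — when its
#' relative content exceeds `content_override_fold` times the median content
#' of the other constituents (`override_applied` is then set).
#'
#' @param rules result of [evaluate_rules()].
#' @param ga_class `"high"` or `"low"`, e.g. from [classify_ga()].
#' @param relative_content the compound's content (any non-negative unit,
#'   consistent with `others_median_content`).
#' @param others_median_content median content of the other constituents,
#'   `> 0` when the override is to be tested.
#' @param config an [admission_config()].
#' @return Object of class `druglikeness_report`: per-rule verdicts,
#'   `rules_passed`, `rules_evaluable`, `ga_class`, `admissible`,
#'   `override_applied`.
#' @export
admit_marker <- function(rules, ga_class, relative_content = 0,
                         others_median_content = 1,
                         config = admission_config()) {
  if (relative_content < 0 || others_median_content <= 0)
    stop("admit_marker: contents must be non-negative (others' median > 0)",
         call. = FALSE)
  if (!ga_class %in% c("high", "low"))
    stop("admit_marker: ga_class must be 'high' or 'low'", call. = FALSE)
  evaluable <- vapply(rules, `[[`, logical(1), "evaluable")
  passed <- vapply(rules[evaluable], function(r) isTRUE(r$pass), logical(1))
  n_pass <- sum(passed)
  ratio <- relative_content / others_median_content
  override <- ratio > config$content_override_fold
  adme_ok <- ga_class == "high" && n_pass >= config$min_rules_passed
  structure(list(rules = rules, rules_passed = n_pass,
                 rules_evaluable = sum(evaluable), ga_class = ga_class,
                 content_ratio = ratio, admissible = adme_ok || override,
                 override_applied = override && !adme_ok),
            class = "druglikeness_report")
}

#' @export
print.druglikeness_report <- function(x, ...) {
  verdicts <- vapply(x$rules, function(r)
    if (!r$evaluable) "n/a" else if (r$pass) "yes" else "no", character(1))
  cat(sprintf("Drug-likeness: %s (GA %s, %d/%d rules pass)\n",
              paste(sprintf("%s=%s", names(verdicts), verdicts), collapse = " "),
              x$ga_class, x$rules_passed, x$rules_evaluable))
  cat(sprintf("  admissible: %s%s\n", x$admissible,
              if (x$override_applied) " (high-content override)" else ""))
  invisible(x)
}

#' Read a compound descriptor table from CSV
#'
#' Expects a `compound_id` column plus the descriptor fields used by
#' [rule_thresholds()] and [classify_ga()] (`mw`, `logp_mlogp`,
#' `logp_wlogp`, `logp_xlogp`, `tpsa`, `hbd`, `hba`, `rotatable_bonds`,
#' `molar_refractivity`, `heavy_atoms`, `rings`, `carbons`, `heteroatoms`).
#'
#' @param path CSV path.
#' @return Data frame with `compound_id` as character.
#' @export
read_descriptors <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"compound_id" %in% names(df))
    stop("read_descriptors: need a 'compound_id' column", call. = FALSE)
  df$compound_id <- as.character(df$compound_id)
  df
}

#' Drug-likeness and admission report for a descriptor table
#'
#' Runs [evaluate_rules()], [classify_ga()] and [admit_marker()] for every
#' compound in a descriptor data frame.
#'
#' @param descriptors data frame as from [read_descriptors()].
#' @param contents optional named numeric vector (compound_id -> relative
#'   content) for the high-content override; compounds without a content
#'   get ratio 0.
#' @param config an [admission_config()].
#' @param thresholds rule table (default [rule_thresholds()]).
#' @return Data frame: one row per compound with per-rule verdicts,
#'   `rules_passed`, `ga_class`, `content_ratio`, `admissible`,
#'   `override_applied`.
#' @examples
#' desc <- load_fixture("marker_descriptors")
#' cont <- load_fixture("marker_contents_synthetic")
#' druglikeness_report(desc, stats::setNames(cont$relative_content, cont$compound_id))
#' @export
druglikeness_report <- function(descriptors, contents = NULL,
                                config = admission_config(),
                                thresholds = rule_thresholds()) {
  rows <- lapply(seq_len(nrow(descriptors)), function(i) {
    d <- descriptors[i, ]
    id <- d$compound_id
    rules <- evaluate_rules(d, thresholds)
    ga <- classify_ga(d$tpsa, d$logp_wlogp, config$ellipse)
    content <- if (!is.null(contents) && id %in% names(contents)) contents[[id]] else 0
    others <- if (!is.null(contents)) contents[setdiff(names(contents), id)] else numeric(0)
    om <- if (length(others) > 0) stats::median(others) else 1
    rep_i <- admit_marker(rules, ga, content, om, config)
    verdict <- vapply(rules, function(r)
      if (!r$evaluable) NA else isTRUE(r$pass), logical(1))
    c(list(compound_id = id), as.list(stats::setNames(verdict, names(rules))),
      list(rules_passed = rep_i$rules_passed, ga_class = rep_i$ga_class,
           content_ratio = rep_i$content_ratio, admissible = rep_i$admissible,
           override_applied = rep_i$override_applied))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}
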