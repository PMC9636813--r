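#' Construct a peak-area table
#'
#' A `peak_table` holds a samples x compounds matrix of chromatographic peak
#' areas (arbitrary units, non-negative) together with sample and compound
#' identifiers and optional per-compound annotations. It is the predictor (X)
#' block of every downstream stage: grey relational analysis, PLS regression
#' and candidate screening.
#'
#' Compound identifiers are opaque strings; numeric peak numbers are stored as
#' strings (`"1"`, `"2"`, ...) to avoid type drift between files and code.
#' Missing cells are never imputed: any `NA` or negative value is a hard
#' validation error naming the offending row and column.
#'
#' @param values numeric matrix, samples in rows, compounds in columns.
#' @param sample_ids character vector of unique sample identifiers
#'   (default: rownames of `values`).
#' @param compound_ids character vector of unique compound identifiers
#'   (default: colnames of `values`).
#' @param compound_meta optional data frame with one row per compound
#'   (columns such as `name`, `class`, `smiles`).
#' @return An object of class `peak_table`: a list with elements
#'   `sample_ids`, `compound_ids`, `values` (dimnamed matrix) and
#'   `compound_meta`.
#' @examples
#' pt <- peak_table(matrix(1:6, 3, 2), paste0("s", 1:3), c("1", "2"))
#' pt
#' @export
peak_table <- function(values, sample_ids = rownames(values),
                       compound_ids = colnames(values), compound_meta = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  sample_ids <- as.character(sample_ids)
  compound_ids <- as.character(compound_ids)
  check_table_ids(sample_ids, compound_ids, values, "compound")
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "peak_table: invalid value (missing, non-finite or negative) at sample '%s', compound '%s'",
      sample_ids[bad[1, 1]], compound_ids[bad[1, 2]]), call. = FALSE)
  }
  if (!is.null(compound_meta)) {
    compound_meta <- as.data.frame(compound_meta)
    if (nrow(compound_meta) != length(compound_ids))
      stop("peak_table: compound_meta must have one row per compound", call. = FALSE)
  }
  dimnames(values) <- list(sample_ids, compound_ids)
  structure(list(sample_ids = sample_ids, compound_ids = compound_ids,
                 values = values, compound_meta = compound_meta),
            class = "peak_table")
}

#' Construct a bioactivity table
#'
#' An `activity_table` holds a samples x assays matrix of bioassay readouts
#' (assay-specific units, e.g. DPPH scavenging %, FRAP umol Fe(II)/g,
#' NO-inhibition %). It is the response (Y) block / grey-relational reference
#' series. Values may be negative (e.g. pro-oxidant readouts) but never
#' missing.
#'
#' @param values numeric matrix, samples in rows, assays in columns.
#' @param sample_ids character vector of unique sample identifiers.
#' @param assay_ids character vector of unique assay identifiers.
#' @return An object of class `activity_table`.
#' @export
activity_table <- function(values, sample_ids = rownames(values),
                           assay_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  sample_ids <- as.character(sample_ids)
  assay_ids <- as.character(assay_ids)
  check_table_ids(sample_ids, assay_ids, values, "assay")
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("activity_table: missing or non-finite value at sample '%s', assay '%s'",
                 sample_ids[bad[1, 1]], assay_ids[bad[1, 2]]), call. = FALSE)
  }
  dimnames(values) <- list(sample_ids, assay_ids)
  structure(list(sample_ids = sample_ids, assay_ids = assay_ids, values = values),
            class = "activity_table")
}

check_table_ids <- function(sample_ids, col_ids, values, col_what) {
  if (length(sample_ids) == 0 || anyNA(sample_ids) || any(sample_ids == ""))
    stop("missing sample id", call. = FALSE)
  if (length(col_ids) == 0 || anyNA(col_ids) || any(col_ids == ""))
    stop(sprintf("missing %s id", col_what), call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop(sprintf("duplicated sample id: '%s'", sample_ids[duplicated(sample_ids)][1]),
         call. = FALSE)
  if (anyDuplicated(col_ids))
    stop(sprintf("duplicated %s id: '%s'", col_what, col_ids[duplicated(col_ids)][1]),
         call. = FALSE)
  if (nrow(values) != length(sample_ids) || ncol(values) != length(col_ids))
    stop("matrix dimensions do not match id lists", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("peak_table: %d samples x %d compounds\n",
              length(x$sample_ids), length(x$compound_ids)))
  if (!is.null(x$compound_meta) && "class" %in% names(x$compound_meta)) {
    tab <- table(x$compound_meta$class)
    cat("  compound classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.activity_table <- function(x, ...) {
  cat(sprintf("activity_table: %d samples x %d assays (%s)\n",
              length(x$sample_ids), length(x$assay_ids),
              paste(x$assay_ids, collapse = ", ")))
  invisible(x)
}

#' Read a peak-area table from CSV
#'
#' Expects a comma-separated UTF-8 file with one header row of compound ids
#' and a first column of sample ids; the body must be numeric and
#' non-negative.
#'
#' @param path path to a CSV file.
#' @return A validated [peak_table]; row/column ordering is preserved from
#'   the file.
#' @export
read_peak_table <- function(path) {
  df <- read_id_matrix_csv(path, "compound")
  peak_table(df$values, df$row_ids, df$col_ids)
}

#' Read a bioactivity table from CSV
#'
#' Same layout as [read_peak_table()]: header row of assay ids, first column
#' of sample ids, numeric body (negative values allowed).
#'
#' @param path path to a CSV file.
#' @return A validated [activity_table].
#' @export
read_activity_table <- function(path) {
  df <- read_id_matrix_csv(path, "assay")
  activity_table(df$values, df$row_ids, df$col_ids)
}

read_id_matrix_csv <- function(path, col_what) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) stop(sprintf("'%s': need an id column plus data columns", path), call. = FALSE)
  row_ids <- raw[[1]]
  col_ids <- colnames(raw)[-1]
  if (anyDuplicated(col_ids))
    stop(sprintf("'%s': duplicated %s id in header: '%s'", path, col_what,
                 col_ids[duplicated(col_ids)][1]), call. = FALSE)
  if (anyDuplicated(row_ids))
    stop(sprintf("'%s': duplicated sample id: '%s'", path,
                 row_ids[duplicated(row_ids)][1]), call. = FALSE)
  body <- raw[, -1, drop = FALSE]
  values <- matrix(NA_real_, nrow(body), ncol(body))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    nonnum <- which(is.na(v) & !is.na(body[[j]]))
    if (length(nonnum) > 0)
      stop(sprintf("'%s': non-numeric cell at sample '%s', column '%s'",
                   path, row_ids[nonnum[1]], col_ids[j]), call. = FALSE)
    values[, j] <- v
  }
  list(row_ids = row_ids, col_ids = col_ids, values = values)
}

#' Write a peak or activity table to CSV
#'
#' Values are written with full decimal precision so that a write/read
#' round trip is bit-exact.
#'
#' @param x a [peak_table] or [activity_table].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  stopifnot(inherits(x, c("peak_table", "activity_table")))
  df <- data.frame(sample = x$sample_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  vals <- x$values
  for (j in seq_len(ncol(vals))) {
    df[[colnames(vals)[j]]] <- format(vals[, j], digits = 17, trim = TRUE,
                                      scientific = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align a peak table and an activity table on shared samples
#'
#' Restricts both tables to the intersection of their sample ids, in the
#' order the ids appear in the peak table, and reports dropped samples with a
#' message. Alignment is by identifier, never by row order, and is
#' idempotent.
#'
#' @param peaks a [peak_table].
#' @param acts an [activity_table].
#' @return A list with elements `peaks` and `acts`, row-matched.
#' @export
align_tables <- function(peaks, acts) {
  stopifnot(inherits(peaks, "peak_table"), inherits(acts, "activity_table"))
  shared <- intersect(peaks$sample_ids, acts$sample_ids)
  if (length(shared) == 0)
    stop("align_tables: no shared sample ids between the two tables", call. = FALSE)
  dropped <- setdiff(union(peaks$sample_ids, acts$sample_ids), shared)
  if (length(dropped) > 0)
    message("align_tables: dropping ", length(dropped), " sample(s): ",
            paste(dropped, collapse = ", "))
  p <- peak_table(peaks$values[shared, , drop = FALSE], shared,
                  peaks$compound_ids, peaks$compound_meta)
  a <- activity_table(acts$values[shared, , drop = FALSE], shared, acts$assay_ids)
  list(peaks = p, acts = a)
}

#' Load a bundled worked-example fixture
#'
#' The package ships, as plain CSV, the printed worked-example tables of the
#' dandelion study this pipeline reproduces: the grey relational degrees of
#' the 22 phenolic peaks against three assays (`table2_grd`), and the
#' VIP/coefficient rows of the antioxidant (`table3_antioxidant`) and
#' anti-inflammatory (`table4_antiinflammatory`) PLS models. These drive the
#' screening-rule worked examples and rank-logic tests.
#'
#' @param name one of `"table2_grd"`, `"table3_antioxidant"`,
#'   `"table4_antiinflammatory"`, `"marker_descriptors"`,
#'   `"marker_contents_synthetic"`.
#' @return A data frame with the table's columns; peak ids as character.
#' @examples
#' head(load_fixture("table2_grd"))
#' @export
load_fixture <- function(name) {
  known <- c("table2_grd", "table3_antioxidant", "table4_antiinflammatory",
             "marker_descriptors", "marker_contents_synthetic")
  if (!name %in% known)
    stop(sprintf("unknown fixture '%s'; available: %s", name,
                 paste(known, collapse = ", ")), call. = FALSE)
  path <- system.file("extdata", paste0(name, ".csv"), package = "qmarker",
                      mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  id_col <- intersect(c("peak", "compound_id"), names(df))
  for (ic in id_col) df[[ic]] <- as.character(df[[ic]])
  df
}
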