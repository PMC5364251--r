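# Domain types shared by all coding builders: factor specifications,
# two-way cell tables, and observation-level datasets.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Specify a categorical predictor
#'
#' A factor specification records the ordered level labels of a categorical
#' variable, the number of observations per level, and which level is the
#' omitted (reference) category whose indicator column is dropped for
#' identifiability.
#'
#' Levels are ordered by first appearance in `values` unless `levels` is
#' given. With `omitted = "auto"` the most frequent level becomes the
#' reference: weighted-effect completion of the omitted-level coefficient
#' divides by the reference count, so the largest category gives the most
#' stable completed estimate. Ties break to the earliest level.
#'
#' @param values Character vector of observed level labels. May be omitted
#'   when `counts` is supplied directly (grouped workflows that only know
#'   the cell table).
#' @param name Label for the factor, used in column names (`"<name>=<level>"`).
#' @param omitted Level label to use as the reference category, or `"auto"`.
#' @param levels Optional explicit level ordering; must cover all observed
#'   values.
#' @param counts Optional named vector of per-level counts, instead of
#'   `values`.
#' @return An object of class `factor_spec` with fields `name`, `levels`,
#'   `counts` (named, in level order) and `omitted`.
#' @examples
#' factor_spec(c("a", "a", "b", "b"), name = "grp", omitted = "a")
#' factor_spec(name = "kids", counts = c(with = 2254, childless = 1060),
#'             omitted = "with")
#' @export
factor_spec <- function(values = NULL, name = "factor", omitted = "auto",
                        levels = NULL, counts = NULL) {
  if (is.null(values) && is.null(counts))
    stopf("factor '%s': supply either values or counts", name)
  if (!is.null(values)) {
    values <- as.character(values)
    if (anyNA(values)) stopf("factor '%s': values contain missing entries", name)
    if (is.null(levels)) levels <- unique(values)
    if (!all(values %in% levels))
      stopf("factor '%s': values outside declared levels: %s", name,
            paste(setdiff(unique(values), levels), collapse = ", "))
    counts <- vapply(levels, function(l) sum(values == l), numeric(1))
  } else {
    if (is.null(names(counts)) || anyNA(names(counts)))
      stopf("factor '%s': counts must be named by level", name)
    if (is.null(levels)) levels <- names(counts)
    counts <- counts[levels]
  }
  counts <- stats::setNames(as.numeric(counts), levels)
  if (length(levels) < 2L)
    stopf("degenerate factor '%s': needs at least 2 levels, got %d",
          name, length(levels))
  if (any(counts < 1))
    stopf("factor '%s': every level needs at least one observation (%s)",
          name, paste(levels[counts < 1], collapse = ", "))
  if (identical(omitted, "auto")) {
    omitted <- levels[which.max(counts)]
  } else if (!omitted %in% levels) {
    stopf("factor '%s': omitted level '%s' not among levels %s",
          name, omitted, paste(levels, collapse = ", "))
  }
  structure(list(name = name, levels = levels, counts = counts,
                 omitted = omitted),
            class = "factor_spec")
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("Factor '%s' (%d levels, n = %d, reference = '%s')\n",
              x$name, length(x$levels), sum(x$counts), x$omitted))
  print(x$counts)
  invisible(x)
}

# Replace the omitted level, keeping everything else; used by the
# refit-based completion of reference-category coefficients.
set_omitted <- function(spec, omitted) {
  stopifnot(inherits(spec, "factor_spec"))
  if (!omitted %in% spec$levels)
    stopf("factor '%s': omitted level '%s' not among levels",
          spec$name, omitted)
  spec$omitted <- omitted
  spec
}

#' Two-way cell table of counts and outcome means
#'
#' The K x L cross-classification of two factors, holding per-cell counts
#' and (optionally) per-cell outcome means. Counts and means together are
#' sufficient statistics for any linear model whose predictors are constant
#' within cells, which is why [fit_ols_grouped()] can work from this table
#' alone.
#'
#' @param factor_a,factor_b [factor_spec] objects for the row and column
#'   factors.
#' @param counts K x L numeric matrix of cell counts; `dimnames` must match
#'   the factor levels. Row sums must equal `factor_a$counts` and column
#'   sums `factor_b$counts`.
#' @param means Optional K x L matrix of per-cell outcome means, same
#'   dimnames.
#' @return An object of class `cell_table`.
#' @export
cell_table <- function(factor_a, factor_b, counts, means = NULL) {
  stopifnot(inherits(factor_a, "factor_spec"), inherits(factor_b, "factor_spec"))
  counts <- as.matrix(counts)
  if (is.null(dimnames(counts)))
    dimnames(counts) <- list(factor_a$levels, factor_b$levels)
  if (!identical(rownames(counts), factor_a$levels) ||
      !identical(colnames(counts), factor_b$levels))
    stopf("cell table dimnames must match factor levels")
  if (any(counts < 0)) stopf("cell counts must be nonnegative")
  if (any(abs(rowSums(counts) - factor_a$counts) > 1e-8))
    stopf("cell count row sums do not match counts of factor '%s'",
          factor_a$name)
  if (any(abs(colSums(counts) - factor_b$counts) > 1e-8))
    stopf("cell count column sums do not match counts of factor '%s'",
          factor_b$name)
  if (!is.null(means)) {
    means <- as.matrix(means)
    if (is.null(dimnames(means))) dimnames(means) <- dimnames(counts)
    if (!identical(dim(means), dim(counts)))
      stopf("cell means must have the same shape as cell counts")
  }
  structure(list(factor_a = factor_a, factor_b = factor_b,
                 counts = counts, means = means),
            class = "cell_table")
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("Cell table: %s (%d) x %s (%d), n = %d\n",
              x$factor_a$name, length(x$factor_a$levels),
              x$factor_b$name, length(x$factor_b$levels),
              sum(x$counts)))
  cat("Counts:\n"); print(x$counts)
  if (!is.null(x$means)) { cat("Outcome means:\n"); print(round(x$means, 4)) }
  invisible(x)
}

#' Cross-tabulate a dataset against two factor specifications
#'
#' Builds the [cell_table] of a dataset: per-cell counts and, when an
#' outcome column is named, per-cell outcome means. Marginal counts are
#' checked against each factor specification and a mismatch is an error,
#' so the table is always consistent with the specs it carries.
#'
#' @param data A data frame with one column per factor (named after the
#'   factor specs) and optionally the outcome.
#' @param factor_a,factor_b [factor_spec] objects; `data[[factor_a$name]]`
#'   etc. must exist.
#' @param outcome Optional name of a numeric outcome column; enables cell
#'   means.
#' @return A [cell_table].
#' @export
cross_tabulate <- function(data, factor_a, factor_b, outcome = NULL) {
  va <- dataset_column(data, factor_a)
  vb <- dataset_column(data, factor_b)
  if (length(va) != length(vb)) stopf("factor columns differ in length")
  la <- factor(va, levels = factor_a$levels)
  lb <- factor(vb, levels = factor_b$levels)
  counts <- table(la, lb)
  counts <- matrix(as.numeric(counts), nrow = length(factor_a$levels),
                   dimnames = list(factor_a$levels, factor_b$levels))
  means <- NULL
  if (!is.null(outcome)) {
    y <- data[[outcome]]
    if (is.null(y)) stopf("outcome column '%s' not found", outcome)
    sums <- tapply(as.numeric(y), list(la, lb), sum)
    sums[is.na(sums)] <- 0
    means <- sums / ifelse(counts > 0, counts, NA_real_)
  }
  cell_table(factor_a, factor_b, counts, means)
}

# Pull a factor's column out of a data frame and validate its labels.
dataset_column <- function(data, spec) {
  v <- data[[spec$name]]
  if (is.null(v)) stopf("column '%s' not found in dataset", spec$name)
  v <- as.character(v)
  bad <- setdiff(unique(v), spec$levels)
  if (length(bad))
    stopf("factor '%s': undeclared level(s) %s", spec$name,
          paste(bad, collapse = ", "))
  v
}

#' Drop rows with missing outcome, factor, or control values
#'
#' Listwise deletion over the named columns, with a message reporting how
#' many rows were dropped (a silent drop hides data problems).
#'
#' @param data A data frame.
#' @param columns Character vector of columns that must be complete.
#' @return The data frame restricted to complete rows.
#' @export
drop_incomplete <- function(data, columns) {
  missing_cols <- setdiff(columns, names(data))
  if (length(missing_cols))
    stopf("columns not found: %s", paste(missing_cols, collapse = ", "))
  keep <- stats::complete.cases(data[columns])
  dropped <- sum(!keep)
  if (dropped > 0)
    message(sprintf("dropping %d row(s) with missing values in %s",
                    dropped, paste(columns, collapse = ", ")))
  data[keep, , drop = FALSE]
}

#' Read and write observation-level datasets
#'
#' Datasets are plain comma-separated text with a header row (UTF-8).
#' Factor columns stay character; nothing is converted to R factors so
#' level handling remains explicit via [factor_spec()].
#'
#' @param path File path.
#' @param data A data frame (for `write_dataset`).
#' @return `read_dataset` returns a data frame.
#' @export
read_dataset <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  encoding = "UTF-8")
}

#' @rdname read_dataset
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- JSON serialization of the domain types -------------------------------

#' Serialize factor specifications and cell tables to JSON
#'
#' Round-trip-lossless JSON representations, used for fixtures and audit
#' trails. Matrices are stored with explicit row/column level labels so the
#' files stay readable and order-stable.
#'
#' @param x A [factor_spec] or [cell_table].
#' @param path File path.
#' @return The reading functions return the reconstructed object.
#' @export
write_factor_spec <- function(x, path) {
  stopifnot(inherits(x, "factor_spec"))
  obj <- list(name = x$name, levels = x$levels,
              counts = as.list(x$counts), omitted = x$omitted)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_factor_spec
#' @export
read_factor_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  factor_spec(name = obj$name, levels = obj$levels,
              counts = unlist(obj$counts), omitted = obj$omitted)
}

#' @rdname write_factor_spec
#' @export
write_cell_table <- function(x, path) {
  stopifnot(inherits(x, "cell_table"))
  obj <- list(
    factor_a = list(name = x$factor_a$name, levels = x$factor_a$levels,
                    counts = as.list(x$factor_a$counts),
                    omitted = x$factor_a$omitted),
    factor_b = list(name = x$factor_b$name, levels = x$factor_b$levels,
                    counts = as.list(x$factor_b$counts),
                    omitted = x$factor_b$omitted),
    counts = as.data.frame(x$counts),
    means = if (!is.null(x$means)) as.data.frame(x$means))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_factor_spec
#' @export
read_cell_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fa <- factor_spec(name = obj$factor_a$name, levels = obj$factor_a$levels,
                    counts = unlist(obj$factor_a$counts),
                    omitted = obj$factor_a$omitted)
  fb <- factor_spec(name = obj$factor_b$name, levels = obj$factor_b$levels,
                    counts = unlist(obj$factor_b$counts),
                    omitted = obj$factor_b$omitted)
  counts <- as.matrix(obj$counts)
  rownames(counts) <- fa$levels
  means <- NULL
  if (!is.null(obj$means)) {
    means <- as.matrix(obj$means)
    rownames(means) <- fa$levels
  }
  cell_table(fa, fb, counts, means)
}
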