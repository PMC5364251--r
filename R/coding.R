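# Coding builders: per-observation design columns for dummy, effect, and
# weighted effect coding, main effects and two-factor interactions.
#
# Weighted effect coding makes coefficients deviations from the
# count-weighted sample mean; its interaction columns follow a four-cell
# pattern (NOT a product of main columns) chosen so every interaction
# column is exactly orthogonal to the intercept and to all main-effect
# columns of both factors. Adding the interaction block therefore leaves
# the main effects of the additive model untouched.

SCHEMES <- c("dummy", "effect", "wec")

check_scheme <- function(scheme) {
  scheme <- match.arg(scheme, SCHEMES)
  scheme
}

# label helpers; interaction labels use the multiplication sign
main_label <- function(spec, level) sprintf("%s=%s", spec$name, level)
int_label <- function(la, lb) sprintf("%s\u00d7%s", la, lb)

# Symbolic per-level codes for one factor: a K x (K-1) matrix, rows =
# levels, columns = non-omitted levels. This is the "coding scheme" a user
# can audit; per-observation columns are just a row lookup into it.
main_cell_codes <- function(spec, scheme, counts = NULL) {
  scheme <- check_scheme(scheme)
  if (is.null(counts)) counts <- spec$counts
  counts <- counts[spec$levels]
  keep <- setdiff(spec$levels, spec$omitted)
  codes <- matrix(0, nrow = length(spec$levels), ncol = length(keep),
                  dimnames = list(spec$levels,
                                  vapply(keep, function(l) main_label(spec, l),
                                         character(1))))
  for (j in seq_along(keep)) {
    k <- keep[j]
    codes[k, j] <- 1
    codes[spec$omitted, j] <- switch(scheme,
      dummy  = 0,
      effect = -1,
      wec    = {
        if (any(is.na(counts)) || counts[spec$omitted] < 1 || counts[k] < 1)
          stopf("weighted effect coding for factor '%s' needs positive counts",
                spec$name)
        -counts[[k]] / counts[[spec$omitted]]
      })
  }
  codes
}

# Symbolic interaction codes: a (K*L) x ((K-1)(L-1)) matrix, rows = cells
# in row-major (levelA, levelB) order. For dummy and effect coding the
# entries are products of the main codes; for weighted effect coding the
# column for pair (k, l) carries the four-cell pattern
#   +1 at (k, l), -n_kl/n_{k,rB} at (k, rB),
#   -n_kl/n_{rA,l} at (rA, l), +n_kl/n_{rA,rB} at (rA, rB),
# and 0 elsewhere, where rA, rB are the omitted levels.
interaction_cell_codes <- function(table, scheme, cell_counts = NULL) {
  scheme <- check_scheme(scheme)
  fa <- table$factor_a; fb <- table$factor_b
  if (is.null(cell_counts)) cell_counts <- table$counts
  keep_a <- setdiff(fa$levels, fa$omitted)
  keep_b <- setdiff(fb$levels, fb$omitted)
  cells <- expand.grid(a = fa$levels, b = fb$levels,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- cells[order(match(cells$a, fa$levels), match(cells$b, fb$levels)), ]
  cell_key <- paste(cells$a, cells$b, sep = "\r")
  labels <- as.vector(outer(keep_a, keep_b, int_label))
  codes <- matrix(0, nrow = nrow(cells), ncol = length(labels),
                  dimnames = list(cell_key, labels))
  if (scheme %in% c("dummy", "effect")) {
    ca <- main_cell_codes(fa, scheme)
    cb <- main_cell_codes(fb, scheme)
    j <- 0L
    for (lb in keep_b) for (la in keep_a) {
      j <- j + 1L
      codes[, j] <- ca[cells$a, main_label(fa, la)] *
        cb[cells$b, main_label(fb, lb)]
    }
  } else {
    rA <- fa$omitted; rB <- fb$omitted
    n_of <- function(a, b) cell_counts[a, b]
    j <- 0L
    for (lb in keep_b) for (la in keep_a) {
      j <- j + 1L
      needed <- rbind(c(la, lb), c(la, rB), c(rA, lb), c(rA, rB))
      nn <- apply(needed, 1L, function(z) n_of(z[1], z[2]))
      if (any(nn < 1))
        stopf("weighted effect interaction '%s' needs a positive count in cell (%s, %s)",
              int_label(la, lb),
              needed[which(nn < 1)[1], 1], needed[which(nn < 1)[1], 2])
      n_kl <- n_of(la, lb)
      codes[paste(la, lb, sep = "\r"), j] <- 1
      codes[paste(la, rB, sep = "\r"), j] <- -n_kl / n_of(la, rB)
      codes[paste(rA, lb, sep = "\r"), j] <- -n_kl / n_of(rA, lb)
      codes[paste(rA, rB, sep = "\r"), j] <- n_kl / n_of(rA, rB)
    }
  }
  codes
}

new_coding_matrix <- function(values, scheme, provenance) {
  structure(values, scheme = scheme, provenance = provenance,
            class = c("coding_matrix", class(values)))
}

#' @export
print.coding_matrix <- function(x, ...) {
  cat(sprintf("<coding_matrix> %d x %d, scheme = %s\n",
              nrow(x), ncol(x), attr(x, "scheme")))
  cat("columns:", paste(colnames(x), collapse = ", "), "\n")
  invisible(x)
}

expand_main <- function(spec, values, scheme, counts = NULL) {
  values <- as.character(values)
  bad <- setdiff(unique(values), spec$levels)
  if (length(bad))
    stopf("factor '%s': undeclared level(s) %s", spec$name,
          paste(bad, collapse = ", "))
  codes <- main_cell_codes(spec, scheme, counts)
  m <- codes[values, , drop = FALSE]
  rownames(m) <- NULL
  prov <- data.frame(column = colnames(codes),
                     factor = spec$name,
                     level = setdiff(spec$levels, spec$omitted),
                     type = "main", stringsAsFactors = FALSE)
  new_coding_matrix(m, scheme, prov)
}

expand_interaction <- function(table, values_a, values_b, scheme,
                               cell_counts = NULL) {
  va <- as.character(values_a); vb <- as.character(values_b)
  if (length(va) != length(vb)) stopf("factor value vectors differ in length")
  codes <- interaction_cell_codes(table, scheme, cell_counts)
  key <- paste(va, vb, sep = "\r")
  bad <- setdiff(unique(key), rownames(codes))
  if (length(bad)) stopf("observations in undeclared cells")
  m <- codes[key, , drop = FALSE]
  rownames(m) <- NULL
  keep_a <- setdiff(table$factor_a$levels, table$factor_a$omitted)
  keep_b <- setdiff(table$factor_b$levels, table$factor_b$omitted)
  grid <- expand.grid(a = keep_a, b = keep_b, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  prov <- data.frame(column = colnames(codes),
                     factor = paste(table$factor_a$name, table$factor_b$name,
                                    sep = ":"),
                     level = paste(grid$a, grid$b, sep = ":"),
                     type = "interaction", stringsAsFactors = FALSE)
  new_coding_matrix(m, scheme, prov)
}

#' Main-effect coding columns
#'
#' Build the K-1 per-observation main-effect columns of one categorical
#' factor under dummy, effect, or weighted effect coding.
#'
#' * **Dummy**: column for level k is 1 where the observation has level k,
#'   else 0; the omitted level is all zeros. Coefficients contrast each
#'   level against the reference.
#' * **Effect**: as dummy, but the omitted level is coded -1 in every
#'   column. Coefficients are deviations from the unweighted mean of level
#'   effects, appropriate when the design is balanced.
#' * **Weighted effect (WEC)**: the omitted level is coded -n_k/n_r in the
#'   column for level k (n_k, n_r level counts). Every column then sums to
#'   zero over observations, so coefficients are deviations from the
#'   count-weighted sample mean — the natural baseline when the data, and
#'   the population they represent, are unbalanced.
#'
#' @param spec A [factor_spec].
#' @param values Character vector of observed level labels (one per
#'   observation).
#' @param counts Optional named per-level counts used for the WEC weights
#'   instead of the counts in `spec` (e.g. known population counts).
#' @return A numeric matrix of class `coding_matrix` with one column per
#'   non-omitted level, labelled `"<factor>=<level>"`, plus `scheme` and
#'   `provenance` attributes.
#' @seealso [wec_interaction_columns()] for the interaction block,
#'   [build_design()] for a full design matrix.
#' @export
dummy_main_columns <- function(spec, values) expand_main(spec, values, "dummy")

#' @rdname dummy_main_columns
#' @export
effect_main_columns <- function(spec, values) expand_main(spec, values, "effect")

#' @rdname dummy_main_columns
#' @export
wec_main_columns <- function(spec, values, counts = NULL)
  expand_main(spec, values, "wec", counts)

#' Two-factor interaction coding columns
#'
#' Build the (K-1)(L-1) per-observation interaction columns for a pair of
#' categorical factors. For dummy and effect coding these are elementwise
#' products of the corresponding main-effect columns. For weighted effect
#' coding they are **not** products: each column (k, l) carries a four-cell
#' pattern — +1 in cell (k, l), -n_kl/n_kr in cell (k, rB),
#' -n_kl/n_rl in cell (rA, l), +n_kl/n_rr in cell (rA, rB), 0 elsewhere —
#' where rA, rB are the omitted levels and n with two subscripts are cell
#' counts. This pattern makes every interaction column exactly orthogonal
#' (under summation over observations) to the intercept and to every WEC
#' main-effect column, so the main effects of the additive model are
#' unchanged when the interaction block is added.
#'
#' All four referenced cells must be non-empty for a WEC interaction
#' column; an empty one is an error naming the cell.
#'
#' @param table A [cell_table] for the two factors (provides cell counts
#'   and omitted levels).
#' @param values_a,values_b Observed level labels of the two factors, one
#'   per observation.
#' @param cell_counts Optional K x L count matrix used for the WEC weights
#'   instead of the counts in `table`.
#' @return A `coding_matrix` with columns labelled
#'   `"<levelA>×<levelB>"`.
#' @export
dummy_interaction_columns <- function(table, values_a, values_b)
  expand_interaction(table, values_a, values_b, "dummy")

#' @rdname dummy_interaction_columns
#' @export
effect_interaction_columns <- function(table, values_a, values_b)
  expand_interaction(table, values_a, values_b, "effect")

#' @rdname dummy_interaction_columns
#' @export
wec_interaction_columns <- function(table, values_a, values_b,
                                    cell_counts = NULL)
  expand_interaction(table, values_a, values_b, "wec", cell_counts)

#' Assemble a full design matrix for a two-factor model
#'
#' Convenience wrapper combining intercept, both main-effect blocks, the
#' optional interaction block, and optional control columns into one
#' design matrix under a single coding scheme.
#'
#' @param data Data frame holding the factor columns (named after the
#'   specs) and any control columns.
#' @param factor_a,factor_b [factor_spec] objects.
#' @param scheme `"dummy"`, `"effect"`, or `"wec"`.
#' @param interactions Include the two-factor interaction block?
#' @param intercept Include a leading all-ones column?
#' @param controls Character vector of numeric control column names.
#' @param table Optional [cell_table]; computed from `data` if missing
#'   (needed for WEC interaction weights).
#' @return A `coding_matrix` with provenance for every column.
#' @export
build_design <- function(data, factor_a, factor_b, scheme,
                         interactions = FALSE, intercept = TRUE,
                         controls = NULL, table = NULL) {
  scheme <- check_scheme(scheme)
  va <- dataset_column(data, factor_a)
  vb <- dataset_column(data, factor_b)
  if (is.null(table)) table <- cross_tabulate(data, factor_a, factor_b)
  blocks <- list()
  prov <- list()
  if (intercept) {
    blocks$int <- matrix(1, nrow = nrow(data), ncol = 1,
                         dimnames = list(NULL, "(Intercept)"))
    prov$int <- data.frame(column = "(Intercept)", factor = NA_character_,
                           level = NA_character_, type = "intercept",
                           stringsAsFactors = FALSE)
  }
  ma <- expand_main(factor_a, va, scheme)
  mb <- expand_main(factor_b, vb, scheme)
  blocks$a <- unclass_cm(ma); prov$a <- attr(ma, "provenance")
  blocks$b <- unclass_cm(mb); prov$b <- attr(mb, "provenance")
  if (interactions) {
    mi <- expand_interaction(table, va, vb, scheme)
    blocks$ab <- unclass_cm(mi); prov$ab <- attr(mi, "provenance")
  }
  if (!is.null(controls)) {
    missing_cols <- setdiff(controls, names(data))
    if (length(missing_cols))
      stopf("control column(s) not found: %s",
            paste(missing_cols, collapse = ", "))
    cm <- as.matrix(data[controls])
    storage.mode(cm) <- "double"
    colnames(cm) <- controls
    blocks$controls <- cm
    prov$controls <- data.frame(column = controls, factor = NA_character_,
                                level = NA_character_, type = "control",
                                stringsAsFactors = FALSE)
  }
  m <- do.call(cbind, blocks)
  new_coding_matrix(m, scheme, do.call(rbind, prov))
}

unclass_cm <- function(x) {
  attr(x, "scheme") <- NULL; attr(x, "provenance") <- NULL
  class(x) <- "matrix"
  unclass(x)
}

#' Export a design matrix or its symbolic coding scheme
#'
#' `write_design` writes the per-observation matrix as comma-separated
#' text with a labelled header. `write_coding_scheme` writes the symbolic
#' level-to-weight map of each column (the audit trail of the coding: what
#' weight each factor level, or cell, receives in each column) as JSON.
#'
#' @param design A `coding_matrix`.
#' @param path Output file path.
#' @param spec A [factor_spec] (main effects) for `write_coding_scheme`.
#' @param table A [cell_table] (interactions) for `write_coding_scheme`.
#' @param scheme Coding scheme name.
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(unclass_cm(design)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
write_coding_scheme <- function(path, scheme, spec = NULL, table = NULL) {
  scheme <- check_scheme(scheme)
  out <- list(scheme = scheme)
  if (!is.null(spec)) {
    codes <- main_cell_codes(spec, scheme)
    out$main <- stats::setNames(
      lapply(colnames(codes), function(cn) as.list(codes[, cn])),
      colnames(codes))
  }
  if (!is.null(table)) {
    codes <- interaction_cell_codes(table, scheme)
    cells <- gsub("\r", ":", rownames(codes), fixed = TRUE)
    out$interaction <- stats::setNames(
      lapply(colnames(codes), function(cn)
        stats::setNames(as.list(codes[, cn]), cells)),
      colnames(codes))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
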