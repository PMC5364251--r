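# Synthetic unbalanced two-factor data with known cell means.
#
# The generator emulates the structure of unbalanced observational
# cross-classifications: fixed (design, not random) cell counts, a known
# mean per cell, homoskedastic normal noise within cells, and optionally
# a continuous control with a linear slope. Known truth makes every
# estimation property testable: with zero noise the fits must recover the
# configured means exactly.

#' Configure a two-factor simulation
#'
#' @param cell_counts K x L matrix of positive integer cell counts with
#'   level labels as dimnames (rows = factor A).
#' @param cell_means K x L matrix of cell outcome means, same dimnames.
#' @param residual_sd Within-cell standard deviation of the outcome
#'   (same units as the outcome); 0 gives deterministic data.
#' @param seed Integer seed; the same seed reproduces the dataset
#'   bit-for-bit.
#' @param control_slope Optional slope for a standard-normal continuous
#'   control added to the outcome.
#' @param name_a,name_b Factor (and output column) names.
#' @param outcome Outcome column name.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(cell_counts, cell_means, residual_sd = 0,
                              seed = 1L, control_slope = NULL,
                              name_a = "a", name_b = "b", outcome = "y") {
  cell_counts <- as.matrix(cell_counts)
  cell_means <- as.matrix(cell_means)
  if (is.null(dimnames(cell_counts)))
    stopf("cell_counts needs level labels as dimnames")
  if (is.null(dimnames(cell_means)))
    dimnames(cell_means) <- dimnames(cell_counts)
  if (!identical(dimnames(cell_counts), dimnames(cell_means)))
    stopf("cell_counts and cell_means must share dimnames")
  if (any(cell_counts < 1) || any(cell_counts != round(cell_counts)))
    stopf("cell counts must be positive integers")
  if (residual_sd < 0) stopf("residual_sd must be nonnegative")
  structure(list(cell_counts = cell_counts, cell_means = cell_means,
                 residual_sd = residual_sd, seed = as.integer(seed),
                 control_slope = control_slope,
                 name_a = name_a, name_b = name_b, outcome = outcome),
            class = "simulation_config")
}

#' Generate a dataset from a simulation configuration
#'
#' One row per observation: outcome = cell mean + residual_sd x N(0, 1)
#' (+ slope x control when configured). Cells are generated in sorted
#' (levelA, levelB) label order from a single seeded stream, so a given
#' seed always yields the identical dataset and the empirical cell counts
#' match the configuration exactly.
#'
#' @param config A [simulation_config].
#' @return A data frame with the two factor columns, the outcome, and the
#'   control column `x` if configured.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  la <- rownames(config$cell_counts)
  lb <- colnames(config$cell_counts)
  cells <- expand.grid(a = la, b = lb, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  cells <- cells[order(cells$a, cells$b, method = "radix"), , drop = FALSE]
  parts <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    a <- cells$a[i]; b <- cells$b[i]
    n <- config$cell_counts[a, b]
    y <- rep(config$cell_means[a, b], n)
    if (config$residual_sd > 0) y <- y + config$residual_sd * stats::rnorm(n)
    part <- data.frame(a = rep(a, n), b = rep(b, n), y = y,
                       stringsAsFactors = FALSE)
    if (!is.null(config$control_slope)) {
      part$x <- stats::rnorm(n)
      part$y <- part$y + config$control_slope * part$x
    }
    parts[[i]] <- part
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  names(out)[names(out) == "a"] <- config$name_a
  names(out)[names(out) == "b"] <- config$name_b
  names(out)[names(out) == "y"] <- config$outcome
  out
}

#' Balanced counterpart of a configuration
#'
#' Returns the same configuration with every cell count set to the
#' maximum configured count. On balanced data the weighted-effect columns
#' and coefficients collapse to ordinary effect coding, which is what the
#' scheme-collapse tests exercise.
#'
#' @param config A [simulation_config].
#' @return A [simulation_config] with equal cell counts.
#' @export
balanced_counterpart <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  config$cell_counts[] <- max(config$cell_counts)
  config
}

#' Read and write simulation configurations as JSON
#'
#' @param config A [simulation_config].
#' @param path File path.
#' @export
write_simulation_config <- function(config, path) {
  obj <- list(levels_a = rownames(config$cell_counts),
              levels_b = colnames(config$cell_counts),
              cell_counts = as.data.frame(config$cell_counts),
              cell_means = as.data.frame(config$cell_means),
              residual_sd = config$residual_sd, seed = config$seed,
              control_slope = config$control_slope,
              name_a = config$name_a, name_b = config$name_b,
              outcome = config$outcome)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_simulation_config
#' @export
read_simulation_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  counts <- as.matrix(obj$cell_counts)
  means <- as.matrix(obj$cell_means)
  rownames(counts) <- rownames(means) <- obj$levels_a
  colnames(counts) <- colnames(means) <- obj$levels_b
  slope <- obj$control_slope
  if (length(slope) == 0) slope <- NULL
  simulation_config(counts, means, residual_sd = obj$residual_sd,
                    seed = obj$seed, control_slope = slope,
                    name_a = obj$name_a %||% "a", name_b = obj$name_b %||% "b",
                    outcome = obj$outcome %||% "y")
}
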