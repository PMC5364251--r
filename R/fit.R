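# Model fitting on coded columns: raw observation-level OLS, grouped
# (cell-level sufficient statistic) least squares, and GLMs.
#
# All coded predictors are constant within cells of the two-way
# cross-classification, so least-squares coefficients depend on the data
# only through cell counts and cell means; the grouped fit exploits this
# with count-weighted least squares on one pseudo-observation per cell.

RANK_TOL <- 1e-10

new_fit <- function(coefficients, scheme, model_order, std_errors = NULL,
                    fitted_cell_means = NULL, r_squared = NULL,
                    sigma = NULL, df_residual = NULL, fitted = NULL,
                    family = "gaussian") {
  structure(list(coefficients = coefficients, std_errors = std_errors,
                 fitted_cell_means = fitted_cell_means,
                 r_squared = r_squared, sigma = sigma,
                 df_residual = df_residual, fitted = fitted,
                 scheme = scheme, model_order = model_order,
                 family = family),
            class = "wec_fit")
}

#' @export
print.wec_fit <- function(x, ...) {
  cat(sprintf("<wec_fit> scheme = %s, model = %s, family = %s\n",
              x$scheme, x$model_order, x$family))
  tab <- data.frame(estimate = signif(x$coefficients, 6))
  if (!is.null(x$std_errors)) tab$std.error <- signif(x$std_errors, 6)
  print(tab)
  if (!is.null(x$r_squared))
    cat(sprintf("r.squared = %s\n", signif(x$r_squared, 6)))
  invisible(x)
}

#' @export
coef.wec_fit <- function(object, ...) object$coefficients

# Shared rank check with an error naming the collinear columns.
check_rank <- function(qr_obj, labels) {
  if (qr_obj$rank < length(labels)) {
    dropped <- labels[qr_obj$pivot[(qr_obj$rank + 1L):length(labels)]]
    stopf("design matrix is rank deficient; collinear column(s): %s",
          paste(dropped, collapse = ", "))
  }
}

#' Ordinary least squares on a coded design matrix
#'
#' Fits the outcome on the supplied design columns by QR-decomposition
#' least squares (no normal-equation inversion). Standard errors and R²
#' are available because the raw observations are.
#'
#' @param data Data frame holding the outcome (and the factor columns used
#'   to build `design`).
#' @param design A `coding_matrix` (or plain numeric matrix) with one row
#'   per observation, e.g. from [build_design()].
#' @param outcome Name of the numeric outcome column in `data`.
#' @param include_intercept Prepend an all-ones column unless the design
#'   already contains one.
#' @return A `wec_fit` with coefficients, standard errors, fitted values,
#'   residual sigma and R².
#' @export
fit_ols_raw <- function(data, design, outcome = "y",
                        include_intercept = TRUE) {
  y <- data[[outcome]]
  if (is.null(y)) stopf("outcome column '%s' not found", outcome)
  y <- as.numeric(y)
  x <- unclass_cm(design)
  if (nrow(x) != length(y))
    stopf("design has %d rows but outcome has %d observations",
          nrow(x), length(y))
  if (include_intercept && !"(Intercept)" %in% colnames(x))
    x <- cbind("(Intercept)" = 1, x)
  qr_x <- qr(x, tol = RANK_TOL)
  check_rank(qr_x, colnames(x))
  fit <- stats::lm.fit(x, y, tol = RANK_TOL)
  coefs <- fit$coefficients
  rss <- sum(fit$residuals^2)
  dfres <- length(y) - fit$rank
  sigma2 <- if (dfres > 0) rss / dfres else 0
  xtx_inv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(pmax(diag(xtx_inv), 0) * sigma2)
  names(se) <- colnames(x)[fit$qr$pivot]
  se <- se[colnames(x)]
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  new_fit(coefficients = coefs,
          scheme = attr(design, "scheme") %||% "custom",
          model_order = NA_character_,
          std_errors = se, r_squared = r2,
          sigma = sqrt(sigma2), df_residual = dfres,
          fitted = fit$fitted.values)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cell-level design for a grouped fit: one pseudo-observation per
# non-empty cell, coded exactly as the per-observation builders would
# code every member of that cell.
cell_design <- function(table, scheme, model_order) {
  fa <- table$factor_a; fb <- table$factor_b
  grid <- expand.grid(a = fa$levels, b = fb$levels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$a, fa$levels), match(grid$b, fb$levels)), ]
  keep <- mapply(function(a, b) table$counts[a, b] > 0, grid$a, grid$b)
  grid <- grid[keep, , drop = FALSE]
  ma <- expand_main(fa, grid$a, scheme)
  mb <- expand_main(fb, grid$b, scheme)
  x <- cbind("(Intercept)" = 1, unclass_cm(ma), unclass_cm(mb))
  if (model_order == "with_interactions") {
    mi <- expand_interaction(table, grid$a, grid$b, scheme)
    x <- cbind(x, unclass_cm(mi))
  }
  list(x = x, grid = grid,
       w = mapply(function(a, b) table$counts[a, b], grid$a, grid$b))
}

#' Grouped least squares from cell counts and cell means
#'
#' Fits the coded two-factor model from sufficient statistics alone:
#' count-weighted least squares on the cell-level design, with the cell
#' means as responses and cell counts as weights. Because every coded
#' predictor is constant within a cell, the coefficients are identical to
#' an observation-level OLS fit of the same model. No standard errors are
#' reported — the within-cell outcome variance is not recoverable from
#' counts and means.
#'
#' @param table A [cell_table] with `means` present.
#' @param scheme `"dummy"`, `"effect"`, or `"wec"`.
#' @param model_order `"additive"` (main effects only) or
#'   `"with_interactions"`.
#' @return A `wec_fit`; `fitted_cell_means` holds the model's fitted mean
#'   for every non-empty cell.
#' @export
fit_ols_grouped <- function(table, scheme = c("wec", "effect", "dummy"),
                            model_order = c("additive", "with_interactions")) {
  scheme <- match.arg(scheme)
  model_order <- match.arg(model_order)
  if (is.null(table$means))
    stopf("grouped fit needs cell means in the cell table")
  d <- cell_design(table, scheme, model_order)
  y <- mapply(function(a, b) table$means[a, b], d$grid$a, d$grid$b)
  if (anyNA(y)) stopf("cell means contain missing values in non-empty cells")
  xw <- d$x * sqrt(d$w)
  qr_x <- qr(xw, tol = RANK_TOL)
  check_rank(qr_x, colnames(d$x))
  fit <- stats::lm.wfit(d$x, y, d$w, tol = RANK_TOL)
  fitted <- matrix(NA_real_, nrow = length(table$factor_a$levels),
                   ncol = length(table$factor_b$levels),
                   dimnames = dimnames(table$counts))
  for (i in seq_len(nrow(d$grid)))
    fitted[d$grid$a[i], d$grid$b[i]] <- fit$fitted.values[i]
  new_fit(coefficients = fit$coefficients, scheme = scheme,
          model_order = model_order, fitted_cell_means = fitted)
}

#' Fit a generalized linear model on coded columns
#'
#' Maximum-likelihood fit of a GLM whose design matrix is a set of coding
#' columns. With the gaussian family this reproduces [fit_ols_raw()]. With
#' the binomial (logit) family the coefficients are deviations on the
#' log-odds scale: weighted-effect-coded effects then relate to the odds,
#' not directly to the probability itself.
#'
#' Non-convergence — including quasi-separation, where fitted
#' probabilities are driven to 0 or 1 and coefficients diverge — is an
#' error reporting the iteration count rather than a silently unstable
#' fit.
#'
#' @param data Data frame holding the outcome.
#' @param design Coding matrix, one row per observation.
#' @param family `"gaussian"` or `"binomial"` (logit link).
#' @param outcome Name of the outcome column (numeric; 0/1 for binomial).
#' @param include_intercept Prepend an all-ones column unless present.
#' @param maxit Maximum IRLS iterations.
#' @return A `wec_fit` with coefficients and standard errors.
#' @export
fit_glm <- function(data, design, family = c("gaussian", "binomial"),
                    outcome = "y", include_intercept = TRUE, maxit = 25L) {
  family <- match.arg(family)
  fam <- switch(family, gaussian = stats::gaussian(),
                binomial = stats::binomial(link = "logit"))
  y <- data[[outcome]]
  if (is.null(y)) stopf("outcome column '%s' not found", outcome)
  y <- as.numeric(y)
  if (family == "binomial" && !all(y %in% c(0, 1)))
    stopf("binomial family needs a 0/1 outcome")
  x <- unclass_cm(design)
  if (include_intercept && !"(Intercept)" %in% colnames(x))
    x <- cbind("(Intercept)" = 1, x)
  qr_x <- qr(x, tol = RANK_TOL)
  check_rank(qr_x, colnames(x))
  fit <- suppressWarnings(
    stats::glm.fit(x, y, family = fam,
                   control = stats::glm.control(maxit = maxit)))
  if (!fit$converged)
    stopf("GLM did not converge after %d iteration(s); %s",
          fit$iter,
          if (family == "binomial")
            "check for separation (a cell with constant outcome)"
          else "check the design")
  if (family == "binomial") {
    eps <- 1e-8
    if (any(fit$fitted.values < eps | fit$fitted.values > 1 - eps))
      stopf(paste0("GLM did not reach a stable optimum after %d iteration(s): ",
                   "fitted probabilities at the 0/1 boundary indicate ",
                   "separation (a cell with constant outcome)"), fit$iter)
  }
  cov_unscaled <- chol2inv(qr.R(fit$qr))
  disp <- if (family == "gaussian")
    sum(fit$weights * fit$residuals^2) / fit$df.residual else 1
  se <- sqrt(pmax(diag(cov_unscaled), 0) * disp)
  names(se) <- colnames(x)[fit$qr$pivot]
  se <- se[colnames(x)]
  new_fit(coefficients = fit$coefficients,
          scheme = attr(design, "scheme") %||% "custom",
          model_order = NA_character_,
          std_errors = se, fitted = fit$fitted.values,
          df_residual = fit$df.residual, family = family)
}

#' Export fit results as text or JSON
#'
#' Writes the coefficient table (label, estimate and — when available —
#' standard error) as comma-separated text, or the full fit as JSON at
#' full precision.
#'
#' @param fit A `wec_fit` or `completed_estimates` object.
#' @param path Output path.
#' @export
write_fit <- function(fit, path) {
  tab <- data.frame(term = names(fit$coefficients),
                    estimate = unname(fit$coefficients))
  if (!is.null(fit$std_errors)) tab$std.error <- unname(fit$std_errors)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fit
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(scheme = fit$scheme, model_order = fit$model_order,
              family = fit$family,
              coefficients = as.list(fit$coefficients))
  if (!is.null(fit$std_errors)) obj$std_errors <- as.list(fit$std_errors)
  if (!is.null(fit$r_squared)) obj$r_squared <- fit$r_squared
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
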