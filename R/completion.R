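# Completion of omitted-category coefficients and the main-effect
# invariance verifier.
#
# Effect and weighted effect coding drop one level per factor (and one
# row/column of interaction cells) for identifiability, but the dropped
# coefficients are recoverable: refitting with a different omitted level
# yields them directly, and the parameterization's sum-to-zero constraints
# give an independent closed form. Both are computed and must agree.

COMPLETION_TOL <- 1e-6

#' Recover coefficients for omitted categories
#'
#' Completes an effect-coded or weighted-effect-coded fit to the full set
#' of coefficients: main effects for every level of both factors (the
#' omitted ones included) and, for an interaction model, effects for all
#' K x L cells.
#'
#' The primary method is refitting the same model with different omitted
#' levels and reading the missing coefficients off the refits. Each
#' completed value is then cross-checked against the scheme's sum-to-zero
#' constraint — unweighted sums for effect coding
#' (sum_k b_k = 0), count-weighted sums for weighted effect coding
#' (sum_k n_k b_k = 0 per factor; sum_l n_kl b_kl = 0 for every row k and
#' sum_k n_kl b_kl = 0 for every column l of the interaction cells).
#' Disagreement beyond `tol` is an error: it signals an inconsistent
#' coding, not a rounding issue.
#'
#' @param fit A `wec_fit` from [fit_ols_grouped()] or [fit_ols_raw()]
#'   under the `"effect"` or `"wec"` scheme.
#' @param table The [cell_table] (with observed cell means) the fit is
#'   based on; refits are run on it.
#' @param tol Maximum allowed |refit - constraint| disagreement.
#' @return An object of class `completed_estimates`: `intercept`,
#'   `main_effects` (named list with one full-length named vector per
#'   factor), and `interaction_effects` (K x L matrix, or `NULL` for an
#'   additive fit).
#' @export
complete_estimates <- function(fit, table, tol = COMPLETION_TOL) {
  stopifnot(inherits(fit, "wec_fit"), inherits(table, "cell_table"))
  scheme <- fit$scheme
  if (!scheme %in% c("effect", "wec"))
    stopf("completion is defined for effect and weighted effect coding, not '%s'",
          scheme)
  model_order <- fit$model_order
  if (is.na(model_order))
    stopf("completion needs a grouped fit (additive or with_interactions)")
  fa <- table$factor_a; fb <- table$factor_b
  rA <- fa$omitted; rB <- fb$omitted
  altA <- setdiff(fa$levels, rA)[1L]
  altB <- setdiff(fb$levels, rB)[1L]

  refit <- function(om_a, om_b) {
    tab <- table
    tab$factor_a <- set_omitted(fa, om_a)
    tab$factor_b <- set_omitted(fb, om_b)
    fit_ols_grouped(tab, scheme, model_order)
  }
  f1 <- refit(altA, rB)   # provides main effect of rA
  f2 <- refit(rA, altB)   # provides main effect of rB

  main_a <- c(fit$coefficients[main_label(fa, setdiff(fa$levels, rA))],
              f1$coefficients[main_label(fa, rA)])
  names(main_a) <- c(setdiff(fa$levels, rA), rA)
  main_a <- main_a[fa$levels]
  main_b <- c(fit$coefficients[main_label(fb, setdiff(fb$levels, rB))],
              f2$coefficients[main_label(fb, rB)])
  names(main_b) <- c(setdiff(fb$levels, rB), rB)
  main_b <- main_b[fb$levels]

  inter <- NULL
  if (model_order == "with_interactions") {
    f3 <- refit(altA, altB)  # provides cell (rA, rB)
    inter <- matrix(NA_real_, nrow = length(fa$levels),
                    ncol = length(fb$levels),
                    dimnames = list(fa$levels, fb$levels))
    pick <- function(f, la, lb) unname(f$coefficients[int_label(la, lb)])
    for (la in fa$levels) for (lb in fb$levels) {
      inter[la, lb] <-
        if (la != rA && lb != rB) pick(fit, la, lb)
        else if (la == rA && lb != rB) pick(f1, la, lb)
        else if (la != rA && lb == rB) pick(f2, la, lb)
        else pick(f3, la, lb)
    }
  }

  check <- function(observed, expected, what) {
    if (abs(observed - expected) > tol)
      stopf("completion cross-check failed for %s: refit %.10g vs constraint %.10g (coding bug?)",
            what, observed, expected)
  }
  wa <- if (scheme == "wec") fa$counts else
    stats::setNames(rep(1, length(fa$levels)), fa$levels)
  wb <- if (scheme == "wec") fb$counts else
    stats::setNames(rep(1, length(fb$levels)), fb$levels)
  check(main_a[[rA]],
        -sum(wa[setdiff(fa$levels, rA)] * main_a[setdiff(fa$levels, rA)]) /
          wa[[rA]],
        sprintf("main effect '%s'", rA))
  check(main_b[[rB]],
        -sum(wb[setdiff(fb$levels, rB)] * main_b[setdiff(fb$levels, rB)]) /
          wb[[rB]],
        sprintf("main effect '%s'", rB))
  if (!is.null(inter)) {
    wcell <- if (scheme == "wec") table$counts else
      matrix(1, nrow = nrow(table$counts), ncol = ncol(table$counts),
             dimnames = dimnames(table$counts))
    for (la in fa$levels)
      check(inter[la, rB],
            -sum(wcell[la, setdiff(fb$levels, rB)] *
                   inter[la, setdiff(fb$levels, rB)]) / wcell[la, rB],
            sprintf("interaction row '%s'", la))
    for (lb in fb$levels)
      check(inter[rA, lb],
            -sum(wcell[setdiff(fa$levels, rA), lb] *
                   inter[setdiff(fa$levels, rA), lb]) / wcell[rA, lb],
            sprintf("interaction column '%s'", lb))
  }

  structure(list(intercept = unname(fit$coefficients[["(Intercept)"]]),
                 main_effects = stats::setNames(
                   list(main_a, main_b), c(fa$name, fb$name)),
                 interaction_effects = inter,
                 scheme = scheme, model_order = model_order),
            class = "completed_estimates")
}

#' @export
print.completed_estimates <- function(x, ...) {
  cat(sprintf("<completed_estimates> scheme = %s, model = %s\n",
              x$scheme, x$model_order))
  cat(sprintf("intercept: %s\n", signif(x$intercept, 6)))
  for (nm in names(x$main_effects)) {
    cat(sprintf("%s:\n", nm)); print(signif(x$main_effects[[nm]], 6))
  }
  if (!is.null(x$interaction_effects)) {
    cat("interactions:\n"); print(signif(x$interaction_effects, 6))
  }
  invisible(x)
}

#' Export completed estimates
#'
#' @param x A `completed_estimates` object.
#' @param path Output path.
#' @export
write_completed_json <- function(x, path) {
  obj <- list(scheme = x$scheme, model_order = x$model_order,
              intercept = x$intercept,
              main_effects = lapply(x$main_effects, as.list),
              interaction_effects =
                if (!is.null(x$interaction_effects))
                  as.data.frame(x$interaction_effects))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Verify main-effect invariance under added interactions
#'
#' Fits the additive and the interaction model on the same cell table and
#' reports the largest absolute change in the intercept and in any
#' main-effect coefficient. Under weighted effect coding the interaction
#' columns are exactly orthogonal to the intercept and main-effect
#' columns, so for identity-link fits without controls both changes are
#' zero up to numerical precision. For effect coding the same holds only
#' in balanced designs. The verifier reports observed changes for any
#' scheme; it asserts nothing itself.
#'
#' @param table A [cell_table] with means.
#' @param scheme Coding scheme to inspect.
#' @return A list: `max_intercept_change`, `max_main_change`, and the two
#'   fits (`additive`, `with_interactions`).
#' @export
verify_invariance <- function(table, scheme = c("wec", "effect", "dummy")) {
  scheme <- match.arg(scheme)
  f0 <- fit_ols_grouped(table, scheme, "additive")
  f1 <- fit_ols_grouped(table, scheme, "with_interactions")
  shared <- names(f0$coefficients)
  delta <- abs(f1$coefficients[shared] - f0$coefficients[shared])
  list(max_intercept_change = unname(delta[["(Intercept)"]]),
       max_main_change = max(delta[setdiff(shared, "(Intercept)")]),
       additive = f0, with_interactions = f1)
}
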