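# Fitting on coded columns: raw vs grouped agreement, scheme
# equivalence, completion constraints, invariance, and GLMs.

fit_raw_scheme <- function(data, table, scheme, interactions) {
  design <- build_design(data, table$factor_a, table$factor_b, scheme,
                         interactions = interactions, table = table)
  fit_ols_raw(data, design)
}

test_that("grouped least squares equals raw OLS on the same data", {
  for (seed in c(21, 22, 23)) {
    tab0 <- random_table(3, 2, seed)
    config <- simulation_config(tab0$counts, tab0$means, residual_sd = 2,
                                seed = seed, name_a = "A", name_b = "B")
    d <- generate_dataset(config)
    fa <- factor_spec(d$A, name = "A", omitted = tab0$factor_a$omitted,
                      levels = tab0$factor_a$levels)
    fb <- factor_spec(d$B, name = "B", omitted = tab0$factor_b$omitted,
                      levels = tab0$factor_b$levels)
    tab <- cross_tabulate(d, fa, fb, outcome = "y")
    for (scheme in c("dummy", "effect", "wec"))
      for (model in c("additive", "with_interactions")) {
        raw <- fit_raw_scheme(d, tab, scheme, model == "with_interactions")
        grp <- fit_ols_grouped(tab, scheme, model)
        expect_equal(raw$coefficients, grp$coefficients, tolerance = 1e-8)
      }
  }
})

test_that("fitted values and R-squared agree across all three schemes", {
  tab0 <- random_table(2, 4, seed = 31)
  config <- simulation_config(tab0$counts, tab0$means, residual_sd = 1.5,
                              seed = 31, name_a = "A", name_b = "B")
  d <- generate_dataset(config)
  fa <- factor_spec(d$A, name = "A", levels = tab0$factor_a$levels)
  fb <- factor_spec(d$B, name = "B", levels = tab0$factor_b$levels)
  tab <- cross_tabulate(d, fa, fb, outcome = "y")
  for (model in c(FALSE, TRUE)) {
    fits <- lapply(c("dummy", "effect", "wec"), function(s)
      fit_raw_scheme(d, tab, s, model))
    expect_equal(fits[[1]]$fitted, fits[[2]]$fitted, tolerance = 1e-8)
    expect_equal(fits[[2]]$fitted, fits[[3]]$fitted, tolerance = 1e-8)
    expect_equal(fits[[1]]$r_squared, fits[[3]]$r_squared, tolerance = 1e-8)
  }
})

test_that("saturated dummy fits recover cell structure; zero noise is exact", {
  tab <- random_table(3, 3, seed = 41)
  d <- expand_table(tab)   # zero-noise data with the table's means
  fa <- tab$factor_a; fb <- tab$factor_b
  names(d)[1:2] <- c(fa$name, fb$name)
  design <- build_design(d, fa, fb, "dummy", interactions = TRUE,
                         table = tab)
  fit <- fit_ols_raw(d, design)
  # intercept of the saturated dummy fit is the all-reference cell mean
  expect_equal(unname(fit$coefficients[["(Intercept)"]]),
               tab$means[fa$omitted, fb$omitted])
  expect_equal(fit$r_squared, 1)
  # grouped saturated fit reproduces every cell mean exactly
  grp <- fit_ols_grouped(tab, "wec", "with_interactions")
  expect_equal(grp$fitted_cell_means, tab$means, tolerance = 1e-10)
})

test_that("rank deficiency is an error naming the collinear columns", {
  tab <- random_table(2, 2, seed = 51)
  d <- expand_table(tab)
  names(d)[1:2] <- c("A", "B")
  design <- build_design(d, tab$factor_a, tab$factor_b, "wec", table = tab)
  doubled <- cbind(unclass(design), dup = unclass(design)[, 2])
  expect_error(fit_ols_raw(d, doubled), "collinear.*dup")
})

test_that("single-factor wec coefficients are deviations from the weighted mean", {
  # closed form checked by brute force: b_k = mean_k - weighted grand mean
  set.seed(61)
  d <- data.frame(g = rep(c("u", "v", "w"), c(12, 5, 23)),
                  y = rnorm(40, mean = 10), stringsAsFactors = FALSE)
  fs <- factor_spec(d$g, name = "g", omitted = "w")
  design <- wec_main_columns(fs, d$g)
  fit <- fit_ols_raw(d, design)
  grand <- mean(d$y)
  expect_equal(unname(fit$coefficients[["(Intercept)"]]), grand,
               tolerance = 1e-10)
  for (l in c("u", "v"))
    expect_equal(unname(fit$coefficients[[paste0("g=", l)]]),
                 mean(d$y[d$g == l]) - grand, tolerance = 1e-10)
})

test_that("completion recovers omitted categories and obeys the constraints", {
  # balanced two-level factors: completion is exact negation
  fa <- factor_spec(name = "A", counts = c(a1 = 4, a2 = 4), omitted = "a1")
  fb <- factor_spec(name = "B", counts = c(b1 = 4, b2 = 4), omitted = "b1")
  means <- matrix(c(1, 2, 3, 7), 2, dimnames = list(fa$levels, fb$levels))
  counts <- matrix(2, 2, 2, dimnames = dimnames(means))
  tab <- cell_table(fa, fb, counts, means)
  for (scheme in c("effect", "wec")) {
    comp <- complete_estimates(fit_ols_grouped(tab, scheme, "additive"), tab)
    expect_equal(comp$main_effects$A[["a1"]], -comp$main_effects$A[["a2"]])
    expect_equal(comp$main_effects$B[["b1"]], -comp$main_effects$B[["b2"]])
  }

  # random unbalanced tables: weighted / unweighted sum-to-zero holds for
  # mains and for every interaction row and column
  for (seed in c(62, 63)) {
    tab <- random_table(3, 4, seed)
    for (scheme in c("effect", "wec")) {
      fit <- fit_ols_grouped(tab, scheme, "with_interactions")
      comp <- complete_estimates(fit, tab)
      wa <- if (scheme == "wec") tab$factor_a$counts else
        setNames(rep(1, 3), tab$factor_a$levels)
      wb <- if (scheme == "wec") tab$factor_b$counts else
        setNames(rep(1, 4), tab$factor_b$levels)
      wc <- if (scheme == "wec") tab$counts else (tab$counts * 0 + 1)
      expect_lt(abs(sum(wa * comp$main_effects$A)), 1e-8)
      expect_lt(abs(sum(wb * comp$main_effects$B)), 1e-8)
      inter <- comp$interaction_effects
      expect_lt(max(abs(rowSums(wc * inter))), 1e-8)
      expect_lt(max(abs(colSums(wc * inter))), 1e-8)
    }
  }

  # completion is undefined for dummy coding
  tab <- random_table(2, 2, seed = 64)
  expect_error(
    complete_estimates(fit_ols_grouped(tab, "dummy", "additive"), tab),
    "dummy")
})

test_that("completed wec interactions equal cell mean minus additive fit", {
  # the saturated-model identity: the interaction effect for cell (k, l)
  # is the cell mean minus intercept + main_k + main_l of the ADDITIVE fit
  tab <- random_table(3, 3, seed = 71)
  add <- complete_estimates(fit_ols_grouped(tab, "wec", "additive"), tab)
  sat <- complete_estimates(
    fit_ols_grouped(tab, "wec", "with_interactions"), tab)
  for (la in tab$factor_a$levels) for (lb in tab$factor_b$levels)
    expect_equal(sat$interaction_effects[la, lb],
                 tab$means[la, lb] -
                   (add$intercept + add$main_effects$A[[la]] +
                      add$main_effects$B[[lb]]),
                 tolerance = 1e-8)
})

test_that("wec main effects are invariant to adding interactions", {
  # exact column orthogonality implies unchanged intercept and mains
  for (seed in 81:85) {
    tab <- random_table(sample(2:4, 1), sample(2:4, 1), seed)
    rep <- verify_invariance(tab, "wec")
    expect_lt(rep$max_intercept_change, 1e-8)
    expect_lt(rep$max_main_change, 1e-8)
  }
  # effect coding is invariant only under balance
  tab_u <- random_table(3, 3, seed = 86)
  expect_gt(verify_invariance(tab_u, "effect")$max_main_change, 1e-6)
  bal <- tab_u
  bal$counts[] <- 12
  bal$factor_a <- factor_spec(name = "A", counts = rowSums(bal$counts),
                              omitted = tab_u$factor_a$omitted,
                              levels = tab_u$factor_a$levels)
  bal$factor_b <- factor_spec(name = "B", counts = colSums(bal$counts),
                              omitted = tab_u$factor_b$omitted,
                              levels = tab_u$factor_b$levels)
  bal <- cell_table(bal$factor_a, bal$factor_b, bal$counts, bal$means)
  inv <- verify_invariance(bal, "effect")
  expect_lt(inv$max_intercept_change, 1e-10)
  expect_lt(inv$max_main_change, 1e-10)
})

test_that("gaussian GLM reproduces OLS; saturated logit matches cell proportions", {
  tab0 <- random_table(2, 3, seed = 91)
  config <- simulation_config(tab0$counts * 3, tab0$means, residual_sd = 1,
                              seed = 91, name_a = "A", name_b = "B")
  d <- generate_dataset(config)
  fa <- factor_spec(d$A, name = "A", levels = tab0$factor_a$levels)
  fb <- factor_spec(d$B, name = "B", levels = tab0$factor_b$levels)
  tab <- cross_tabulate(d, fa, fb, outcome = "y")
  design <- build_design(d, fa, fb, "wec", interactions = TRUE, table = tab)
  ols <- fit_ols_raw(d, design)
  glm_g <- fit_glm(d, design, family = "gaussian")
  expect_equal(glm_g$coefficients, ols$coefficients, tolerance = 1e-8)

  # binary outcome with known, interior cell probabilities: the
  # saturated logit's fitted probabilities equal the observed cell
  # proportions (maximum-likelihood identity for saturated models)
  set.seed(92)
  prob <- matrix(c(0.2, 0.5, 0.7, 0.4, 0.6, 0.3), nrow = 2,
                 dimnames = dimnames(tab0$counts))
  nb <- tab0$counts * 0 + 60
  db <- expand_table(cell_table(
    factor_spec(name = "A", counts = rowSums(nb), levels = rownames(nb)),
    factor_spec(name = "B", counts = colSums(nb), levels = colnames(nb)),
    nb))
  db$y <- rbinom(nrow(db), 1, prob[cbind(db$A, db$B)])
  fab <- factor_spec(db$A, name = "A")
  fbb <- factor_spec(db$B, name = "B")
  tb <- cross_tabulate(db, fab, fbb, outcome = "y")
  des <- build_design(db, fab, fbb, "wec", interactions = TRUE, table = tb)
  fit <- fit_glm(db, des, family = "binomial")
  fitted_cells <- tapply(fit$fitted, list(db$A, db$B), mean)
  expect_equal(unclass(fitted_cells), unclass(tb$means), tolerance = 1e-6)

  # a cell with constant outcome separates the saturated logit
  db2 <- db
  db2$y[db2$A == "a1" & db2$B == "b1"] <- 1
  tb2 <- cross_tabulate(db2, fab, fbb, outcome = "y")
  des2 <- build_design(db2, fab, fbb, "wec", interactions = TRUE,
                       table = tb2)
  expect_error(fit_glm(db2, des2, family = "binomial"),
               "iteration|separation")
})

test_that("controls are supported as extra design columns", {
  tab0 <- random_table(2, 2, seed = 95)
  config <- simulation_config(tab0$counts * 5, tab0$means,
                              residual_sd = 0.5, seed = 95,
                              control_slope = 1.7,
                              name_a = "A", name_b = "B")
  d <- generate_dataset(config)
  fa <- factor_spec(d$A, name = "A", levels = tab0$factor_a$levels)
  fb <- factor_spec(d$B, name = "B", levels = tab0$factor_b$levels)
  design <- build_design(d, fa, fb, "wec", controls = "x")
  fit <- fit_ols_raw(d, design)
  expect_equal(unname(fit$coefficients[["x"]]), 1.7, tolerance = 0.1)
  expect_error(build_design(d, fa, fb, "wec", controls = "nope"),
               "control column")
})
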