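# Shared fixtures: random unbalanced tables, expansion to raw data, and
# the reconstructed published example.

# Random unbalanced K x L cell table with positive counts and arbitrary
# cell means. Counts are drawn wide (1..40) so designs are far from
# balanced; omitted levels are chosen by the default most-frequent rule.
random_table <- function(K, L, seed, with_means = TRUE) {
  set.seed(seed)
  counts <- matrix(sample(1:40, K * L, replace = TRUE), nrow = K,
                   dimnames = list(paste0("a", seq_len(K)),
                                   paste0("b", seq_len(L))))
  fa <- factor_spec(name = "A", counts = rowSums(counts), omitted = "auto")
  fb <- factor_spec(name = "B", counts = colSums(counts), omitted = "auto")
  means <- NULL
  if (with_means)
    means <- matrix(round(rnorm(K * L, mean = 20, sd = 3), 3), nrow = K,
                    dimnames = dimnames(counts))
  cell_table(fa, fb, counts, means)
}

# Expand a cell table into a zero-noise observation-level dataset whose
# cell means equal the table's exactly.
expand_table <- function(table) {
  grid <- expand.grid(a = table$factor_a$levels, b = table$factor_b$levels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    n <- table$counts[grid$a[i], grid$b[i]]
    if (n == 0) return(NULL)
    data.frame(A = rep(grid$a[i], n), B = rep(grid$b[i], n),
               y = rep(if (is.null(table$means)) 0
                       else table$means[grid$a[i], grid$b[i]], n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Brute-force cell-level dot product of two coding columns given their
# symbolic per-cell codes: sum over cells of n_cell * code1 * code2.
# Independent of the per-observation expansion path.
cell_dot <- function(counts, codes1, codes2) {
  stopifnot(identical(rownames(codes1), rownames(codes2)))
  n <- as.vector(t(counts))  # row-major (levelA, levelB) cell order
  crossprod(codes1 * n, codes2)
}

# The published example as a fitted-ready cell table: printed counts plus
# cell means reconstructed from the printed saturated dummy coefficients.
table4_cell_table <- function() {
  fx <- table4_fixture()
  means <- reconstruct_cell_means(
    intercept = fx$dummy_model2$intercept,
    effects_a = unlist(fx$dummy_model2$children),
    effects_b = unlist(fx$dummy_model2$age),
    effects_ab = unlist(fx$dummy_model2$interaction),
    factor_a = fx$factor_a, factor_b = fx$factor_b)
  cell_table(fx$factor_a, fx$factor_b, fx$counts, means)
}
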