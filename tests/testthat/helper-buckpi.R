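# Shared fixtures, all built in code.

# A tiny two-length-variable system: x/y is the only pi-group.
two_length_specs <- function() {
  list(variable_spec("x", c(length = 1), "independent"),
       variable_spec("y", c(length = 1), "independent"),
       variable_spec("z", c(length = 0), "dependent"))
}

# Random variable system over the four base dimensions with integer
# exponents in [-3, 3]; roles all independent.
random_specs <- function(n_vars, seed) {
  set.seed(seed)
  lapply(seq_len(n_vars), function(i) {
    d <- sample(-3:3, 4, replace = TRUE)
    names(d) <- base_dimensions()
    variable_spec(paste0("v", i), d[d != 0], "independent")
  })
}

# Numeric matrix of a dim_matrix (entries are exact small rationals, so
# the float image is exact for integral entries).
dm_numeric <- function(dm) dm$num / dm$den

# Exact span-equality check for integer exponent matrices (rows = vectors):
# spans are equal iff stacking changes no rank.  Entries are small
# integers, so qr() ranks are reliable.
same_span <- function(A, B) {
  qr(A)$rank == qr(B)$rank && qr(rbind(A, B))$rank == qr(A)$rank
}

# Exponent matrix (groups x variables) of a pi basis over given symbols.
basis_matrix <- function(groups, symbols) {
  t(vapply(groups, function(g) {
    v <- stats::setNames(rep(0, length(symbols)), symbols)
    v[names(g$num)] <- g$num / g$den
    v
  }, numeric(length(symbols))))
}

# Small complete observation table for dataio tests.
tiny_table <- function(n = 10, seed = 42) {
  generate_observations(synthetic_config(n_rows = n, sigma = 0.1,
                                         seed = seed))
}
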