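test_that("dimensional matrix transcribes specs exactly, in input order", {
  specs <- two_length_specs()[1:2]
  dm <- build_dimensional_matrix(specs)
  expect_equal(dm$symbols, c("x", "y"))
  expect_equal(unname(dm_numeric(dm)["length", ]), c(1, 1))
  # dimensions nobody uses still get a (zero) row
  expect_equal(nrow(dm$num), 4)
  expect_true(all(dm_numeric(dm)["mass", ] == 0))

  dup <- list(variable_spec("x", c(length = 1)),
              variable_spec("x", c(time = 1)))
  expect_error(build_dimensional_matrix(dup), "duplicate.*x")
  expect_error(build_dimensional_matrix(list()), "non-empty")
})

test_that("the 8 independent biofilter variables give a rank-4 matrix", {
  indep <- Filter(function(s) s$role == "independent", biofilter_variables())
  dm <- build_dimensional_matrix(indep)
  expect_equal(ncol(dm$num), 8)
  expect_equal(dim_matrix_rank(dm), 4)
  expect_equal(qr(dm_numeric(dm))$rank, 4)  # independent float oracle
})

test_that("rational_nullspace matches the n - rank rule and is exact", {
  # trivial null space
  ident <- list(variable_spec("a", c(mass = 1)),
                variable_spec("b", c(length = 1)))
  expect_length(rational_nullspace(build_dimensional_matrix(ident)), 0)

  # two like-dimensioned variables: basis is the ratio
  dm <- build_dimensional_matrix(two_length_specs()[1:2])
  ns <- rational_nullspace(dm)
  expect_length(ns, 1)
  v <- as.numeric(ns[[1]])  # the ratio of like quantities, up to sign
  expect_true(identical(v, c(1, -1)) || identical(v, c(-1, 1)))

  # biofilter independents: 4 basis vectors, each exactly in the kernel
  indep <- Filter(function(s) s$role == "independent", biofilter_variables())
  dmb <- build_dimensional_matrix(indep)
  nsb <- rational_nullspace(dmb)
  expect_length(nsb, 4)
  for (v in nsb)
    expect_true(all(dm_numeric(dmb) %*% as.numeric(v) == 0))
})

test_that("null-space dimension equals n - rank on random rational systems", {
  for (seed in 1:20) {
    n_vars <- sample(3:10, 1)
    specs <- random_specs(n_vars, seed = 100 + seed)
    dm <- build_dimensional_matrix(specs)
    ns <- rational_nullspace(dm)
    r <- qr(dm_numeric(dm))$rank  # independent row-reduction oracle
    expect_length(ns, n_vars - r)
    for (v in ns) {
      expect_true(all(dm_numeric(dm) %*% as.numeric(v) == 0))
      # canonical form: integer entries, overall gcd 1
      expect_true(all(v == round(v)))
      g <- Reduce(function(a, b) buckpi:::.gcd2(a, b), abs(v))
      expect_equal(g, 1)
    }
  }
})

test_that("biofilter basis has 4 groups spanning the printed ratios", {
  basis <- construct_pi_basis(biofilter_variables())
  expect_length(basis$independent, 4)
  syms <- c("IC_org", "C_fit", "A", "T", "Pz", "Bt", "P", "t0")
  got <- basis_matrix(basis$independent, syms)
  want <- rbind(
    `Pz/C_fit` = c(0, -1, 0, 0, 1, 0, 0, 0),
    `Bt/A` = c(0, 0, -1, 0, 0, 1, 0, 0),
    `P/C_fit` = c(0, -1, 0, 0, 0, 0, 1, 0),
    `t0/T` = c(0, 0, 0, -1, 0, 0, 0, 1))
  colnames(want) <- syms
  expect_true(same_span(got, want))
  # dependent group is exactly EC_org / IC_org
  dep <- basis$dependent
  expect_equal(sort(names(dep$num)), c("EC_org", "IC_org"))
  expect_equal(unname(dep$num[c("EC_org", "IC_org")] /
                        dep$den[c("EC_org", "IC_org")]), c(1, -1))
  expect_equal(dep$label, "EC_org/IC_org")
})

test_that("degenerate system: dimensionless dependent, one independent", {
  specs <- list(variable_spec("u", c(length = 1), "independent"),
                variable_spec("q", c(), "dependent"))
  basis <- construct_pi_basis(specs)
  expect_length(basis$independent, 0)
  expect_equal(names(basis$dependent$num), "q")
  expect_equal(unname(basis$dependent$num), 1)
})

test_that("dependent variable outside the independent span is an error", {
  specs <- list(variable_spec("u", c(length = 1), "independent"),
                variable_spec("m", c(mass = 1), "dependent"))
  expect_error(construct_pi_basis(specs), "cannot be nondimensionalized")
  # role-count validation
  expect_error(construct_pi_basis(list(variable_spec("u", c(length = 1)))),
               "exactly one")
})

test_that("planted null spaces are recovered exactly", {
  # build variable dimensions as integer combinations of 3 generator rows:
  # the null space then has dimension n - rank(generators' image)
  for (seed in 1:10) {
    set.seed(seed)
    G <- matrix(sample(-2:2, 12, replace = TRUE), nrow = 3)  # 3 x 4 dims
    C <- matrix(sample(-2:2, 18, replace = TRUE), nrow = 3)  # coeffs, 6 vars
    D <- t(C) %*% G                                          # 6 x 4 dim rows
    specs <- lapply(1:6, function(i) {
      d <- stats::setNames(D[i, ], base_dimensions())
      variable_spec(paste0("w", i), d[d != 0], "independent")
    })
    dm <- build_dimensional_matrix(specs)
    ns <- rational_nullspace(dm)
    expect_length(ns, 6 - qr(D)$rank)
    # planted span: the float null space of t(D); compare spans
    if (length(ns) > 0) {
      got <- do.call(rbind, lapply(ns, as.numeric))
      planted <- t(MASS::Null(D))
      expect_equal(qr(rbind(got, planted))$rank, qr(got)$rank)
    }
  }
})

test_that("evaluate_pi computes exact power products", {
  basis <- construct_pi_basis(biofilter_variables())
  tab <- tiny_table(5)
  tab$P <- tab$C_fit  # force P/C_fit == 1
  f <- evaluate_pi(basis, tab)
  expect_equal(f[["P/C_fit"]], rep(1, 5))

  ones <- tab[1, ]
  for (s in c("T", "Pz", "A", "IC_org", "EC_org", "Bt", "P", "C_fit", "t0"))
    ones[[s]] <- 1
  f1 <- evaluate_pi(basis, ones)
  expect_true(all(unlist(f1) == 1))

  # independent per-term product oracle on a random positive row
  set.seed(3)
  row <- tab[2, ]
  f2 <- evaluate_pi(basis, row)
  for (g in c(basis$independent, list(basis$dependent))) {
    oracle <- prod(vapply(seq_along(g$num), function(i)
      row[[names(g$num)[i]]]^(g$num[i] / g$den[i]), numeric(1)))
    expect_equal(f2[[g$label]], oracle, tolerance = 1e-12)
  }
})

test_that("evaluate_pi rejects non-positive values with row and symbol", {
  basis <- construct_pi_basis(biofilter_variables())
  tab <- tiny_table(4)
  tab$Bt[3] <- -1
  expect_error(evaluate_pi(basis, tab), "Bt.*row 3|row 3.*Bt")
  tab2 <- tiny_table(4)
  tab2$Pz <- NULL
  expect_error(evaluate_pi(basis, tab2), "Pz")
})

test_that("check_dimensionless is exact and true for all emitted groups", {
  specs <- biofilter_variables()
  expect_true(check_dimensionless(
    pi_group(c(Pz = 1, C_fit = -1)), specs))
  expect_false(check_dimensionless(
    pi_group(c(Bt = 1, Pz = -1)), specs))
  expect_error(check_dimensionless(pi_group(c(nope = 1)), specs),
               "unknown symbol")
  basis <- construct_pi_basis(specs)
  for (g in c(basis$independent, list(basis$dependent)))
    expect_true(check_dimensionless(g, specs))
})

test_that("pi values are invariant to consistent unit changes", {
  basis <- construct_pi_basis(biofilter_variables())
  tab <- tiny_table(8)
  f0 <- evaluate_pi(basis, tab)
  scaled <- tab
  for (s in c("Pz", "P", "C_fit")) scaled[[s]] <- scaled[[s]] * 1000
  f1 <- evaluate_pi(basis, scaled)
  for (nm in names(f0)) expect_equal(f1[[nm]], f0[[nm]], tolerance = 1e-12)

  # scaling one column by c multiplies pi by c^exponent
  one <- tab
  one$Bt <- one$Bt * 7
  f2 <- evaluate_pi(basis, one)
  expect_equal(f2[["Bt/A"]], f0[["Bt/A"]] * 7, tolerance = 1e-12)
  expect_equal(f2[["P/C_fit"]], f0[["P/C_fit"]], tolerance = 1e-12)
})

test_that("fractional dimension exponents stay exact rationals", {
  s <- variable_spec("h", c(length = "1/2", time = "-3/2"))
  expect_equal(unname(s$dim_num[c("length", "time")]), c(1, -3))
  expect_equal(unname(s$dim_den[c("length", "time")]), c(2, 2))
  expect_error(variable_spec("bad", c(length = 0.5)), "strings")
  # sqrt(length) and length combine into a dimensionless group
  specs <- list(variable_spec("r", c(length = "1/2"), "independent"),
                variable_spec("l", c(length = 1), "independent"),
                variable_spec("q", c(), "dependent"))
  basis <- construct_pi_basis(specs)
  expect_length(basis$independent, 1)
  expect_true(check_dimensionless(basis$independent[[1]], specs))
})
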