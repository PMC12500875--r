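#' Base dimensions used by the dimensional system
#'
#' The package works in a fixed, ordered four-dimensional system:
#' mass, length, time and temperature.  Every variable's dimension vector
#' has exactly one exponent per base dimension.
#'
#' @return Character vector of the four base dimension names, in order.
#' @export
base_dimensions <- function() c("mass", "length", "time", "temperature")

#' Define a physical variable
#'
#' A variable specification carries a symbol, its dimension exponents
#' (exact rationals), its role in the model, and unit metadata used on
#' ingest.  Exponents may be integers or strings such as \code{"1/2"};
#' floating-point fractions are rejected so that the downstream linear
#' algebra stays exact.
#'
#' @param symbol Short name, e.g. \code{"Pz"}.
#' @param dims Named vector of dimension exponents over
#'   \code{\link{base_dimensions}}; unnamed dimensions default to 0.
#'   Integers, or strings like \code{"1/2"} for non-integer exponents.
#' @param role \code{"independent"} or \code{"dependent"}.
#' @param description Free-text description.
#' @param unit Canonical (SI) unit string, informational.
#' @param convert_factor,convert_offset Affine map from the input unit in
#'   data files to the canonical unit: \code{canonical = factor * x + offset}
#'   (offset is needed for Celsius to kelvin).
#' @return An object of class \code{variable_spec}.
#' @export
variable_spec <- function(symbol, dims, role = c("independent", "dependent"),
                          description = "", unit = "",
                          convert_factor = 1, convert_offset = 0) {
  role <- match.arg(role)
  stopifnot(is.character(symbol), length(symbol) == 1, nzchar(symbol))
  bd <- base_dimensions()
  if (is.null(names(dims)) && length(dims) > 0)
    stop("dims must be a named vector over ", paste(bd, collapse = ", "))
  unknown <- setdiff(names(dims), bd)
  if (length(unknown) > 0)
    stop("unknown base dimension(s): ", paste(unknown, collapse = ", "))
  num <- stats::setNames(rep(0, length(bd)), bd)
  den <- stats::setNames(rep(1, length(bd)), bd)
  if (length(dims) > 0) {
    r <- .rat_parse(dims)
    num[names(dims)] <- r$num
    den[names(dims)] <- r$den
  }
  structure(list(symbol = symbol, description = description,
                 dim_num = num, dim_den = den, role = role, unit = unit,
                 convert_factor = convert_factor,
                 convert_offset = convert_offset),
            class = "variable_spec")
}

#' @export
print.variable_spec <- function(x, ...) {
  d <- .dims_label(x$dim_num, x$dim_den)
  cat(sprintf("<variable_spec> %s (%s): [%s] %s\n", x$symbol, x$role,
              if (nzchar(d)) d else "dimensionless", x$unit))
  invisible(x)
}

.dims_label <- function(num, den) {
  nz <- which(num != 0)
  if (length(nz) == 0) return("")
  paste(vapply(nz, function(i) {
    e <- if (den[i] == 1) as.character(num[i]) else paste0(num[i], "/", den[i])
    paste0(names(num)[i], "^", e)
  }, character(1)), collapse = " ")
}

#' The nine biofilter variables
#'
#' Returns the variable system for the granular activated carbon (GAC)
#' drinking-water biofilter problem: eight independent variables and the
#' dependent effluent organic carbon concentration.  Reference variables
#' (influent concentration, filter bed diameter, filter age, water
#' temperature) are listed first so that the canonical null-space basis
#' pairs each remaining variable with its natural reference, yielding the
#' ratios Pz/C_fit, Bt/A, P/C_fit and t0/T.
#'
#' Input units assumed by the default conversions: temperatures in degrees
#' Celsius, lengths in millimetres, ages in days, contact times in hours,
#' concentrations in mg/L.  Canonical units: m, s, K, and g/m^3 for
#' concentrations (numerically identical to mg/L, the field's reporting
#' unit).
#'
#' @return List of \code{\link{variable_spec}} objects.
#' @export
biofilter_variables <- function() {
  list(
    variable_spec("IC_org", c(mass = 1, length = -3), "independent",
                  "influent organic carbon concentration", "g/m^3"),
    variable_spec("C_fit", c(length = 1), "independent",
                  "filter bed diameter", "m", convert_factor = 1e-3),
    variable_spec("A", c(time = 1), "independent",
                  "filter age since start of operation", "s",
                  convert_factor = 86400),
    variable_spec("T", c(temperature = 1), "independent",
                  "water temperature at the sample location", "K",
                  convert_offset = 273.15),
    variable_spec("Pz", c(length = 1), "independent",
                  "characteristic pore size of the filter medium", "m",
                  convert_factor = 1e-3),
    variable_spec("Bt", c(time = 1), "independent",
                  "empty bed contact time", "s", convert_factor = 3600),
    variable_spec("P", c(length = 1), "independent",
                  "mean GAC particle diameter", "m", convert_factor = 1e-3),
    variable_spec("t0", c(temperature = 1), "independent",
                  "ambient air temperature", "K", convert_offset = 273.15),
    variable_spec("EC_org", c(mass = 1, length = -3), "dependent",
                  "effluent organic carbon concentration", "g/m^3")
  )
}

#' Build the dimensional matrix of a variable system
#'
#' Rows are indexed by the base dimensions, columns by the variable symbols
#' in input order; entries are the exact rational dimension exponents.
#'
#' @param specs List of \code{\link{variable_spec}} objects with unique
#'   symbols.
#' @return Object of class \code{dim_matrix} with components \code{num},
#'   \code{den} (4 x n exact integer matrices), \code{symbols} and
#'   \code{dimensions}.
#' @export
build_dimensional_matrix <- function(specs) {
  if (length(specs) == 0) stop("specs must be non-empty")
  syms <- vapply(specs, function(s) s$symbol, character(1))
  dup <- syms[duplicated(syms)]
  if (length(dup) > 0)
    stop("duplicate variable symbol(s): ", paste(unique(dup), collapse = ", "))
  bd <- base_dimensions()
  num <- matrix(0, nrow = length(bd), ncol = length(specs),
                dimnames = list(bd, syms))
  den <- matrix(1, nrow = length(bd), ncol = length(specs),
                dimnames = list(bd, syms))
  for (j in seq_along(specs)) {
    num[, j] <- specs[[j]]$dim_num[bd]
    den[, j] <- specs[[j]]$dim_den[bd]
  }
  structure(list(num = num, den = den, symbols = syms, dimensions = bd),
            class = "dim_matrix")
}

#' @export
print.dim_matrix <- function(x, ...) {
  m <- matrix(paste0(x$num, ifelse(x$den == 1, "", paste0("/", x$den))),
              nrow = nrow(x$num), dimnames = dimnames(x$num))
  cat("<dim_matrix>", nrow(m), "dimensions x", ncol(m), "variables\n")
  print(m, quote = FALSE)
  invisible(x)
}

#' Rank of a dimensional matrix (exact)
#'
#' @param matrix A \code{dim_matrix}.
#' @return Integer rank computed by exact rational row reduction.
#' @export
dim_matrix_rank <- function(matrix) {
  stopifnot(inherits(matrix, "dim_matrix"))
  .rref_rat(matrix$num, matrix$den)$rank
}

#' Exact rational null space of a dimensional matrix
#'
#' Computes a basis of the right null space with exact rational arithmetic,
#' canonicalized so each basis vector has integer entries with overall gcd 1
#' and a distinguished (free) variable with positive exponent.  The number
#' of vectors equals \code{ncol - rank} (the n - m rule of dimensional
#' analysis).
#'
#' @param matrix A \code{dim_matrix}.
#' @return List of named integer exponent vectors (possibly empty), one per
#'   null-space basis vector, with attribute \code{"free_symbol"} naming the
#'   distinguished variable.
#' @export
rational_nullspace <- function(matrix) {
  stopifnot(inherits(matrix, "dim_matrix"))
  rr <- .rref_rat(matrix$num, matrix$den)
  nc <- ncol(matrix$num)
  free <- setdiff(seq_len(nc), rr$pivots)
  basis <- vector("list", length(free))
  for (k in seq_along(free)) {
    f <- free[k]
    xn <- rep(0, nc); xd <- rep(1, nc)
    xn[f] <- 1
    for (r in seq_along(rr$pivots)) {
      p <- rr$pivots[r]
      xn[p] <- -rr$num[r, f]
      xd[p] <- rr$den[r, f]
    }
    v <- .rat_canonical_int(xn, xd, anchor = f)
    names(v) <- matrix$symbols
    attr(v, "free_symbol") <- matrix$symbols[f]
    basis[[k]] <- v
  }
  basis
}

#' A dimensionless power product of variables
#'
#' @param exponents Named vector mapping variable symbols to exact
#'   exponents (numerators; paired with \code{den} for rationals).
#' @param den Optional named vector of denominators (defaults to 1).
#' @return Object of class \code{pi_group} with a human-readable label
#'   such as \code{"Pz/C_fit"}.
#' @export
pi_group <- function(exponents, den = NULL) {
  stopifnot(!is.null(names(exponents)))
  if (is.null(den)) den <- stats::setNames(rep(1, length(exponents)),
                                           names(exponents))
  keep <- exponents != 0
  exponents <- exponents[keep]; den <- den[keep]
  structure(list(num = exponents, den = den,
                 label = .pi_label(exponents, den)),
            class = "pi_group")
}

.pi_label <- function(num, den) {
  fmt1 <- function(sym, n, d) {
    e <- abs(n)
    if (d == 1 && e == 1) sym
    else if (d == 1) paste0(sym, "^", e)
    else paste0(sym, "^(", e, "/", d, ")")
  }
  pos <- which(num > 0); neg <- which(num < 0)
  top <- if (length(pos)) paste(mapply(fmt1, names(num)[pos], num[pos],
                                       den[pos]), collapse = "*") else "1"
  if (length(neg) == 0) return(top)
  bot <- paste(mapply(fmt1, names(num)[neg], num[neg], den[neg]),
               collapse = "*")
  if (length(neg) > 1) bot <- paste0("(", bot, ")")
  paste0(top, "/", bot)
}

#' @export
print.pi_group <- function(x, ...) {
  cat("<pi_group>", x$label, "\n")
  invisible(x)
}

#' Verify that a power product is dimensionless
#'
#' Sums the dimension exponents of the group's variables, weighted by the
#' group exponents, in exact rational arithmetic; returns \code{TRUE} iff
#' every base-dimension total is exactly zero.
#'
#' @param group A \code{\link{pi_group}}.
#' @param specs The variable system the group is defined over.
#' @return Logical scalar.
#' @export
check_dimensionless <- function(group, specs) {
  stopifnot(inherits(group, "pi_group"))
  syms <- vapply(specs, function(s) s$symbol, character(1))
  unknown <- setdiff(names(group$num), syms)
  if (length(unknown) > 0)
    stop("unknown symbol(s) in pi group: ", paste(unknown, collapse = ", "))
  bd <- base_dimensions()
  tot_n <- rep(0, length(bd)); tot_d <- rep(1, length(bd))
  for (i in seq_along(group$num)) {
    sp <- specs[[match(names(group$num)[i], syms)]]
    term <- .rat_mul(sp$dim_num[bd], sp$dim_den[bd],
                     rep(group$num[i], length(bd)),
                     rep(group$den[i], length(bd)))
    acc <- .rat_add(tot_n, tot_d, term$num, term$den)
    tot_n <- acc$num; tot_d <- acc$den
  }
  all(tot_n == 0)
}

#' Construct the pi-group basis of a variable system
#'
#' Independent groups are the canonicalized exact null-space basis of the
#' independent-variable dimensional matrix: one group per free variable,
#' each with integer exponents of gcd 1 and the free variable raised to a
#' positive power, ordered by the free variables' input order.  The
#' dependent group nondimensionalizes the dependent variable by a power
#' product of independent variables, preferring a single matching variable
#' (for the biofilter system this resolves to EC_org/IC_org).
#'
#' @param specs List of \code{\link{variable_spec}}; exactly one must have
#'   role \code{"dependent"}.
#' @return Object of class \code{pi_basis}: list with \code{independent}
#'   (list of \code{pi_group}) and \code{dependent} (one \code{pi_group}).
#' @export
construct_pi_basis <- function(specs) {
  roles <- vapply(specs, function(s) s$role, character(1))
  if (sum(roles == "dependent") != 1)
    stop("exactly one variable must have role 'dependent' (found ",
         sum(roles == "dependent"), ")")
  indep <- specs[roles == "independent"]
  dep <- specs[[which(roles == "dependent")]]
  A <- build_dimensional_matrix(indep)
  null_basis <- rational_nullspace(A)
  groups <- lapply(null_basis, function(v) pi_group(v[v != 0]))

  dep_grp <- .nondimensionalize_dependent(A, dep)
  structure(list(independent = groups, dependent = dep_grp, specs = specs),
            class = "pi_basis")
}

# Solve A x = d exactly for the dependent variable's dimension vector d,
# preferring a single independent variable whose dimensions are an exact
# rational multiple of d; otherwise take the particular solution of the
# augmented RREF with all free variables set to zero.
.nondimensionalize_dependent <- function(A, dep) {
  bd <- base_dimensions()
  dn <- dep$dim_num[bd]; dd <- dep$dim_den[bd]
  if (all(dn == 0)) {
    g <- stats::setNames(1, dep$symbol)
    return(pi_group(g))
  }
  # single-variable match: A[,j] * s == d for a rational scalar s
  for (j in seq_len(ncol(A$num))) {
    cn <- A$num[, j]; cd <- A$den[, j]
    nz <- which(cn != 0)
    if (length(nz) == 0) next
    if (!setequal(nz, which(dn != 0))) next
    # candidate scalar from the first nonzero entry: s = (d/c) there
    i <- nz[1]
    s <- .rat_reduce(dn[i] * cd[i], dd[i] * cn[i])
    prod <- .rat_mul(cn, cd, rep(s$num, length(bd)), rep(s$den, length(bd)))
    if (all(prod$num == dn & prod$den == dd)) {
      num <- c(1, -s$num); den <- c(1, s$den)
      names(num) <- names(den) <- c(dep$symbol, A$symbols[j])
      return(pi_group(num, den))
    }
  }
  # general exact solve on the augmented matrix [A | d]
  aug_n <- cbind(A$num, dn); aug_d <- cbind(A$den, dd)
  rr <- .rref_rat(aug_n, aug_d)
  if ((ncol(A$num) + 1) %in% rr$pivots)
    stop("dependent variable '", dep$symbol,
         "' cannot be nondimensionalized by the independent variables ",
         "(its dimensions lie outside their span)")
  nvar <- ncol(A$num)
  xn <- rep(0, nvar); xd <- rep(1, nvar)
  for (r in seq_along(rr$pivots)) {
    p <- rr$pivots[r]
    xn[p] <- rr$num[r, nvar + 1]
    xd[p] <- rr$den[r, nvar + 1]
  }
  num <- c(1, -xn); den <- c(1, xd)
  names(num) <- names(den) <- c(dep$symbol, A$symbols)
  pi_group(num, den)
}

#' @export
print.pi_basis <- function(x, ...) {
  cat("<pi_basis>", length(x$independent), "independent group(s)\n")
  for (g in x$independent) cat("  ", g$label, "\n")
  cat("  dependent:", x$dependent$label, "\n")
  invisible(x)
}

#' Exponent table of a pi basis
#'
#' @param basis A \code{\link{pi_basis}}.
#' @return Data frame with one row per group (dependent last) and one
#'   column per variable symbol, holding numeric exponents.
#' @export
pi_basis_table <- function(basis) {
  stopifnot(inherits(basis, "pi_basis"))
  syms <- vapply(basis$specs, function(s) s$symbol, character(1))
  groups <- c(basis$independent, list(basis$dependent))
  tab <- matrix(0, nrow = length(groups), ncol = length(syms),
                dimnames = list(vapply(groups, function(g) g$label,
                                       character(1)), syms))
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    tab[i, names(g$num)] <- g$num / g$den
  }
  df <- data.frame(group = rownames(tab),
                   role = c(rep("independent", length(basis$independent)),
                            "dependent"),
                   tab, check.names = FALSE, row.names = NULL)
  df
}

#' Evaluate pi-group features on an observation table
#'
#' Computes the power product of each group for every row.  All variable
#' values must be strictly positive (temperatures in kelvin): fractional
#' powers and downstream logarithms are undefined otherwise.
#'
#' @param basis A \code{\link{pi_basis}}.
#' @param table Data frame with one column per variable symbol used by the
#'   basis, values in canonical units.
#' @return Data frame with one column per independent group (named by
#'   label) plus the dependent group, and attribute
#'   \code{"independent_labels"}.
#' @export
evaluate_pi <- function(basis, table) {
  stopifnot(inherits(basis, "pi_basis"))
  groups <- c(basis$independent, list(basis$dependent))
  syms <- unique(unlist(lapply(groups, function(g) names(g$num))))
  missing_cols <- setdiff(syms, names(table))
  if (length(missing_cols) > 0)
    stop("observation table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  for (s in syms) {
    bad <- which(!is.finite(table[[s]]) | table[[s]] <= 0)
    if (length(bad) > 0)
      stop("non-positive or missing value for '", s, "' in row ", bad[1],
           ": pi groups require strictly positive inputs")
  }
  out <- lapply(groups, function(g) {
    acc <- rep(1, nrow(table))
    for (i in seq_along(g$num))
      acc <- acc * table[[names(g$num)[i]]]^(g$num[i] / g$den[i])
    acc
  })
  labels <- vapply(groups, function(g) g$label, character(1))
  res <- as.data.frame(stats::setNames(out, labels), check.names = FALSE)
  attr(res, "independent_labels") <- labels[seq_along(basis$independent)]
  attr(res, "dependent_label") <- labels[length(labels)]
  res
}
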