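# Exact rational arithmetic on small matrices.
#
# Null spaces of dimensional matrices must be computed exactly: the entries
# are small integers (or simple fractions) and a floating-point elimination
# can turn a structural zero into 1e-16, changing the rank.  Numerators and
# denominators are stored as doubles holding exact integers; all magnitudes
# involved here stay far below 2^53.

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) {
    r <- a %% b
    a <- b
    b <- r
  }
  a
}

.gcd_vec <- function(x) {
  g <- 0
  for (v in x) g <- .gcd2(g, v)
  g
}

.lcm2 <- function(a, b) {
  if (a == 0 || b == 0) return(0)
  abs(a / .gcd2(a, b) * b)
}

# Reduce num/den pairs to lowest terms with den > 0.
.rat_reduce <- function(num, den) {
  if (any(den == 0)) stop("zero denominator in rational value")
  sgn <- ifelse(den < 0, -1, 1)
  num <- num * sgn
  den <- den * sgn
  for (i in seq_along(num)) {
    if (num[i] == 0) {
      den[i] <- 1
    } else {
      g <- .gcd2(num[i], den[i])
      num[i] <- num[i] / g
      den[i] <- den[i] / g
    }
  }
  list(num = num, den = den)
}

# Parse rational scalars given as numbers (must be integral) or "p/q" strings.
.rat_parse <- function(x) {
  if (is.character(x)) {
    out <- lapply(x, function(s) {
      s <- trimws(s)
      if (grepl("/", s, fixed = TRUE)) {
        parts <- strsplit(s, "/", fixed = TRUE)[[1]]
        if (length(parts) != 2) stop("cannot parse rational '", s, "'")
        num <- as.numeric(parts[1]); den <- as.numeric(parts[2])
      } else {
        num <- as.numeric(s); den <- 1
      }
      if (is.na(num) || is.na(den) || num != round(num) || den != round(den))
        stop("cannot parse rational '", s, "'")
      c(num, den)
    })
    num <- vapply(out, `[`, numeric(1), 1)
    den <- vapply(out, `[`, numeric(1), 2)
  } else {
    if (any(x != round(x)))
      stop("non-integer dimension exponents must be given as strings like \"1/2\"")
    num <- as.numeric(x)
    den <- rep(1, length(x))
  }
  .rat_reduce(num, den)
}

# a/b + c/d and (a/b)*(c/d), elementwise, reduced.
.rat_add <- function(an, ad, bn, bd) .rat_reduce(an * bd + bn * ad, ad * bd)
.rat_mul <- function(an, ad, bn, bd) .rat_reduce(an * bn, ad * bd)

# Reduced row echelon form of a rational matrix given as num/den matrices.
# Returns the reduced matrices, the pivot column indices and the rank.
.rref_rat <- function(num, den) {
  nr <- nrow(num); nc <- ncol(num)
  pivots <- integer(0)
  row <- 1
  for (col in seq_len(nc)) {
    if (row > nr) break
    pr <- which(num[row:nr, col] != 0)
    if (length(pr) == 0) next
    pr <- pr[1] + row - 1
    if (pr != row) {
      num[c(row, pr), ] <- num[c(pr, row), ]
      den[c(row, pr), ] <- den[c(pr, row), ]
    }
    # scale pivot row to make the pivot exactly 1
    pn <- num[row, col]; pd <- den[row, col]
    sc <- .rat_mul(num[row, ], den[row, ], rep(pd, nc), rep(pn, nc))
    num[row, ] <- sc$num; den[row, ] <- sc$den
    for (r in seq_len(nr)) {
      if (r == row || num[r, col] == 0) next
      f_n <- num[r, col]; f_d <- den[r, col]
      sub <- .rat_mul(num[row, ], den[row, ], rep(-f_n, nc), rep(f_d, nc))
      upd <- .rat_add(num[r, ], den[r, ], sub$num, sub$den)
      num[r, ] <- upd$num; den[r, ] <- upd$den
    }
    pivots <- c(pivots, col)
    row <- row + 1
  }
  list(num = num, den = den, pivots = pivots, rank = length(pivots))
}

# Clear denominators and divide by the gcd, keeping entry `anchor` positive.
# Input/output are parallel num/den vectors; output has den == 1 throughout.
.rat_canonical_int <- function(num, den, anchor = NULL) {
  L <- 1
  for (d in den) L <- .lcm2(L, d)
  ints <- num * (L / den)
  g <- .gcd_vec(ints)
  if (g > 0) ints <- ints / g
  if (!is.null(anchor) && ints[anchor] < 0) ints <- -ints
  ints
}
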