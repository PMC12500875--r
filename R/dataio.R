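#' Read a units/dimensions configuration
#'
#' The YAML config declares, per variable symbol: role, dimension exponents,
#' canonical unit and the affine input-unit conversion
#' (\code{canonical = factor * value + offset}).  A reference config for the
#' biofilter system ships with the package
#' (\code{system.file("extdata", "biofilter_units.yaml", package = "buckpi")}).
#'
#' @param path Path to a YAML file.
#' @return List of \code{\link{variable_spec}} objects.
#' @export
read_units_config <- function(path) {
  if (!file.exists(path)) stop("units config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$variables)) stop("units config has no 'variables' section")
  lapply(names(cfg$variables), function(sym) {
    v <- cfg$variables[[sym]]
    dims <- unlist(v$dims)
    if (is.null(dims)) dims <- stats::setNames(numeric(0), character(0))
    variable_spec(symbol = sym,
                  dims = dims,
                  role = if (is.null(v$role)) "independent" else v$role,
                  description = if (is.null(v$description)) "" else v$description,
                  unit = if (is.null(v$unit)) "" else v$unit,
                  convert_factor = if (is.null(v$convert$factor)) 1 else v$convert$factor,
                  convert_offset = if (is.null(v$convert$offset)) 0 else v$convert$offset)
  })
}

#' Write a units/dimensions configuration
#'
#' @param specs List of \code{\link{variable_spec}} objects.
#' @param path Output YAML path.
#' @return \code{path}, invisibly.
#' @export
write_units_config <- function(specs, path) {
  vars <- lapply(specs, function(s) {
    nz <- which(s$dim_num != 0)
    dims <- lapply(nz, function(i) {
      if (s$dim_den[i] == 1) s$dim_num[[i]]
      else paste0(s$dim_num[i], "/", s$dim_den[i])
    })
    names(dims) <- names(s$dim_num)[nz]
    list(role = s$role, description = s$description, unit = s$unit,
         dims = dims,
         convert = list(factor = s$convert_factor, offset = s$convert_offset))
  })
  names(vars) <- vapply(specs, function(s) s$symbol, character(1))
  yaml::write_yaml(list(variables = vars), path)
  invisible(path)
}

.variable_symbols <- function(specs)
  vapply(specs, function(s) s$symbol, character(1))

#' Read biofilter observations from CSV
#'
#' Reads a header-row CSV, maps columns onto the configured variable
#' symbols, and converts each variable to canonical units using the
#' config's affine conversion.  Unparseable cells become \code{NA} and are
#' kept until \code{\link{drop_incomplete}}.  Metadata columns
#' \code{study_id} and \code{sample_time} are carried through untouched.
#'
#' @param path CSV path.
#' @param units_config List of \code{\link{variable_spec}} (e.g. from
#'   \code{\link{read_units_config}} or \code{\link{biofilter_variables}}).
#' @param converted Set \code{TRUE} if the file already holds canonical
#'   units (e.g. it was written by \code{\link{write_observations}});
#'   conversions are then skipped.
#' @return Data frame in canonical units, row order preserved, with
#'   attribute \code{"units"} = "canonical".
#' @export
read_observations <- function(path, units_config, converted = FALSE) {
  if (!file.exists(path)) stop("observation file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  syms <- .variable_symbols(units_config)
  meta <- intersect(c("study_id", "sample_time"), names(raw))
  known <- intersect(names(raw), c(syms, meta))
  if (length(intersect(names(raw), syms)) == 0)
    stop("no recognizable variable columns in ", path,
         " (expected some of: ", paste(syms, collapse = ", "), ")")
  unknown <- setdiff(names(raw), c(syms, meta))
  if (length(unknown) > 0)
    stop("unknown column(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  out <- raw[, known, drop = FALSE]
  for (s in intersect(syms, names(out))) {
    v <- suppressWarnings(as.numeric(out[[s]]))
    if (!converted) {
      sp <- units_config[[match(s, syms)]]
      v <- sp$convert_factor * v + sp$convert_offset
    }
    out[[s]] <- v
  }
  attr(out, "units") <- "canonical"
  out
}

#' Write observations to CSV (canonical units)
#'
#' @param table Observation data frame in canonical units.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_observations <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Drop rows with missing or non-positive variable values
#'
#' Retains only rows where every configured variable is present and
#' strictly positive (positivity is required by the log/pi transforms).
#' No imputation is performed.
#'
#' @param table Observation data frame.
#' @param symbols Variable columns to require; defaults to all numeric
#'   non-metadata columns.
#' @return List with \code{table} (the filtered rows) and
#'   \code{dropped_count}.
#' @export
drop_incomplete <- function(table, symbols = NULL) {
  if (is.null(symbols))
    symbols <- setdiff(names(table), c("study_id", "sample_time"))
  ok <- rep(TRUE, nrow(table))
  for (s in symbols) {
    v <- table[[s]]
    ok <- ok & !is.na(v) & is.finite(v) & v > 0
  }
  dropped <- sum(!ok)
  if (dropped == nrow(table))
    stop("all ", nrow(table), " rows dropped as incomplete; ",
         "no data left for analysis")
  list(table = table[ok, , drop = FALSE], dropped_count = dropped)
}

#' Study-based train/test split with a training quota
#'
#' All test rows come from one held-out study; optionally a seeded random
#' sample of \code{train_quota} rows from that study is moved into the
#' training set (mirroring multi-study protocols where part of the held-out
#' study's data is used for training).
#'
#' @param table Observation data frame with a \code{study_id} column.
#' @param holdout_study Study identifier to hold out.
#' @param train_quota Number of held-out-study rows moved to training.
#' @param seed Integer seed for the quota sample.
#' @return List with \code{train} and \code{test} data frames and a
#'   \code{manifest} of row indices per partition.
#' @export
split_by_study <- function(table, holdout_study, train_quota = 0, seed = 1) {
  if (!"study_id" %in% names(table))
    stop("table has no 'study_id' column")
  idx_hold <- which(table$study_id == holdout_study)
  if (length(idx_hold) == 0)
    stop("held-out study '", holdout_study, "' not present")
  if (train_quota > length(idx_hold))
    stop("train_quota (", train_quota, ") exceeds held-out study size (",
         length(idx_hold), ")")
  set.seed(seed)
  moved <- if (train_quota > 0) sort(sample(idx_hold, train_quota)) else integer(0)
  idx_test <- setdiff(idx_hold, moved)
  idx_train <- sort(c(setdiff(seq_len(nrow(table)), idx_hold), moved))
  list(train = table[idx_train, , drop = FALSE],
       test = table[idx_test, , drop = FALSE],
       manifest = list(holdout_study = holdout_study,
                       train_quota = train_quota, seed = seed,
                       train_rows = idx_train, test_rows = idx_test))
}

#' Fit a feature standardizer on training data
#'
#' Per-column location/scale with the population standard deviation
#' (divide by n), so the transformed training set has exactly zero mean
#' and unit variance under that convention.
#'
#' @param features Numeric data frame or matrix (training features only).
#' @return Object of class \code{standardizer}.
#' @export
fit_standardizer <- function(features) {
  X <- as.matrix(features)
  if (nrow(X) < 2) stop("need at least 2 rows to fit a standardizer")
  mu <- colMeans(X)
  sd_pop <- sqrt(colMeans(sweep(X, 2, mu)^2))
  zero <- which(sd_pop == 0)
  if (length(zero) > 0)
    stop("zero-variance column(s): ",
         paste(colnames(X)[zero], collapse = ", "))
  structure(list(mean = mu, sd = sd_pop, columns = colnames(X)),
            class = "standardizer")
}

#' Apply (or invert) a fitted standardizer
#'
#' @param std A \code{standardizer} from \code{\link{fit_standardizer}}.
#' @param features Features to transform; columns matched by name when
#'   named.
#' @param invert If \code{TRUE}, maps standardized values back to the
#'   original scale.
#' @return Matrix of transformed features.
#' @export
apply_standardizer <- function(std, features, invert = FALSE) {
  stopifnot(inherits(std, "standardizer"))
  X <- as.matrix(features)
  if (!is.null(colnames(X)) && !is.null(std$columns)) {
    missing_cols <- setdiff(std$columns, colnames(X))
    if (length(missing_cols) > 0)
      stop("features lack column(s): ", paste(missing_cols, collapse = ", "))
    X <- X[, std$columns, drop = FALSE]
  }
  if (invert) sweep(sweep(X, 2, std$sd, "*"), 2, std$mean, "+")
  else sweep(sweep(X, 2, std$mean), 2, std$sd, "/")
}
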