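#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum_i (y_i-\hat y_i)^2 / \sum_i (y_i-\bar y)^2}.  May be
#' negative when the model fits worse than the mean.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @return R-squared.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted differ in length")
  if (length(observed) < 2) stop("need at least 2 observations")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observed values are constant; R^2 undefined")
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Symmetric mean absolute percentage error
#'
#' \eqn{(100/n) \sum_i |y_i - Y_i| / (|y_i| + |Y_i|)} — the variant without
#' the conventional factor of 2, so the result is bounded by 100.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return sMAPE in percent, in \code{[0, 100]}.
#' @export
smape <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted differ in length")
  den <- abs(observed) + abs(predicted)
  bad <- which(den == 0)
  if (length(bad) > 0)
    stop("zero |observed| + |predicted| in row ", bad[1],
         "; sMAPE undefined there")
  100 * mean(abs(observed - predicted) / den)
}

#' Pearson correlation with two-sided p-value
#'
#' @param observed,predicted Non-constant numeric vectors (>= 3 pairs).
#' @return List with \code{r} and \code{p_value} (t-transform, two-sided).
#' @export
pearson_r <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted differ in length")
  if (length(observed) < 3) stop("need at least 3 pairs")
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0)
    stop("constant vector; correlation undefined")
  ct <- stats::cor.test(observed, predicted, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Aggregate a metric across seeds
#'
#' Arithmetic mean plus population standard deviation (divide by n); the
#' SD is \code{NA} for a single seed, matching the convention of reporting
#' a dispersion only for stochastic (multi-seed) models.
#'
#' @param values Numeric vector of per-seed metric values.
#' @return List with \code{mean}, \code{sd} and \code{n}.
#' @export
aggregate_seeds <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("no values to aggregate")
  m <- mean(values)
  s <- if (length(values) > 1) sqrt(mean((values - m)^2)) else NA_real_
  list(mean = m, sd = s, n = length(values))
}

#' Assemble the reducer-by-regressor comparison table
#'
#' Arranges evaluation rows into the canonical grid: reducers BP, PCA,
#' KPCA, Autoencoder crossed with model families NN, LR, GBR, RFR, SVR,
#' for the training and testing splits and metrics \code{r2} and
#' \code{smape}.  Missing combinations render as \code{NA}, never silently
#' dropped.
#'
#' @param report Data frame with columns \code{reducer}, \code{model},
#'   \code{split}, \code{metric}, \code{mean}, \code{sd} (e.g. from
#'   \code{\link{run_comparison}}).
#' @param metric Which metric to tabulate: \code{"r2"} or \code{"smape"}.
#' @return Data frame: one row per reducer-model pair in canonical order,
#'   columns \code{training} and \code{testing} holding formatted values
#'   (SD in parentheses when present).
#' @export
comparison_table <- function(report, metric = c("r2", "smape")) {
  metric <- match.arg(metric)
  reducers <- c("BP", "PCA", "KPCA", "Autoencoder")
  families <- c("NN", "LR", "GBR", "RFR", "SVR")
  fmt <- function(m, s) {
    if (is.na(m)) return(NA_character_)
    if (!is.na(s)) sprintf("%.3g (%.2g)", m, s) else sprintf("%.3g", m)
  }
  rows <- list()
  for (rd in reducers) for (fam in families) {
    cells <- vapply(c("training", "testing"), function(sp) {
      hit <- report$reducer == rd & report$model == fam &
        report$split == sp & report$metric == metric
      if (!any(hit)) return(NA_character_)
      fmt(report$mean[hit][1], report$sd[hit][1])
    }, character(1))
    rows[[paste(rd, fam, sep = "-")]] <-
      data.frame(algorithm = paste(rd, fam, sep = "-"),
                 training = cells[1], testing = cells[2],
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a comparison table as aligned text
#'
#' @param table Output of \code{\link{comparison_table}}.
#' @param title Optional heading line.
#' @return Character vector of lines, invisibly; also printed.
#' @export
format_comparison <- function(table, title = NULL) {
  w <- vapply(table, function(col) max(nchar(c(col, "NA")), na.rm = TRUE),
              numeric(1))
  w <- pmax(w, nchar(names(table)))
  line <- function(vals) paste(mapply(formatC, as.character(vals),
                                      width = w), collapse = "  ")
  lines <- c(if (!is.null(title)) title,
             line(names(table)),
             vapply(seq_len(nrow(table)),
                    function(i) line(unlist(table[i, ])), character(1)))
  cat(lines, sep = "\n")
  invisible(lines)
}
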