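#' Fit a PCA reducer
#'
#' Principal component analysis retaining the first \code{k} components.
#' Features are expected to be standardized upstream; the reducer centers
#' on the training means and projects onto the leading orthonormal
#' loading vectors.
#'
#' @param features Training feature matrix/data frame.
#' @param k Number of components (default 4, mirroring the pi-group count).
#' @return Object of class \code{buckpi_reducer} (kind \code{"pca"}).
#' @export
fit_pca <- function(features, k = 4) {
  X <- as.matrix(features)
  r <- qr(sweep(X, 2, colMeans(X)))$rank
  if (k > r)
    stop("k (", k, ") exceeds the feature rank (", r, ")")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  structure(list(kind = "pca", k = k, fit = pc,
                 sdev = pc$sdev[seq_len(k)]),
            class = "buckpi_reducer")
}

#' Fit a kernel PCA reducer (RBF kernel)
#'
#' Kernel principal component analysis with a radial basis function
#' kernel, retaining the first \code{k} kernel components.  The bandwidth
#' defaults to \code{gamma = 1/ncol(features)}, the common default when
#' only "RBF" is specified.
#'
#' @param features Training feature matrix/data frame (standardized
#'   upstream).
#' @param k Number of kernel components.
#' @param gamma RBF bandwidth in \code{exp(-gamma * ||x - y||^2)}.
#' @return Object of class \code{buckpi_reducer} (kind \code{"kpca"}).
#' @export
fit_kpca <- function(features, k = 4, gamma = NULL) {
  X <- as.matrix(features)
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  fit <- kernlab::kpca(X, kernel = "rbfdot", kpar = list(sigma = gamma),
                       features = k)
  structure(list(kind = "kpca", k = k, fit = fit, gamma = gamma),
            class = "buckpi_reducer")
}

#' Fit an autoencoder reducer
#'
#' Symmetric dense autoencoder (input -> 6 -> bottleneck -> 6 -> input)
#' with ReLU hidden units and a linear output, trained by Adam on
#' mean-squared reconstruction error with early stopping on a held-back
#' validation slice.  The bottleneck activations are the reduced features.
#'
#' @param features Training feature matrix/data frame (standardized
#'   upstream).
#' @param bottleneck Latent width (default 4).
#' @param seed Integer seed controlling initialization, shuffling and the
#'   validation slice.
#' @param epochs Maximum training epochs.
#' @param hidden Width of the intermediate encoder/decoder layer.
#' @return Object of class \code{buckpi_reducer} (kind
#'   \code{"autoencoder"}); if training hit the epoch cap without the
#'   validation loss converging, a note is stored in \code{$warning}.
#' @export
fit_autoencoder <- function(features, bottleneck = 4, seed = 0,
                            epochs = 500, hidden = 6) {
  X <- as.matrix(features)
  if (ncol(X) < bottleneck)
    stop("need at least ", bottleneck, " input features")
  set.seed(seed)
  n <- nrow(X)
  n_val <- max(2, round(0.1 * n))
  val_idx <- sample.int(n, n_val)
  net <- .mlp_fit(X[-val_idx, , drop = FALSE], X[-val_idx, , drop = FALSE],
                  hidden = c(hidden, bottleneck, hidden),
                  lr = 1e-3, l2 = 1e-4, epochs = epochs, batch_size = 32,
                  patience = 50,
                  val = list(X = X[val_idx, , drop = FALSE],
                             Y = X[val_idx, , drop = FALSE]),
                  seed = seed)
  warn <- NULL
  if (nrow(net$trace) >= epochs && net$best_epoch >= epochs - 1)
    warn <- "autoencoder hit the epoch cap before validation loss converged"
  structure(list(kind = "autoencoder", k = bottleneck, fit = net,
                 seed = seed, warning = warn),
            class = "buckpi_reducer")
}

#' Transform features with a fitted reducer
#'
#' Deterministic given the fitted state; never re-estimates parameters
#' from the data being transformed.
#'
#' @param reducer A \code{buckpi_reducer}.
#' @param features Features to reduce.
#' @return Matrix with \code{k} columns.
#' @export
transform_features <- function(reducer, features) {
  stopifnot(inherits(reducer, "buckpi_reducer"))
  X <- as.matrix(features)
  out <- switch(reducer$kind,
    pca = stats::predict(reducer$fit, X)[, seq_len(reducer$k), drop = FALSE],
    kpca = kernlab::predict(reducer$fit, X)[, seq_len(reducer$k),
                                            drop = FALSE],
    autoencoder = .mlp_activations(reducer$fit, X, layer = 2),
    stop("unknown reducer kind: ", reducer$kind)
  )
  colnames(out) <- paste0(toupper(reducer$kind), seq_len(ncol(out)))
  out
}

#' Reconstruction error of an autoencoder reducer
#'
#' @param reducer Autoencoder reducer.
#' @param features Features to reconstruct.
#' @return Mean squared reconstruction error.
#' @export
autoencoder_mse <- function(reducer, features) {
  stopifnot(reducer$kind == "autoencoder")
  X <- as.matrix(features)
  .mse(.mlp_predict_mat(reducer$fit, X), X)
}
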