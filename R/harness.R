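#' Run the full reducer-by-regressor comparison
#'
#' Reproduces the benchmarking protocol on a train/test pair: the
#' physics-guided path evaluates the pi-groups and models the log of the
#' dimensionless ratio EC/IC as a function of the standardized log
#' pi-groups (the natural scale of power-product features); predictions
#' are exponentiated and back-transformed to EC_org via the influent
#' concentration before scoring.  The data-driven paths
#' standardize the eight raw independent variables, reduce them to four
#' features with PCA, kernel PCA or an autoencoder, and model EC_org
#' directly.  Model families: the feedforward network (multi-seed), LR
#' (the monomial power law on pi-groups; ordinary least squares on reduced
#' features, which may be negative), gradient boosting, random forest and
#' epsilon-SVR.  All metrics are computed on the dimensional effluent
#' concentration.
#'
#' @param train,test Observation tables in canonical units (e.g. from
#'   \code{\link{split_by_study}}).
#' @param specs Variable system; defaults to
#'   \code{\link{biofilter_variables}}.
#' @param nn_config \code{\link{ffnn_config}} for the network (and its
#'   seed list).
#' @param reducers Subset of \code{c("BP", "PCA", "KPCA", "Autoencoder")}.
#' @param families Subset of \code{c("NN", "LR", "GBR", "RFR", "SVR")}.
#' @param k Reduced dimension for the data-driven reducers.
#' @return Data frame of class \code{evaluation_report} with columns
#'   \code{reducer}, \code{model}, \code{split}, \code{metric},
#'   \code{mean}, \code{sd}, \code{n_seeds}, \code{n_rows}; NN loss traces
#'   are attached as attribute \code{"traces"}.
#' @export
run_comparison <- function(train, test, specs = biofilter_variables(),
                           nn_config = ffnn_config(),
                           reducers = c("BP", "PCA", "KPCA", "Autoencoder"),
                           families = c("NN", "LR", "GBR", "RFR", "SVR"),
                           k = 4) {
  basis <- construct_pi_basis(specs)
  pi_tr <- evaluate_pi(basis, train)
  pi_te <- evaluate_pi(basis, test)
  ind_lab <- attr(pi_tr, "independent_labels")
  dep_lab <- attr(pi_tr, "dependent_label")
  indep_syms <- vapply(Filter(function(s) s$role == "independent", specs),
                       function(s) s$symbol, character(1))

  rows <- list(); traces <- list()
  add <- function(reducer, model, split, metric, agg, n_rows) {
    rows[[length(rows) + 1]] <<- data.frame(
      reducer = reducer, model = model, split = split, metric = metric,
      mean = agg$mean, sd = agg$sd, n_seeds = agg$n, n_rows = n_rows,
      stringsAsFactors = FALSE)
  }
  score_both <- function(reducer, model, pred_tr, pred_te) {
    # pred_* are EC_org predictions: vectors, or matrices with one
    # column per seed
    for (split in c("training", "testing")) {
      pred <- if (split == "training") pred_tr else pred_te
      obs <- if (split == "training") train$EC_org else test$EC_org
      pred <- as.matrix(pred)
      r2 <- apply(pred, 2, function(p) r_squared(obs, p))
      sm <- apply(pred, 2, function(p) smape(obs, p))
      add(reducer, model, split, "r2", aggregate_seeds(r2), length(obs))
      add(reducer, model, split, "smape", aggregate_seeds(sm), length(obs))
    }
  }

  for (rd in reducers) {
    if (rd == "BP") {
      # physics-guided path: everything lives on the log scale, the
      # natural scale of power-product features; predictions are
      # exponentiated and back-transformed before scoring
      Xtr_raw <- log(as.matrix(pi_tr[ind_lab]))
      Xte_raw <- log(as.matrix(pi_te[ind_lab]))
      y_tr <- log(pi_tr[[dep_lab]])
      to_ec <- function(p, split)
        apply(as.matrix(p), 2, function(col)
          back_transform(exp(col),
                         if (split == "tr") train$IC_org else test$IC_org))
    } else {
      std0 <- fit_standardizer(train[indep_syms])
      Ztr <- apply_standardizer(std0, train[indep_syms])
      Zte <- apply_standardizer(std0, test[indep_syms])
      red <- switch(rd,
        PCA = fit_pca(Ztr, k = k),
        KPCA = fit_kpca(Ztr, k = k),
        Autoencoder = fit_autoencoder(Ztr, bottleneck = k,
                                      seed = nn_config$seeds[1]))
      Xtr_raw <- transform_features(red, Ztr)
      Xte_raw <- transform_features(red, Zte)
      y_tr <- train$EC_org
      to_ec <- function(p, split) p
    }
    std <- fit_standardizer(Xtr_raw)
    Xtr <- apply_standardizer(std, Xtr_raw)
    Xte <- apply_standardizer(std, Xte_raw)

    for (fam in families) {
      if (fam == "NN") {
        nn <- train_ffnn(Xtr, y_tr, nn_config)
        traces[[rd]] <- nn$traces
        score_both(rd, fam, to_ec(predict_ffnn(nn, Xtr), "tr"),
                   to_ec(predict_ffnn(nn, Xte), "te"))
      } else if (fam == "LR") {
        if (rd == "BP") {
          m <- fit_monomial(pi_tr[ind_lab], pi_tr[[dep_lab]])
          score_both(rd, fam,
                     back_transform(predict_monomial(m, pi_tr[ind_lab]),
                                    train$IC_org),
                     back_transform(predict_monomial(m, pi_te[ind_lab]),
                                    test$IC_org))
        } else {
          m <- train_ensemble(Xtr, y_tr, "ols")
          score_both(rd, fam, predict_regressor(m, Xtr),
                     predict_regressor(m, Xte))
        }
      } else {
        m <- train_ensemble(Xtr, y_tr, tolower(fam))
        score_both(rd, fam, to_ec(predict_regressor(m, Xtr), "tr"),
                   to_ec(predict_regressor(m, Xte), "te"))
      }
    }
  }
  report <- do.call(rbind, rows)
  attr(report, "traces") <- traces
  class(report) <- c("evaluation_report", class(report))
  report
}

#' Pi-groups versus raw variables ablation
#'
#' Trains the identical feedforward network on (a) the standardized
#' pi-group features and (b) the standardized raw independent variables,
#' on synthetic data whose two studies differ 10-fold in filter bed
#' diameter, holding one study out for testing.  Both networks predict the
#' log dimensionless ratio log(EC/IC), exponentiated and back-transformed
#' to EC_org for scoring.
#' Because the generating law depends only on dimensionless ratios, the
#' pi features generalize across the scale gap while raw features face a
#' covariate shift.
#'
#' @param sigma Log-noise sd of the generator.
#' @param seed Base seed for the two study tables.
#' @param nn_config \code{\link{ffnn_config}}.
#' @param n_per_study Rows per study.
#' @return List with mean test \code{r2_pi}, \code{r2_raw},
#'   \code{smape_pi}, \code{smape_raw} across the config's seeds.
#' @export
ablation_pi_vs_raw <- function(sigma = 0.05, seed = 1,
                               nn_config = ffnn_config(),
                               n_per_study = 150) {
  lab <- generate_observations(synthetic_config(
    n_rows = n_per_study, sigma = sigma, seed = seed, n_studies = 1,
    ranges = list(C_fit = c(20e-3, 200e-3))))
  full <- generate_observations(synthetic_config(
    n_rows = n_per_study, sigma = sigma, seed = seed + 1, n_studies = 1,
    ranges = list(C_fit = c(200e-3, 2000e-3))))
  lab$study_id <- "lab"; full$study_id <- "full"
  train <- lab; test <- full

  specs <- biofilter_variables()
  basis <- construct_pi_basis(specs)
  pi_tr <- evaluate_pi(basis, train); pi_te <- evaluate_pi(basis, test)
  ind_lab <- attr(pi_tr, "independent_labels")
  dep_lab <- attr(pi_tr, "dependent_label")
  indep_syms <- vapply(Filter(function(s) s$role == "independent", specs),
                       function(s) s$symbol, character(1))
  y_tr <- log(pi_tr[[dep_lab]])

  run_mode <- function(Ftr, Fte) {
    std <- fit_standardizer(Ftr)
    nn <- train_ffnn(apply_standardizer(std, Ftr), y_tr, nn_config)
    pred <- predict_ffnn(nn, apply_standardizer(std, Fte))
    ec <- apply(pred, 2, function(p) back_transform(exp(p), test$IC_org))
    list(r2 = mean(apply(ec, 2, function(p) r_squared(test$EC_org, p))),
         smape = mean(apply(ec, 2, function(p) smape(test$EC_org, p))))
  }
  res_pi <- run_mode(log(as.matrix(pi_tr[ind_lab])),
                     log(as.matrix(pi_te[ind_lab])))
  res_raw <- run_mode(train[indep_syms], test[indep_syms])
  list(r2_pi = res_pi$r2, r2_raw = res_raw$r2,
       smape_pi = res_pi$smape, smape_raw = res_raw$smape)
}
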