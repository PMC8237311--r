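# The multi-regressor evaluation suite: 24 model configurations whose test
# MAEs are reduced to a 10th-percentile summary. The point of using many
# regressors is that judging a variable selection through a single model
# family confounds the selection with the model; the low quantile of many
# MAEs asks "how well can the selected variables predict, given a decent
# choice of model".

#' Mean absolute error
#'
#' \deqn{MAE = \frac{1}{m}\sum_i |y_i - \hat y_i|}
#'
#' @param y_obs,y_pred Equal-length numeric vectors.
#' @return Non-negative scalar.
#' @export
mae <- function(y_obs, y_pred) {
  if (length(y_obs) != length(y_pred))
    abort_("y_obs and y_pred lengths differ")
  if (!length(y_obs)) abort_("empty input")
  mean(abs(y_obs - y_pred))
}

#' Percentile of a vector of MAEs
#'
#' Linear interpolation between order statistics (quantile type 7);
#' `q = 0` is the minimum, `q = 100` the maximum.
#'
#' @param values Non-empty numeric vector.
#' @param q Percentile in \[0, 100\]; default 10.
#' @return The interpolated percentile.
#' @export
percentile_mae <- function(values, q = 10) {
  if (!length(values)) abort_("empty input")
  stopifnot(q >= 0, q <= 100)
  quantile(values, q / 100, names = FALSE, type = 7)
}

new_config <- function(id, family, kernel = NA_character_, grid, seed) {
  structure(list(id = id, family = family, kernel = kernel, grid = grid,
                 seed = seed),
            class = "regressor_config")
}

#' Build the regression suite
#'
#' The `"paper"` profile holds the full 24 configurations: PLS, ridge,
#' LASSO, elastic net, SVR with linear and Gaussian kernels, decision tree,
#' random forest, Gaussian process regression with the 11 registered
#' kernels ([gpr_kernels()]), four gradient-boosting configurations (a
#' classic GBDT, a regularized subsampling variant, a histogram/loss-guided
#' variant, and a depth-wise strongly L2-regularized variant — all on the
#' xgboost backend), and a single-hidden-layer neural network. The
#' `"fast"` profile is an 8-configuration subset for quick benchmarking.
#' Every configuration carries a small hyperparameter grid tuned by seeded
#' 5-fold cross-validation at fit time.
#'
#' @param profile `"paper"` (24 configs) or `"fast"` (8 configs).
#' @param seed Integer seed stamped into every configuration.
#' @return List of `regressor_config` objects.
#' @export
build_suite <- function(profile = c("paper", "fast"), seed = 1) {
  profile <- match.arg(profile)
  g <- function(...) expand.grid(..., KEEP.OUT.ATTRS = FALSE,
                                 stringsAsFactors = FALSE)
  cfgs <- list(
    new_config("pls", "pls", grid = g(ncomp = c(1, 2, 3, 5, 8, 12)), seed = seed),
    new_config("rr", "rr", grid = g(lambda = 10^c(-8, -5, -3, -1, 1)), seed = seed),
    new_config("lasso", "lasso", grid = g(lambda = 2^seq(-15, -1, 2)), seed = seed),
    new_config("en", "en", grid = g(lambda = 2^seq(-15, -1, 2)), seed = seed),
    new_config("svr_linear", "svr", "linear",
               grid = g(cost = 2^c(-2, 0, 2, 4), epsilon = c(0.01, 0.1)),
               seed = seed),
    new_config("svr_gaussian", "svr", "gaussian",
               grid = g(cost = 2^c(-1, 2, 5), epsilon = c(0.01, 0.1),
                        gamma_mult = c(0.3, 1, 3)), seed = seed),
    new_config("dt", "dt", grid = g(cp = c(0.001, 0.01, 0.05)), seed = seed),
    new_config("rf", "rf", grid = g(mtry_rule = c("third", "sqrt")), seed = seed)
  )
  gpr_cfgs <- lapply(gpr_kernels(), function(k) {
    grid <- if (k %in% c("linear", "linear_white")) g(noise = c(0.01, 0.1))
            else g(ls_mult = c(0.5, 1, 2), noise = c(0.01, 0.1))
    new_config(paste0("gpr_", k), "gpr", k, grid = grid, seed = seed)
  })
  boost_cfgs <- list(
    new_config("gbdt", "gbdt", grid = g(max_depth = c(2, 3)), seed = seed),
    new_config("xgb", "xgb", grid = g(max_depth = c(3, 6)), seed = seed),
    new_config("boost_lossguide", "boost_lossguide",
               grid = g(max_leaves = c(15, 31)), seed = seed),
    new_config("boost_depthwise", "boost_depthwise",
               grid = g(eta = c(0.05, 0.1)), seed = seed)
  )
  dnn <- new_config("dnn", "dnn", grid = g(size = c(5, 10), decay = c(1e-3, 1e-1)),
                    seed = seed)
  all <- c(cfgs, gpr_cfgs, boost_cfgs, list(dnn))
  if (profile == "fast")
    all <- all[vapply(all, function(cc) cc$id %in%
                        c("pls", "rr", "lasso", "en", "svr_gaussian",
                          "dt", "rf", "gpr_rbf"), logical(1))]
  attr(all, "profile") <- profile
  all
}

#' Build the full 24-configuration suite
#'
#' @param seed Integer seed.
#' @return List of 24 `regressor_config` objects (the `"paper"` profile of
#'   [build_suite()]).
#' @export
build_default_suite <- function(seed = 1) build_suite("paper", seed)

# Pad a single-column matrix so glmnet (which requires >= 2 columns)
# accepts it; the constant column gets a zero coefficient.
pad1 <- function(X) {
  if (ncol(X) >= 2) return(X)
  cbind(X, `.pad` = 0)
}

suite_fit <- function(config, X, y, params) {
  fam <- config$family
  p <- ncol(X)
  if (var(y) == 0) # degenerate target: the intercept-only model is exact
    return(list(kind = "const", fit = y[1]))
  if (fam == "pls") {
    if (p == 1) { # one-component PLS on one column is least squares
      cf <- coef(lsfit(X[, 1], y))
      return(list(kind = "lm1", fit = cf))
    }
    nc <- min(params$ncomp, p, nrow(X) - 1)
    fit <- mixOmics::pls(X, y, ncomp = max(nc, 1), mode = "regression",
                         scale = FALSE)
    return(list(kind = "pls", fit = fit, ncomp = max(nc, 1)))
  }
  if (fam %in% c("rr", "lasso", "en")) {
    alpha <- c(rr = 0, lasso = 1, en = 0.5)[[fam]]
    fit <- glmnet::glmnet(pad1(X), y, alpha = alpha,
                          lambda = c(params$lambda * 2, params$lambda),
                          standardize = FALSE)
    return(list(kind = "glmnet", fit = fit, lambda = params$lambda))
  }
  if (fam == "svr") {
    kern <- if (config$kernel == "linear") "linear" else "radial"
    args <- list(x = X, y = y, type = "eps-regression", kernel = kern,
                 cost = params$cost, epsilon = params$epsilon, scale = FALSE)
    if (kern == "radial") args$gamma <- params$gamma_mult / p
    return(list(kind = "svm", fit = do.call(e1071::svm, args)))
  }
  if (fam == "dt") {
    d <- data.frame(.y = y, X, check.names = FALSE)
    fit <- rpart::rpart(.y ~ ., data = d, method = "anova",
                        control = rpart::rpart.control(cp = params$cp))
    return(list(kind = "rpart", fit = fit))
  }
  if (fam == "rf") {
    mtry <- if (params$mtry_rule == "third") max(1, floor(p / 3))
            else max(1, floor(sqrt(p)))
    fit <- ranger::ranger(x = X, y = y, num.trees = 500, mtry = min(mtry, p),
                          seed = config$seed, num.threads = 1)
    return(list(kind = "ranger", fit = fit))
  }
  if (fam == "gpr") {
    ls <- if (is.null(params$ls_mult)) 1
          else params$ls_mult * median_lengthscale(X)
    return(list(kind = "gpr",
                fit = gpr_fit(X, y, config$kernel, ls, params$noise)))
  }
  if (fam %in% c("gbdt", "xgb", "boost_lossguide", "boost_depthwise")) {
    xp <- switch(fam,
      gbdt = list(eta = 0.05, max_depth = params$max_depth, lambda = 0,
                  subsample = 1, nrounds = 300),
      xgb = list(eta = 0.1, max_depth = params$max_depth, lambda = 1,
                 subsample = 0.8, colsample_bytree = 0.8, nrounds = 200),
      boost_lossguide = list(eta = 0.1, max_depth = 0,
                             max_leaves = params$max_leaves,
                             grow_policy = "lossguide", tree_method = "hist",
                             nrounds = 200),
      boost_depthwise = list(eta = params$eta, max_depth = 6, lambda = 3,
                             colsample_bylevel = 0.8, nrounds = 300))
    nrounds <- xp$nrounds
    xp$nrounds <- NULL
    xp$objective <- "reg:squarederror"
    xp$nthread <- 1
    xp$seed <- config$seed
    dtrain <- xgboost::xgb.DMatrix(X, label = y)
    fit <- xgboost::xgb.train(params = xp, data = dtrain, nrounds = nrounds,
                              verbose = 0)
    return(list(kind = "xgb", fit = fit))
  }
  if (fam == "dnn") {
    fit <- with_seed_(config$seed,
      nnet::nnet(X, y, size = params$size, decay = params$decay,
                 linout = TRUE, maxit = 300, trace = FALSE,
                 MaxNWts = 50000))
    return(list(kind = "nnet", fit = fit))
  }
  abort_("unknown regressor family: ", fam)
}

suite_predict <- function(model, Xnew) {
  switch(model$kind,
    pls = predict(model$fit, Xnew)$predict[, 1, model$ncomp],
    lm1 = model$fit[1] + model$fit[2] * Xnew[, 1],
    const = rep(model$fit, nrow(Xnew)),
    glmnet = drop(predict(model$fit, pad1(Xnew), s = model$lambda)),
    svm = as.numeric(predict(model$fit, Xnew)),
    rpart = predict(model$fit, data.frame(Xnew, check.names = FALSE)),
    ranger = predict(model$fit, Xnew, num.threads = 1)$predictions,
    gpr = gpr_predict(model$fit, Xnew),
    xgb = predict(model$fit, xgboost::xgb.DMatrix(Xnew)),
    nnet = drop(predict(model$fit, Xnew)),
    abort_("unknown model kind")
  )
}

#' Fit one suite configuration and report its test MAE
#'
#' Tunes the configuration's hyperparameter grid by seeded 5-fold
#' cross-validation on the training rows (selecting the grid row with the
#' smallest CV MAE), refits on the full training data, predicts the test
#' rows, and returns the test MAE — in original response units when a
#' `scaling` list (from [autoscale()]) is given.
#'
#' @param config A `regressor_config` from [build_suite()].
#' @param train,test [vsb_dataset()] partitions with identical columns.
#' @param mask Logical or integer selector of at least one column.
#' @param scaling Optional scaling attribute of the autoscaled split; when
#'   supplied, the MAE is reported in original response units.
#' @param cv_folds Folds of the tuning CV.
#' @return The test MAE (scalar).
#' @export
fit_predict_mae <- function(config, train, test, mask, scaling = NULL,
                            cv_folds = 5) {
  X <- train$X[, mask, drop = FALSE]
  Xt <- test$X[, mask, drop = FALSE]
  if (!ncol(X)) abort_("mask selects no columns")
  grid <- config$grid
  best_row <- 1L
  if (nrow(grid) > 1) {
    folds <- make_folds(nrow(X), cv_folds, config$seed)
    cv_mae <- vapply(seq_len(nrow(grid)), function(r) {
      params <- as.list(grid[r, , drop = FALSE])
      oof <- numeric(nrow(X))
      for (k in sort(unique(folds))) {
        in_k <- folds == k
        m <- suite_fit(config, X[!in_k, , drop = FALSE], train$y[!in_k], params)
        oof[in_k] <- suite_predict(m, X[in_k, , drop = FALSE])
      }
      mae(train$y, oof)
    }, numeric(1))
    best_row <- which.min(cv_mae)
  }
  model <- suite_fit(config, X, train$y, as.list(grid[best_row, , drop = FALSE]))
  pred <- suite_predict(model, Xt)
  if (!is.null(scaling))
    mae(unscale_y(test$y, scaling), unscale_y(pred, scaling))
  else mae(test$y, pred)
}

#' Run the regression suite on a selection
#'
#' Fits every configuration of the chosen profile on the selected columns
#' and reduces the test MAEs to their 10th percentile. A configuration that
#' fails to fit is excluded from the percentile with a warning and counted
#' in `failures`.
#'
#' @param pair An autoscaled `vsb_split`.
#' @param selection A [selection_result()] (or a logical/integer column
#'   mask).
#' @param profile Suite profile passed to [build_suite()]; ignored when
#'   `configs` is given.
#' @param configs Optional explicit list of `regressor_config`s.
#' @param seed Integer seed for the suite.
#' @return A `suite_result`: list with `per_config_mae` (named numeric),
#'   `mae_p10`, `n_selected`, `failures`, `profile`.
#' @export
run_suite <- function(pair, selection, profile = "paper", configs = NULL,
                      seed = 1) {
  stopifnot(inherits(pair, "vsb_split"))
  mask <- if (inherits(selection, "selection_result")) selection$selected
          else selection
  if (!length(mask) || (is.logical(mask) && !any(mask)))
    abort_("empty selection; the suite needs at least one column")
  configs <- configs %||% build_suite(profile, seed)
  scaling <- attr(pair, "scaling")
  maes <- numeric(0)
  failures <- 0L
  for (cc in configs) {
    v <- tryCatch(fit_predict_mae(cc, pair$train, pair$test, mask, scaling),
                  error = function(e) {
                    warning("suite config '", cc$id, "' failed: ",
                            conditionMessage(e))
                    NA_real_
                  })
    if (is.na(v)) failures <- failures + 1L
    else maes[cc$id] <- v
  }
  if (!length(maes)) abort_("every suite configuration failed")
  structure(list(per_config_mae = maes, mae_p10 = percentile_mae(maes, 10),
                 n_selected = if (is.logical(mask)) sum(mask) else length(mask),
                 failures = failures,
                 profile = attr(configs, "profile") %||% "custom"),
            class = "suite_result")
}

#' @method print suite_result
#' @export
print.suite_result <- function(x, ...) {
  cat(sprintf("<suite_result> %d configs (%s profile), %d selected vars\n",
              length(x$per_config_mae), x$profile, x$n_selected))
  cat(sprintf("  10th-percentile MAE: %.4g (range %.4g - %.4g)\n",
              x$mae_p10, min(x$per_config_mae), max(x$per_config_mae)))
  if (x$failures) cat("  failed configs:", x$failures, "\n")
  invisible(x)
}
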