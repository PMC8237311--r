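#' Default LASSO penalty grid
#'
#' The standard wide penalty grid for descriptor tables:
#' \eqn{\lambda = 2^{-15}, 2^{-14}, \dots, 2^{-1}}, 15 values ascending.
#'
#' @return Numeric vector of 15 penalties.
#' @export
default_lambda_grid <- function() 2^seq(-15, -1)

#' LASSO variable selection
#'
#' Embedded selection via L1-penalized least squares
#' \deqn{\sum_i (y_i - x_i b)^2 + \lambda \sum_j |b_j|.}
#' For every penalty on the grid the pooled out-of-fold \eqn{r^2} over
#' seeded, shuffled K-fold cross-validation is computed; the penalty with
#' the largest CV \eqn{r^2} wins (ties go to the smaller penalty, i.e. the
#' least shrinkage). The model is then refit on the full training data and
#' the selected set is the support of the coefficient vector — coordinate
#' descent returns exact zeros, so no epsilon is involved.
#'
#' @param train Autoscaled training [vsb_dataset()].
#' @param lambda_grid Ascending positive penalties; default
#'   [default_lambda_grid()].
#' @param cv_folds Number of CV folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return A [selection_result()]; `meta` records the chosen `lambda`, its
#'   `cv_r2`, the full `cv_r2_grid`, and `empty_selection = TRUE` (with a
#'   warning) if every coefficient is zero at every penalty.
#' @export
select_lasso <- function(train, lambda_grid = default_lambda_grid(),
                         cv_folds = 5, seed = 1) {
  stopifnot(inherits(train, "vsb_dataset"))
  if (!length(lambda_grid) || any(lambda_grid <= 0) || is.unsorted(lambda_grid))
    abort_("lambda_grid must be non-empty, positive and ascending")
  n <- nrow(train$X)
  if (n < cv_folds) abort_("need at least cv_folds samples")
  lam_desc <- rev(lambda_grid) # glmnet wants a decreasing sequence
  folds <- make_folds(n, cv_folds, seed)
  oof <- matrix(NA_real_, n, length(lam_desc))
  for (k in seq_len(cv_folds)) {
    in_k <- folds == k
    fit <- glmnet::glmnet(train$X[!in_k, , drop = FALSE], train$y[!in_k],
                          alpha = 1, lambda = lam_desc, standardize = FALSE)
    oof[in_k, ] <- predict(fit, train$X[in_k, , drop = FALSE])
  }
  r2 <- apply(oof, 2, function(p) pooled_r2(train$y, p))
  # lam_desc is decreasing; which.max on the reversed vector favors the
  # smaller lambda on exact ties
  best_i_asc <- which.max(rev(r2))
  lambda <- lambda_grid[best_i_asc]
  full <- glmnet::glmnet(train$X, train$y, alpha = 1, lambda = lam_desc,
                         standardize = FALSE)
  beta <- as.matrix(coef(full))[-1, length(lam_desc) - best_i_asc + 1]
  selected <- which(beta != 0)
  meta <- list(lambda = lambda, cv_r2 = rev(r2)[best_i_asc],
               cv_r2_grid = setNames(rev(r2), lambda_grid), seed = seed)
  if (!length(selected)) {
    meta$empty_selection <- TRUE
    warning("LASSO selected no variables at any penalty on the grid")
  }
  selection_result("lasso", selected, colnames(train$X), meta = meta)
}
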