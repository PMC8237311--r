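#' Split a dataset into training and test partitions
#'
#' Random 70/30 (by default) split. The number of training samples is
#' `round(train_fraction * n)`; membership is drawn from a seeded
#' permutation, so the same seed always yields the same split.
#'
#' @param ds A [vsb_dataset()].
#' @param train_fraction Fraction of samples assigned to training, in (0, 1).
#' @param seed Integer seed for the permutation.
#' @return An object of class `vsb_split`: list with `train`, `test`
#'   (both `vsb_dataset`) and `seed`.
#' @export
split_train_test <- function(ds, train_fraction = 0.7, seed = 1) {
  stopifnot(inherits(ds, "vsb_dataset"))
  if (train_fraction <= 0 || train_fraction >= 1)
    abort_("train_fraction must be in (0, 1)")
  n <- nrow(ds$X)
  if (n < 5) abort_("need at least 5 samples to split")
  n_train <- round(train_fraction * n)
  if (n_train < 1 || n_train > n - 1)
    abort_("split leaves an empty partition (n = ", n, ")")
  perm <- with_seed_(seed, sample.int(n))
  idx_train <- sort(perm[seq_len(n_train)])
  idx_test <- sort(perm[(n_train + 1):n])
  structure(list(
    train = vsb_dataset(ds$X[idx_train, , drop = FALSE], ds$y[idx_train], ds$origin),
    test = vsb_dataset(ds$X[idx_test, , drop = FALSE], ds$y[idx_test], ds$origin),
    seed = seed
  ), class = "vsb_split")
}

#' @method print vsb_split
#' @export
print.vsb_split <- function(x, ...) {
  cat(sprintf("<vsb_split> train %d x %d | test %d x %d%s\n",
              nrow(x$train$X), ncol(x$train$X), nrow(x$test$X), ncol(x$test$X),
              if (!is.null(attr(x, "scaling"))) " (autoscaled)" else ""))
  invisible(x)
}

keep_cols <- function(pair, keep) {
  if (!any(keep))
    abort_("all columns would be removed; relax the filter threshold")
  pair$train <- dataset_cols(pair$train, keep)
  pair$test <- dataset_cols(pair$test, keep)
  pair
}

#' Drop low-variation columns
#'
#' Removes every column whose most frequent value (exact equality, no
#' binning) accounts for at least `threshold` of the TRAIN samples. The
#' decision is made on the training partition only and applied to both
#' partitions, so the test data never influence which columns survive.
#'
#' @param pair A `vsb_split`.
#' @param threshold Mode-frequency cutoff in (0, 1]; default 0.8.
#' @return The filtered `vsb_split`.
#' @export
filter_low_variation <- function(pair, threshold = 0.8) {
  stopifnot(inherits(pair, "vsb_split"))
  if (threshold <= 0 || threshold > 1) abort_("threshold must be in (0, 1]")
  n <- nrow(pair$train$X)
  mode_freq <- apply(pair$train$X, 2, function(col) max(table(col)) / n)
  keep_cols(pair, mode_freq < threshold)
}

#' Drop perfectly correlated duplicate columns
#'
#' For every pair of TRAIN columns with `|Pearson r| >= 1 - tol`, the
#' later-indexed column is removed from both partitions. Columns are
#' processed left to right, so the survivor of a correlated group is always
#' its first occurrence.
#'
#' @param pair A `vsb_split`, normally after [filter_low_variation()].
#' @param tol Tolerance on `|r| - 1`; default `1e-12`.
#' @return The deduplicated `vsb_split`.
#' @export
dedup_perfect_correlation <- function(pair, tol = 1e-12) {
  stopifnot(inherits(pair, "vsb_split"), tol >= 0)
  X <- pair$train$X
  p <- ncol(X)
  if (p < 2) return(pair)
  C <- abs(suppressWarnings(cor(X)))
  C[is.na(C)] <- 0
  keep <- rep(TRUE, p)
  for (j in 2:p) {
    prior <- which(keep[seq_len(j - 1)])
    if (length(prior) && any(C[prior, j] >= 1 - tol)) keep[j] <- FALSE
  }
  keep_cols(pair, keep)
}

#' Spike uniform random probe variables
#'
#' Appends as many new columns as there are original descriptors, each drawn
#' i.i.d. from uniform(0, 1) (independently for the training and test rows),
#' flagged `origin = "random_probe"` and named with the reserved prefix
#' `rand_`. The fraction of these probes later picked by a selector measures
#' its tendency to select variables unrelated to the response.
#'
#' @param pair A `vsb_split` containing only original columns.
#' @param seed Integer seed for the probe draws.
#' @return The spiked `vsb_split` with twice the original column count.
#' @export
spike_random_variables <- function(pair, seed = 1) {
  stopifnot(inherits(pair, "vsb_split"))
  if (any(pair$train$origin != "original"))
    abort_("dataset already contains random_probe columns")
  k <- ncol(pair$train$X)
  if (any(startsWith(colnames(pair$train$X), "rand_")))
    abort_("column names collide with the reserved probe prefix 'rand_'")
  nm <- paste0("rand_", seq_len(k))
  probes <- with_seed_(seed, list(
    train = matrix(runif(nrow(pair$train$X) * k), ncol = k),
    test = matrix(runif(nrow(pair$test$X) * k), ncol = k)
  ))
  colnames(probes$train) <- colnames(probes$test) <- nm
  origin <- c(pair$train$origin, rep("random_probe", k))
  pair$train <- vsb_dataset(cbind(pair$train$X, probes$train), pair$train$y, origin)
  pair$test <- vsb_dataset(cbind(pair$test$X, probes$test), pair$test$y, origin)
  pair
}

#' Autoscale a split by training statistics
#'
#' Centers and scales every column (and the response) to zero mean and unit
#' variance using TRAIN means and standard deviations; the identical
#' transform is applied to the test partition. The scaling parameters are
#' stored in `attr(pair, "scaling")` so predictions can be mapped back to
#' original response units with [unscale_y()].
#'
#' @param pair A `vsb_split` with no zero-variance training columns.
#' @return The autoscaled `vsb_split`.
#' @export
autoscale <- function(pair) {
  stopifnot(inherits(pair, "vsb_split"))
  ctr <- colMeans(pair$train$X)
  scl <- apply(pair$train$X, 2, sd)
  if (any(scl == 0))
    abort_("zero train standard deviation in column(s): ",
           paste(colnames(pair$train$X)[scl == 0], collapse = ", "))
  y_ctr <- mean(pair$train$y)
  y_scl <- sd(pair$train$y)
  if (y_scl == 0) abort_("train response is constant; cannot autoscale y")
  pair$train$X <- scale(pair$train$X, ctr, scl)
  pair$test$X <- scale(pair$test$X, ctr, scl)
  pair$train$y <- (pair$train$y - y_ctr) / y_scl
  pair$test$y <- (pair$test$y - y_ctr) / y_scl
  attr(pair, "scaling") <- list(x_center = ctr, x_scale = scl,
                                y_center = y_ctr, y_scale = y_scl)
  pair
}

#' Map a scaled response back to original units
#'
#' @param values Numeric vector on the autoscaled response scale.
#' @param pair An autoscaled `vsb_split` (or its `scaling` attribute).
#' @return Values in the original response units.
#' @export
unscale_y <- function(values, pair) {
  sc <- if (is.list(pair) && !is.null(pair$y_center)) pair else attr(pair, "scaling")
  if (is.null(sc)) abort_("pair carries no scaling attribute")
  values * sc$y_scale + sc$y_center
}

#' Full preprocessing pipeline
#'
#' Convenience wrapper running, in order: [split_train_test()],
#' [filter_low_variation()], [dedup_perfect_correlation()], optionally
#' [spike_random_variables()] (seeded with `seed + 1`), and optionally
#' [autoscale()].
#'
#' @param ds A [vsb_dataset()].
#' @param train_fraction,same_value_threshold,dedup_tol Filter parameters.
#' @param spike,scale Logical switches for probe spiking and autoscaling.
#' @param seed Integer seed; the split uses `seed`, the probes `seed + 1`.
#' @return A processed `vsb_split`.
#' @export
preprocess <- function(ds, train_fraction = 0.7, same_value_threshold = 0.8,
                       dedup_tol = 1e-12, spike = TRUE, scale = TRUE, seed = 1) {
  pair <- split_train_test(ds, train_fraction, seed)
  pair <- filter_low_variation(pair, same_value_threshold)
  pair <- dedup_perfect_correlation(pair, dedup_tol)
  if (spike) pair <- spike_random_variables(pair, seed + 1)
  if (scale) pair <- autoscale(pair)
  pair
}
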