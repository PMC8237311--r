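# All-relevant variable selection with shadow features (Boruta) and the
# chance-correlation percentile calibration (r-Boruta).

#' Boruta configuration
#'
#' @param percentile Reference percentile of the shadow importances in
#'   (0, 100]; 100 (the default) uses the maximum shadow importance, the
#'   classical rule.
#' @param alpha Two-sided significance level of the binomial decision test.
#' @param max_iter Maximum number of shuffle/fit/test iterations.
#' @param rf_trees Trees per random forest.
#' @param tentative_policy `"exclude"` (default) counts only confirmed
#'   variables as selected; `"include"` also counts still-tentative ones.
#' @param seed Integer seed covering shadow shuffles and forest fits.
#' @return A `boruta_config` list.
#' @export
boruta_config <- function(percentile = 100, alpha = 0.05, max_iter = 100,
                          rf_trees = 500,
                          tentative_policy = c("exclude", "include"),
                          seed = 1) {
  tentative_policy <- match.arg(tentative_policy)
  stopifnot(percentile > 0, percentile <= 100, alpha > 0, alpha < 1,
            max_iter >= 5, rf_trees >= 1)
  structure(list(percentile = percentile, alpha = alpha, max_iter = max_iter,
                 rf_trees = rf_trees, tentative_policy = tentative_policy,
                 seed = seed),
            class = "boruta_config")
}

#' Shadow copy of a descriptor matrix
#'
#' Returns a matrix of the same shape in which every column is an
#' independent row permutation of the corresponding original column: each
#' shadow keeps its marginal distribution but loses any relation to the
#' response.
#'
#' @param X Numeric matrix.
#' @param seed Optional seed; if `NULL` the current RNG stream is used
#'   (as inside the [run_boruta()] loop).
#' @return The shuffled matrix, columns prefixed `shadow_`.
#' @export
make_shadow <- function(X, seed = NULL) {
  shuffle <- function() apply(X, 2, sample)
  S <- if (is.null(seed)) shuffle() else with_seed_(seed, shuffle())
  colnames(S) <- paste0("shadow_", colnames(X))
  S
}

#' One Boruta hit update
#'
#' Given the importances of the original columns followed by their shadows,
#' computes the reference value as the `percentile`-th percentile of the
#' shadow importances (linear interpolation between order statistics; at
#' percentile 100 this is exactly the maximum) and flags each original
#' column as a hit iff its importance strictly exceeds the reference.
#'
#' @param importances Numeric vector of length `2 * n_original`
#'   (originals first, shadows second).
#' @param n_original Number of original columns.
#' @param percentile Reference percentile in (0, 100].
#' @return Logical hit vector of length `n_original`.
#' @export
hit_update <- function(importances, n_original, percentile = 100) {
  stopifnot(length(importances) == 2 * n_original)
  ref <- quantile(importances[(n_original + 1):(2 * n_original)],
                  percentile / 100, names = FALSE, type = 7)
  importances[seq_len(n_original)] > ref
}

#' Binomial decision for one variable
#'
#' Exact two-sided test of `hits` successes in `trials` fair coin flips,
#' split evenly across the tails: confirmed when
#' \eqn{P[H \ge hits] < \alpha/2}, rejected when
#' \eqn{P[H \le hits] < \alpha/2}, otherwise tentative.
#'
#' @param hits,trials Hit count and iteration count, `0 <= hits <= trials`.
#' @param alpha Two-sided significance level.
#' @return One of `"confirmed"`, `"rejected"`, `"tentative"`.
#' @export
binomial_decision <- function(hits, trials, alpha = 0.05) {
  if (trials < 1) abort_("trials must be >= 1")
  stopifnot(hits >= 0, hits <= trials)
  p_upper <- pbinom(hits - 1, trials, 0.5, lower.tail = FALSE) # P[H >= hits]
  p_lower <- pbinom(hits, trials, 0.5)                         # P[H <= hits]
  if (p_upper < alpha / 2) "confirmed"
  else if (p_lower < alpha / 2) "rejected"
  else "tentative"
}

#' Boruta variable selection
#'
#' Iterates: re-shuffle a shadow copy of every still-active original column,
#' fit a random-forest regression on `[actives | shadows]` against the
#' response, compare each active column's impurity importance with the
#' `percentile`-th percentile of the shadow importances ([hit_update()]),
#' and decide each still-tentative column by the exact binomial test
#' ([binomial_decision()]). Rejected columns are removed from subsequent
#' iterations and their hit counts freeze; confirmed columns keep competing.
#' Stops when no column is tentative or after `max_iter` iterations.
#'
#' @param train Autoscaled training [vsb_dataset()].
#' @param cfg A [boruta_config()].
#' @return A [selection_result()] with per-column status in
#'   `{"confirmed", "rejected", "tentative"}`; `meta` records `hits`,
#'   `trials`, `percentile` and the iteration count. Selected variables are
#'   the confirmed ones (plus tentative under
#'   `tentative_policy = "include"`).
#' @export
run_boruta <- function(train, cfg = boruta_config()) {
  stopifnot(inherits(train, "vsb_dataset"), inherits(cfg, "boruta_config"))
  X <- train$X
  p <- ncol(X)
  if (sum(apply(X, 2, var) > 0) < 2)
    abort_("need at least 2 non-constant columns")
  hits <- integer(p)
  status <- rep("tentative", p)
  trials <- 0L
  with_seed_(cfg$seed, {
    for (iter in seq_len(cfg$max_iter)) {
      act <- which(status != "rejected")
      Xact <- X[, act, drop = FALSE]
      S <- make_shadow(Xact)
      rf_seed <- sample.int(.Machine$integer.max, 1)
      rf <- ranger::ranger(x = cbind(Xact, S), y = train$y,
                           num.trees = cfg$rf_trees, importance = "impurity",
                           seed = rf_seed, num.threads = 1)
      imp <- ranger::importance(rf)
      hit <- hit_update(imp, length(act), cfg$percentile)
      hits[act] <- hits[act] + hit
      trials <- trials + 1L
      for (j in act[status[act] == "tentative"]) {
        d <- binomial_decision(hits[j], trials, cfg$alpha)
        if (d != "tentative") status[j] <- d
      }
      if (!any(status == "tentative")) break
    }
  })
  selected <- which(status == "confirmed" |
                    (cfg$tentative_policy == "include" & status == "tentative"))
  selection_result("boruta", selected, colnames(X), status = status,
                   meta = list(hits = setNames(hits, colnames(X)),
                               trials = trials, iterations = trials,
                               percentile = cfg$percentile, seed = cfg$seed))
}

#' Chance-correlation percentile for r-Boruta
#'
#' Generates `n_random` standard-normal columns with as many rows as `y`,
#' computes the absolute Pearson correlation of each with `y`, and returns
#' 100 times the maximum — the percentile at which a shadow importance
#' reference should sit so that chance correlation at this sample size does
#' not wipe out genuinely informative variables.
#'
#' @param y Response vector with nonzero variance.
#' @param n_random Number of random columns (default 10000).
#' @param seed Integer seed.
#' @return A percentile in (0, 100].
#' @export
rboruta_percentile <- function(y, n_random = 10000, seed = 1) {
  if (var(y) == 0) abort_("y is constant; correlation undefined")
  if (n_random < 100) abort_("n_random must be >= 100")
  n <- length(y)
  max_r <- with_seed_(seed, {
    # blocks keep memory flat for very large n_random
    block <- 2000L
    m <- 0
    done <- 0L
    while (done < n_random) {
      b <- min(block, n_random - done)
      Z <- matrix(rnorm(n * b), nrow = n)
      m <- max(m, max(abs(cor(Z, y))))
      done <- done + b
    }
    m
  })
  min(100 * max_r, 100)
}

#' r-Boruta variable selection
#'
#' Boruta with the reference percentile calibrated to chance correlation:
#' the percentile is set to [rboruta_percentile()] of the training response
#' (instead of the fixed 100), lowering the hit bar when the sample size is
#' small enough for random variables to correlate with the response by
#' accident — which prevents over-deletion of genuinely informative
#' variables.
#'
#' @param train Autoscaled training [vsb_dataset()].
#' @param cfg A [boruta_config()]; its `percentile` field is overwritten.
#' @param n_random Random columns used for the calibration.
#' @param seed Seed for the calibration draw (independent of `cfg$seed`,
#'   which still drives the Boruta loop).
#' @param percentile Optional override; if supplied the calibration is
#'   skipped and this value is used directly (forcing 100 makes r-Boruta
#'   coincide with plain Boruta).
#' @return A [selection_result()] with `method = "rboruta"`; `meta` records
#'   the percentile actually used.
#' @export
run_rboruta <- function(train, cfg = boruta_config(), n_random = 10000,
                        seed = 1, percentile = NULL) {
  p_ref <- percentile %||% rboruta_percentile(train$y, n_random, seed)
  cfg$percentile <- p_ref
  res <- run_boruta(train, cfg)
  res$method <- "rboruta"
  res$meta$percentile <- p_ref
  res$meta$calibration_seed <- seed
  res
}
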