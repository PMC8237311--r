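#' Specification for a synthetic benchmark dataset
#'
#' Describes a regression table with a known informative block: the first
#' `n_informative` columns are drawn from an equicorrelated multivariate
#' normal (pairwise correlation `within_block_correlation`) and carry the
#' response signal through `coefficients`; the remaining `n_noise` columns
#' are i.i.d. standard normal and unrelated to the response. The defaults
#' emulate a typical QSAR descriptor table of 75 variables on 200 molecules
#' (10 informative descriptors with geometrically decaying effect sizes
#' from 3 down to 0.3, unit observation noise).
#'
#' @param n_samples,n_informative,n_noise Dimensions of the table.
#' @param coefficients Effect sizes of the informative columns
#'   (length `n_informative`).
#' @param within_block_correlation Equicorrelation of the informative block,
#'   in \[0, 1).
#' @param noise_sd Standard deviation of additive observation noise.
#' @param response `"linear"`, or `"quadratic_interaction"` to add the
#'   product of the first two informative columns.
#' @param seed Integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_samples = 200, n_informative = 10, n_noise = 65,
                           coefficients = 3 * (0.3 / 3)^((seq_len(n_informative) - 1) /
                                                         max(n_informative - 1, 1)),
                           within_block_correlation = 0.3, noise_sd = 1,
                           response = c("linear", "quadratic_interaction"),
                           seed = 1) {
  response <- match.arg(response)
  stopifnot(n_samples > 0, n_informative >= 1, n_noise >= 0, noise_sd >= 0)
  if (length(coefficients) != n_informative)
    abort_("coefficients must have length n_informative")
  if (within_block_correlation < 0 || within_block_correlation >= 1)
    abort_("within_block_correlation must lie in [0, 1) for a positive-definite block")
  structure(list(n_samples = n_samples, n_informative = n_informative,
                 n_noise = n_noise, coefficients = coefficients,
                 within_block_correlation = within_block_correlation,
                 noise_sd = noise_sd, response = response, seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic dataset with known ground truth
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `dataset` (a [vsb_dataset()], columns `x1`, `x2`, ...)
#'   and `truth` (list with `informative_mask` and the informative column
#'   `names`).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rho <- spec$within_block_correlation
  p_inf <- spec$n_informative
  with_seed_(spec$seed, {
    # equicorrelated MVN via a shared latent factor:
    # x_j = sqrt(rho) * g + sqrt(1 - rho) * e_j  has cor(x_i, x_j) = rho
    g <- rnorm(spec$n_samples)
    E <- matrix(rnorm(spec$n_samples * p_inf), ncol = p_inf)
    Xi <- sqrt(rho) * g + sqrt(1 - rho) * E
    Xn <- if (spec$n_noise > 0)
      matrix(rnorm(spec$n_samples * spec$n_noise), ncol = spec$n_noise)
    else NULL
    y <- drop(Xi %*% spec$coefficients)
    if (spec$response == "quadratic_interaction" && p_inf >= 2)
      y <- y + Xi[, 1] * Xi[, 2]
    y <- y + rnorm(spec$n_samples, sd = spec$noise_sd)
    X <- cbind(Xi, Xn)
    colnames(X) <- paste0("x", seq_len(ncol(X)))
    mask <- c(rep(TRUE, p_inf), rep(FALSE, spec$n_noise))
    list(dataset = vsb_dataset(X, y),
         truth = list(informative_mask = mask,
                      names = colnames(X)[mask]))
  })
}

#' Recall and precision of a selection against known ground truth
#'
#' Scores a selector's output against the informative columns of a synthetic
#' dataset. Matching is by column name, so the selection may come from a
#' preprocessed (filtered, spiked) version of the generated table. Recall is
#' the fraction of informative variables selected; precision is the fraction
#' of selected variables that are informative (1 when both sets are empty,
#' 0 when the selection is empty but informative variables exist).
#'
#' @param sel A `selection_result`.
#' @param truth The `truth` element returned by [generate_synthetic()].
#' @return Named numeric vector `c(recall = , precision = )`.
#' @export
recovery_metrics <- function(sel, truth) {
  stopifnot(inherits(sel, "selection_result"))
  sel_names <- sel$names[sel$selected]
  inf_names <- truth$names
  tp <- length(intersect(sel_names, inf_names))
  recall <- if (length(inf_names) == 0) 1 else tp / length(inf_names)
  precision <- if (length(sel_names) == 0) {
    if (length(inf_names) == 0) 1 else 0
  } else tp / length(sel_names)
  c(recall = recall, precision = precision)
}
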