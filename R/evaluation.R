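# Orchestration of selector x repeat benchmark runs and the three
# evaluation indicators.

#' Proportion of original variables selected
#'
#' Number of selected `origin = "original"` columns divided by the total
#' number of original columns.
#'
#' @param sel A [selection_result()] over the columns of `ds`.
#' @param ds The (spiked) [vsb_dataset()] the selection refers to.
#' @return A ratio in \[0, 1\].
#' @export
ratio_selected <- function(sel, ds) {
  n_orig <- sum(ds$origin == "original")
  if (!n_orig) abort_("dataset has no original columns")
  sum(ds$origin[sel$selected] == "original") / n_orig
}

#' Proportion of random probe variables selected
#'
#' Number of selected `origin = "random_probe"` columns divided by the
#' number of ORIGINAL columns (the probe count equals the original count
#' after spiking, so the ratio is also in \[0, 1\]). This is the protocol's
#' false-selection indicator.
#'
#' @inheritParams ratio_selected
#' @return A ratio in \[0, 1\].
#' @export
ratio_random <- function(sel, ds) {
  if (!any(ds$origin == "random_probe"))
    abort_("dataset has no random_probe columns; spike before selecting")
  n_orig <- sum(ds$origin == "original")
  sum(ds$origin[sel$selected] == "random_probe") / n_orig
}

# Dispatch one selector on a preprocessed training partition.
run_selector <- function(method, train, config, seed) {
  config <- config %||% list()
  switch(method,
    lasso = select_lasso(train,
                         lambda_grid = config$lambda_grid %||% default_lambda_grid(),
                         cv_folds = config$cv_folds %||% 5, seed = seed),
    gapls = ,
    gasvr = {
      base <- config[intersect(names(config), names(formals(ga_config)))]
      cfg <- do.call(ga_config, modifyList(base, list(seed = seed)))
      run_ga(train, method, cfg)
    },
    boruta = ,
    rboruta = {
      base <- config[intersect(names(config), names(formals(boruta_config)))]
      cfg <- do.call(boruta_config, modifyList(base, list(seed = seed)))
      if (method == "boruta") run_boruta(train, cfg)
      else run_rboruta(train, cfg, n_random = config$n_random %||% 10000,
                       seed = seed + 1)
    },
    abort_("unknown selector method: ", method)
  )
}

#' Run the full selector benchmark
#'
#' For every repeat `r` a seed `base_seed + r * 10007` drives the whole
#' pipeline: preprocessing (split, low-variation filter, perfect-correlation
#' dedup, probe spiking, autoscaling), every requested selector, and — for
#' non-empty selections — the regression suite on the selected columns
#' (original and wrongly-selected probes alike, since that is what a model
#' built "on the selected variables" means). One record per
#' (method, repeat) is emitted; an empty selection yields a record with
#' both ratios 0 and `mae_p10 = NA`. A selector failure is caught, recorded
#' and does not abort the other selectors.
#'
#' @param dataset A [vsb_dataset()] or a [synthetic_spec()] (generated once
#'   from its own seed; repeats re-split and re-spike it).
#' @param selectors Named list: names in
#'   `{"lasso", "gapls", "gasvr", "boruta", "rboruta"}`, values are
#'   per-method config lists (possibly empty).
#' @param n_repeats Number of repeats (default 10).
#' @param base_seed Base seed; repeat `r` uses `base_seed + r * 10007`.
#' @param suite_profile `"paper"`, `"fast"`, or `"none"` to skip the
#'   regression suite (selection-ratio studies only).
#' @param preprocess_args Extra arguments passed to [preprocess()].
#' @return A data.frame with one row per (method, repeat): `method`,
#'   `repeat_`, `seed`, `n_original`, `n_selected_original`,
#'   `n_selected_random`, `ratio_selected`, `ratio_random`, `mae_p10`,
#'   `empty_selection`, `failed`. The per-run [selection_result()]s are
#'   attached as `attr(, "selections")` (a list keyed `method.repeat`),
#'   ground truth (when synthetic) as `attr(, "truth")`.
#' @export
run_benchmark <- function(dataset, selectors, n_repeats = 10, base_seed = 1,
                          suite_profile = c("fast", "paper", "none"),
                          preprocess_args = list()) {
  suite_profile <- match.arg(suite_profile)
  stopifnot(n_repeats >= 1, length(selectors) >= 1, !is.null(names(selectors)))
  truth <- NULL
  if (inherits(dataset, "synthetic_spec")) {
    gen <- generate_synthetic(dataset)
    truth <- gen$truth
    dataset <- gen$dataset
  }
  stopifnot(inherits(dataset, "vsb_dataset"))
  rows <- list()
  selections <- list()
  for (r in seq_len(n_repeats)) {
    seed_r <- base_seed + r * 10007
    pair <- do.call(preprocess, c(list(ds = dataset, seed = seed_r),
                                  preprocess_args))
    for (mi in seq_along(selectors)) {
      method <- names(selectors)[mi]
      sel_seed <- seed_r + 131 * mi
      rec <- list(method = method, repeat_ = r, seed = seed_r,
                  n_original = sum(pair$train$origin == "original"),
                  n_selected_original = NA_integer_,
                  n_selected_random = NA_integer_,
                  ratio_selected = NA_real_, ratio_random = NA_real_,
                  mae_p10 = NA_real_, empty_selection = FALSE, failed = FALSE)
      sel <- tryCatch(
        run_selector(method, pair$train, selectors[[mi]], sel_seed),
        error = function(e) {
          warning("selector '", method, "' failed in repeat ", r, ": ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(sel)) {
        rec$failed <- TRUE
      } else {
        selections[[paste0(method, ".", r)]] <- sel
        rec$n_selected_original <-
          sum(pair$train$origin[sel$selected] == "original")
        rec$n_selected_random <-
          sum(pair$train$origin[sel$selected] == "random_probe")
        rec$ratio_selected <- ratio_selected(sel, pair$train)
        rec$ratio_random <- ratio_random(sel, pair$train)
        if (!length(sel$selected)) {
          rec$empty_selection <- TRUE
        } else if (suite_profile != "none") {
          sr <- run_suite(pair, sel, profile = suite_profile, seed = sel_seed)
          rec$mae_p10 <- sr$mae_p10
        }
      }
      rows[[length(rows) + 1L]] <- rec
    }
  }
  out <- do.call(rbind, lapply(rows, function(x) as.data.frame(x)))
  attr(out, "selections") <- selections
  attr(out, "truth") <- truth
  attr(out, "base_seed") <- base_seed
  attr(out, "suite_profile") <- suite_profile
  out
}

#' Write benchmark records to disk
#'
#' Writes a tidy CSV (one row per record, fixed column order) and a JSON
#' sidecar carrying the base seed, suite profile and session versions.
#'
#' @param records Data frame from [run_benchmark()].
#' @param path Output CSV path; the sidecar replaces the extension with
#'   `.json`.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  if (!nrow(records)) abort_("no records to write")
  cols <- c("method", "repeat_", "seed", "n_original", "n_selected_original",
            "n_selected_random", "ratio_selected", "ratio_random", "mae_p10",
            "empty_selection", "failed")
  write.csv(records[, cols], path, row.names = FALSE)
  sidecar <- sub("\\.[^.]+$", ".json", path)
  jsonlite::write_json(
    list(base_seed = attr(records, "base_seed"),
         suite_profile = attr(records, "suite_profile"),
         n_records = nrow(records),
         package_version = as.character(utils::packageVersion("varselbench")),
         r_version = R.version.string),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Plot the three benchmark panels
#'
#' Scatter of the benchmark indicators across repeats, one point per
#' (method, repeat): (a) ratio of selected originals vs ratio of selected
#' probes, (b) ratio of selected originals vs 10th-percentile MAE,
#' (c) ratio of selected probes vs 10th-percentile MAE.
#'
#' @param records Data frame from [run_benchmark()].
#' @param panel One of `"selected_vs_random"`, `"selected_vs_mae"`,
#'   `"random_vs_mae"`.
#' @return A ggplot object.
#' @export
plot_benchmark <- function(records, panel = c("selected_vs_random",
                                              "selected_vs_mae",
                                              "random_vs_mae")) {
  panel <- match.arg(panel)
  if (!requireNamespace("ggplot2", quietly = TRUE))
    abort_("plot_benchmark needs the ggplot2 package")
  ax <- switch(panel,
    selected_vs_random = c("ratio_selected", "ratio_random"),
    selected_vs_mae = c("ratio_selected", "mae_p10"),
    random_vs_mae = c("ratio_random", "mae_p10"))
  ggplot2::ggplot(records,
                  ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]],
                               colour = .data$method)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = ax[1], y = ax[2]) +
    ggplot2::theme_minimal()
}
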