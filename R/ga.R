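# Genetic-algorithm wrapper selection: GAPLS (PLS fitness) and GASVR
# (Gaussian-kernel SVR fitness with three hyperparameter genes).

#' GA configuration
#'
#' Chromosomes are real vectors in \[0, 1\], one gene per variable
#' (GASVR appends three genes encoding log2 C, log2 epsilon and log2 gamma
#' of the SVR). Genes become an inclusion mask by thresholding at
#' `mask_threshold`. Fitness is the pooled out-of-fold cross-validated
#' \eqn{r^2} of the wrapped model on the masked columns.
#'
#' @param population_size,generations GA size; defaults 100 x 50.
#' @param crossover_prob Probability a mating pair undergoes uniform
#'   crossover (per-gene swap probability 0.5).
#' @param mutation_prob Per-gene probability of uniform reset; `NULL` means
#'   `1 / chromosome_length`.
#' @param mask_threshold Gene-to-mask cutoff in (0, 1); inclusion uses `>=`.
#' @param cv_folds Folds for the fitness CV.
#' @param max_pls_components Cap on PLS components (further capped by the
#'   masked column count and the fold sample count).
#' @param svr_gene_ranges List of three `c(lo, hi)` log2 ranges for the SVR
#'   genes `C`, `epsilon`, `gamma`.
#' @param tournament_size,elitism Selection pressure knobs.
#' @param seed Integer seed covering initialization and all operators.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 100, generations = 50,
                      crossover_prob = 0.9, mutation_prob = NULL,
                      mask_threshold = 0.5, cv_folds = 5,
                      max_pls_components = 30,
                      svr_gene_ranges = list(C = c(-5, 10), epsilon = c(-10, 0),
                                             gamma = c(-20, 10)),
                      tournament_size = 3, elitism = 1, seed = 1) {
  stopifnot(population_size >= 2, generations >= 1,
            crossover_prob >= 0, crossover_prob <= 1,
            mask_threshold > 0, mask_threshold < 1)
  if (!is.null(mutation_prob))
    stopifnot(mutation_prob >= 0, mutation_prob <= 1)
  structure(list(population_size = population_size, generations = generations,
                 crossover_prob = crossover_prob, mutation_prob = mutation_prob,
                 mask_threshold = mask_threshold, cv_folds = cv_folds,
                 max_pls_components = max_pls_components,
                 svr_gene_ranges = svr_gene_ranges,
                 tournament_size = tournament_size, elitism = elitism,
                 seed = seed),
            class = "ga_config")
}

#' Decode a chromosome into an inclusion mask
#'
#' @param genes Numeric gene vector in \[0, 1\].
#' @param threshold Cutoff in (0, 1); gene `>=` threshold means included.
#' @param n_vars Number of variable genes (defaults to all genes; GASVR
#'   passes its chromosome length minus 3).
#' @return Logical vector of length `n_vars`.
#' @export
decode_mask <- function(genes, threshold = 0.5, n_vars = length(genes)) {
  stopifnot(threshold > 0, threshold < 1, n_vars <= length(genes))
  genes[seq_len(n_vars)] >= threshold
}

#' Decode the three SVR hyperparameter genes
#'
#' Each trailing gene maps onto `2^(lo + gene * (hi - lo))` of its log2
#' range, giving strictly positive C, epsilon and gamma.
#'
#' @param genes Chromosome with three trailing hyperparameter genes.
#' @param ranges List of three `c(lo, hi)` log2 ranges.
#' @return Named numeric vector `c(C = , epsilon = , gamma = )`.
#' @export
decode_svr_params <- function(genes, ranges = ga_config()$svr_gene_ranges) {
  stopifnot(length(genes) >= 3, length(ranges) == 3)
  for (r in ranges) if (r[1] >= r[2])
    abort_("each svr gene range needs lo < hi",
           class = "varselbench_config_error")
  g <- genes[(length(genes) - 2):length(genes)]
  vals <- vapply(seq_len(3), function(i) {
    lo <- ranges[[i]][1]; hi <- ranges[[i]][2]
    2^(lo + g[i] * (hi - lo))
  }, numeric(1))
  setNames(vals, c("C", "epsilon", "gamma"))
}

# Pooled out-of-fold r2 of PLS on the masked columns; the component count
# is chosen internally by the same CV (mixOmics returns predictions for
# every component count in one pass). With a single column, one-component
# PLS is ordinary least squares on that column.
cv_r2_pls <- function(X, y, folds, max_comp) {
  n <- length(y)
  if (ncol(X) == 1) {
    oof <- numeric(n)
    for (k in sort(unique(folds))) {
      in_k <- folds == k
      cf <- coef(lsfit(X[!in_k, 1], y[!in_k]))
      oof[in_k] <- cf[1] + cf[2] * X[in_k, 1]
    }
    return(list(r2 = pooled_r2(y, oof), ncomp = 1L))
  }
  A <- min(max_comp, ncol(X), n - ceiling(n / max(folds)) - 1)
  A <- max(A, 1)
  oof <- array(NA_real_, c(n, A))
  for (k in sort(unique(folds))) {
    in_k <- folds == k
    a_k <- min(A, nrow(X) - sum(in_k) - 1, ncol(X))
    a_k <- max(a_k, 1)
    fit <- mixOmics::pls(X[!in_k, , drop = FALSE], y[!in_k], ncomp = a_k,
                         mode = "regression", scale = FALSE)
    pr <- predict(fit, X[in_k, , drop = FALSE])$predict
    for (a in seq_len(A)) oof[in_k, a] <- pr[, 1, min(a, a_k)]
  }
  r2 <- apply(oof, 2, function(p) pooled_r2(y, p))
  list(r2 = max(r2), ncomp = which.max(r2))
}

#' GAPLS fitness of a variable mask
#'
#' Pooled out-of-fold CV \eqn{r^2} of a PLS regression restricted to the
#' masked columns, maximized over the PLS component count. An empty mask
#' scores `-Inf`.
#'
#' @param mask Logical inclusion vector over the training columns.
#' @param train Autoscaled training [vsb_dataset()].
#' @param cfg A [ga_config()].
#' @return A single fitness value (larger is better).
#' @export
fitness_gapls <- function(mask, train, cfg = ga_config()) {
  if (!any(mask)) return(-Inf)
  folds <- make_folds(nrow(train$X), cfg$cv_folds, cfg$seed)
  cv_r2_pls(train$X[, mask, drop = FALSE], train$y, folds,
            cfg$max_pls_components)$r2
}

#' GASVR fitness of a chromosome
#'
#' Decodes the variable mask and the three SVR genes, then returns the
#' pooled out-of-fold CV \eqn{r^2} of a Gaussian-kernel epsilon-SVR with the
#' decoded (C, epsilon, gamma) on the masked columns. An empty mask scores
#' `-Inf`.
#'
#' @param chrom Chromosome of length `n_vars + 3`.
#' @param train Autoscaled training [vsb_dataset()].
#' @param cfg A [ga_config()].
#' @return A single fitness value.
#' @export
fitness_gasvr <- function(chrom, train, cfg = ga_config()) {
  p <- ncol(train$X)
  stopifnot(length(chrom) == p + 3)
  mask <- decode_mask(chrom, cfg$mask_threshold, p)
  if (!any(mask)) return(-Inf)
  par <- decode_svr_params(chrom, cfg$svr_gene_ranges)
  X <- train$X[, mask, drop = FALSE]
  folds <- make_folds(nrow(X), cfg$cv_folds, cfg$seed)
  oof <- numeric(length(train$y))
  for (k in sort(unique(folds))) {
    in_k <- folds == k
    fit <- e1071::svm(X[!in_k, , drop = FALSE], train$y[!in_k],
                      type = "eps-regression", kernel = "radial",
                      cost = par["C"], epsilon = par["epsilon"],
                      gamma = par["gamma"], scale = FALSE)
    oof[in_k] <- predict(fit, X[in_k, , drop = FALSE])
  }
  pooled_r2(train$y, oof)
}

#' Run GA wrapper variable selection
#'
#' Seeded generational GA — tournament selection, uniform crossover,
#' per-gene uniform-reset mutation, elitism — maximizing [fitness_gapls()]
#' (`mode = "gapls"`) or [fitness_gasvr()] (`mode = "gasvr"`). Fitness
#' values are cached by decoded mask (and decoded SVR parameters), so
#' duplicate individuals cost nothing. Because of elitism the best fitness
#' is monotone non-decreasing across generations.
#'
#' @param train Autoscaled training [vsb_dataset()].
#' @param mode `"gapls"` or `"gasvr"`.
#' @param cfg A [ga_config()].
#' @return A [selection_result()]; `meta` holds `best_fitness`, the
#'   per-generation `history` (length `generations + 1`, starting from the
#'   initial population), and for GASVR the decoded `svr_params`.
#' @export
run_ga <- function(train, mode = c("gapls", "gasvr"), cfg = ga_config()) {
  mode <- match.arg(mode)
  stopifnot(inherits(train, "vsb_dataset"))
  p <- ncol(train$X)
  len <- if (mode == "gasvr") p + 3 else p
  pmut <- cfg$mutation_prob %||% (1 / len)
  cache <- new.env(parent = emptyenv())

  evaluate <- function(chrom) {
    mask <- decode_mask(chrom, cfg$mask_threshold, p)
    key <- paste(c(as.integer(mask),
                   if (mode == "gasvr")
                     signif(decode_svr_params(chrom, cfg$svr_gene_ranges), 12)),
                 collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- if (mode == "gapls") fitness_gapls(mask, train, cfg)
         else fitness_gasvr(chrom, train, cfg)
    cache[[key]] <- f
    f
  }

  with_seed_(cfg$seed, {
    pop <- matrix(runif(cfg$population_size * len), nrow = cfg$population_size)
    fit <- apply(pop, 1, evaluate)
    history <- max(fit)
    for (gen in seq_len(cfg$generations)) {
      elite_i <- order(fit, decreasing = TRUE)[seq_len(cfg$elitism)]
      offspring <- matrix(NA_real_, cfg$population_size, len)
      offspring[seq_len(cfg$elitism), ] <- pop[elite_i, , drop = FALSE]
      i <- cfg$elitism
      while (i < cfg$population_size) {
        tour <- function() {
          cand <- sample.int(cfg$population_size, cfg$tournament_size,
                             replace = TRUE)
          pop[cand[which.max(fit[cand])], ]
        }
        c1 <- tour(); c2 <- tour()
        if (runif(1) < cfg$crossover_prob) {
          swap <- runif(len) < 0.5
          tmp <- c1[swap]; c1[swap] <- c2[swap]; c2[swap] <- tmp
        }
        for (child in list(c1, c2)) {
          if (i >= cfg$population_size) break
          mut <- runif(len) < pmut
          child[mut] <- runif(sum(mut))
          i <- i + 1
          offspring[i, ] <- child
        }
      }
      pop <- offspring
      fit <- apply(pop, 1, evaluate)
      history <- c(history, max(fit))
    }
    best <- pop[which.max(fit), ]
    mask <- decode_mask(best, cfg$mask_threshold, p)
    meta <- list(best_fitness = max(fit), history = history, seed = cfg$seed,
                 generations = cfg$generations,
                 population_size = cfg$population_size)
    if (mode == "gasvr")
      meta$svr_params <- decode_svr_params(best, cfg$svr_gene_ranges)
    selection_result(mode, which(mask), colnames(train$X), meta = meta)
  })
}
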