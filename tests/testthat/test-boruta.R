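test_that("shadow columns are per-column permutations unrelated to y", {
  withr::with_seed(3, {
    X <- cbind(a = rnorm(200), b = runif(200), const = rep(2, 200))
  })
  S <- make_shadow(X, seed = 11)
  expect_equal(dim(S), dim(X))
  expect_equal(colnames(S), paste0("shadow_", colnames(X)))
  for (j in 1:3) expect_equal(sort(S[, j]), sort(X[, j]))
  expect_equal(S[, "shadow_const"], X[, "const"], ignore_attr = TRUE)
  # a column perfectly correlated with y decorrelates once shuffled
  y <- X[, "a"]
  expect_lt(abs(cor(S[, "shadow_a"], y)), 0.3)
  expect_identical(make_shadow(X, seed = 11), S)
})

test_that("hits require strictly exceeding the shadow percentile", {
  shadows <- c(0.1, 0.2, 0.3)
  expect_true(hit_update(c(0.31, 0, 0, shadows), 3, 100)[1])
  expect_false(hit_update(c(0.30, 0, 0, shadows), 3, 100)[1]) # boundary: not a hit
  # p = 50: reference is the median 0.2
  expect_true(hit_update(c(0.25, 0, 0, shadows), 3, 50)[1])
  # lowering the percentile never converts a hit into a non-hit
  imps <- withr::with_seed(4, runif(20))
  for (p in c(100, 80, 60, 40, 20)) {
    hi <- hit_update(imps, 10, p)
    lo <- hit_update(imps, 10, p / 2)
    expect_true(all(lo[hi]))
  }
})

test_that("binomial decisions match exact tail enumeration for all n <= 25", {
  # independent oracle: direct summation of Binomial(n, 1/2) tail masses
  tail_ge <- function(h, n) sum(choose(n, h:n)) / 2^n
  tail_le <- function(h, n) sum(choose(n, 0:h)) / 2^n
  alpha <- 0.05
  for (n in 1:25) {
    for (h in 0:n) {
      expected <- if (tail_ge(h, n) < alpha / 2) "confirmed"
                  else if (tail_le(h, n) < alpha / 2) "rejected"
                  else "tentative"
      expect_identical(binomial_decision(h, n, alpha), expected)
    }
  }
  expect_identical(binomial_decision(20, 20), "confirmed")
  expect_identical(binomial_decision(0, 20), "rejected")
  expect_identical(binomial_decision(10, 20), "tentative")
  expect_error(binomial_decision(0, 0), "trials")
})

test_that("Boruta confirms informative variables and rejects noise", {
  spec <- synthetic_spec(n_samples = 300, n_informative = 2, n_noise = 8,
                         coefficients = c(1, 1), within_block_correlation = 0,
                         noise_sd = 0.5, seed = 99)
  gen <- generate_synthetic(spec)
  confirmed_both <- 0L
  for (s in 1:5) {
    pair <- preprocess(gen$dataset, spike = FALSE, seed = 100 + s)
    res <- run_boruta(pair$train,
                      boruta_config(rf_trees = 300, max_iter = 50, seed = s))
    st <- res$status[c("x1", "x2")]
    if (all(st == "confirmed")) confirmed_both <- confirmed_both + 1L
    # contract: hits bounded by trials, statuses partition the columns
    expect_true(all(res$meta$hits >= 0 & res$meta$hits <= res$meta$trials))
    expect_true(all(res$status %in% c("confirmed", "rejected", "tentative")))
    # mostly rejects pure noise
    expect_lt(sum(res$status[paste0("x", 3:10)] == "confirmed"), 3)
  }
  expect_gte(confirmed_both, 4L)
})

test_that("tentative columns are excluded under the default policy", {
  fx <- linear_pair(n = 60, p_inf = 2, p_noise = 6,
                    coefficients = c(0.6, 0.4), noise_sd = 1, seed = 55)
  res <- run_boruta(fx$pair$train,
                    boruta_config(rf_trees = 100, max_iter = 5, seed = 2))
  expect_true(any(res$status == "tentative")) # 5 iterations cannot settle all
  expect_false(any(res$selected %in% which(res$status == "tentative")))
  inc <- run_boruta(fx$pair$train,
                    boruta_config(rf_trees = 100, max_iter = 5, seed = 2,
                                  tentative_policy = "include"))
  expect_true(all(which(inc$status != "rejected") %in% inc$selected))
})

test_that("the chance-correlation percentile behaves as max |r| times 100", {
  y <- withr::with_seed(7, rnorm(50))
  p <- rboruta_percentile(y, n_random = 10000, seed = 1)
  expect_identical(p, rboruta_percentile(y, n_random = 10000, seed = 1))
  expect_lte(p, 100)
  expect_gt(p, 0)
  # at n = 50 the maximum of 10000 absolute sample correlations between
  # independent normals concentrates around sqrt(2 log 20000 / n)
  for (s in 1:3) {
    ps <- rboruta_percentile(y, n_random = 10000, seed = s)
    expect_gt(ps, 40)
    expect_lt(ps, 70)
  }
  expect_error(rboruta_percentile(rep(1, 50)), "constant")
  expect_error(rboruta_percentile(rnorm(50), n_random = 10), "n_random")
})

test_that("r-Boruta records its calibrated percentile below 100 at small n", {
  fx <- linear_pair(n = 40, p_inf = 2, p_noise = 4, coefficients = c(2, 1),
                    noise_sd = 0.5, seed = 13)
  res <- run_rboruta(fx$pair$train,
                     boruta_config(rf_trees = 100, max_iter = 20, seed = 3),
                     n_random = 2000, seed = 8)
  expect_identical(res$method, "rboruta")
  expect_lt(res$meta$percentile, 100)
  expect_gt(res$meta$percentile, 0)
})
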