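test_that("load_table reads a CSV back and validates its cells", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("y,a,b", "1,2,3", "2,4,6", "3,6,9", "4,8,12"), f)
  ds <- load_table(f, "y")
  expect_s3_class(ds, "vsb_dataset")
  expect_equal(dim(ds), c(4L, 2L))
  expect_equal(ds$y, 1:4)
  expect_equal(unname(ds$X[, "a"]), c(2, 4, 6, 8))
  expect_true(all(ds$origin == "original"))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("y,a,a", "1,2,3"), f2)
  expect_error(load_table(f2, "y"), "duplicate column names")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("y,a,b", "1,2,3", "2,4,"), f3)
  err <- expect_error(load_table(f3, "y"), "column 'b', row 2")
  expect_s3_class(err, "varselbench_parse_error")

  expect_error(load_table(f, "nope"), "target column")
})

test_that("split assigns round(fraction * n) training samples, reproducibly", {
  ds <- withr::with_seed(1, vsb_dataset(matrix(rnorm(3000), 1000), rnorm(1000)))
  pair <- split_train_test(ds, 0.7, seed = 3)
  expect_equal(nrow(pair$train$X), 700L)
  expect_equal(nrow(pair$test$X), 300L)

  ds10 <- withr::with_seed(2, vsb_dataset(matrix(rnorm(20), 10), rnorm(10)))
  a <- split_train_test(ds10, 0.7, seed = 11)
  b <- split_train_test(ds10, 0.7, seed = 11)
  expect_identical(a$train$X, b$train$X)
  c_ <- split_train_test(ds10, 0.7, seed = 12)
  expect_false(identical(a$train$y, c_$train$y))

  tiny <- vsb_dataset(matrix(rnorm(8), 4), rnorm(4))
  expect_error(split_train_test(tiny, 0.7, 1), "at least 5")
})

test_that("low-variation filter drops columns by train mode frequency", {
  # mode frequency 8/10 = 0.8 -> dropped at the default threshold;
  # 10 distinct values -> kept; constant -> dropped
  Xtr <- cbind(mod8 = c(1, 1, 1, 1, 1, 1, 1, 1, 2, 3),
               uniq = 1:10,
               const = rep(5, 10))
  pair <- make_pair(Xtr, rnorm(10))
  filtered <- filter_low_variation(pair)
  expect_equal(colnames(filtered$train$X), "uniq")
  expect_equal(colnames(filtered$test$X), "uniq")

  # idempotent
  again <- filter_low_variation(filtered)
  expect_identical(again$train$X, filtered$train$X)

  expect_error(filter_low_variation(make_pair(Xtr[, 3, drop = FALSE],
                                              rnorm(10))),
               "all columns")
})

test_that("perfect-correlation dedup keeps first occurrences only", {
  a <- withr::with_seed(4, rnorm(30))
  noise <- withr::with_seed(5, rnorm(30, sd = 0.3))
  Xtr <- cbind(a = a, double_a = 2 * a, neg_a = -a, near_a = a + noise)
  expect_lt(abs(cor(a, a + noise)), 1 - 1e-12) # near_a genuinely imperfect
  pair <- dedup_perfect_correlation(make_pair(Xtr, rnorm(30)))
  expect_equal(colnames(pair$train$X), c("a", "near_a"))
  # idempotent
  expect_identical(dedup_perfect_correlation(pair)$train$X, pair$train$X)
})

test_that("spiking doubles the column count with seeded uniform probes", {
  spec <- synthetic_spec(n_samples = 500, n_informative = 5, n_noise = 5,
                         coefficients = rep(1, 5), seed = 21)
  ds <- generate_synthetic(spec)$dataset
  raw <- split_train_test(ds, 0.7, seed = 2)
  spiked <- spike_random_variables(raw, seed = 7)
  expect_equal(ncol(spiked$train$X), 20L)
  expect_equal(sum(spiked$train$origin == "random_probe"), 10L)
  expect_identical(spiked$train$X,
                   spike_random_variables(raw, seed = 7)$train$X)
  # probes unrelated to y: |r| below 3/sqrt(n) for every probe
  probe_cols <- spiked$train$origin == "random_probe"
  r <- abs(cor(spiked$train$X[, probe_cols], spiked$train$y))
  expect_lt(max(r), 3 / sqrt(nrow(spiked$train$X)))
  # double spiking is rejected
  expect_error(spike_random_variables(spiked, seed = 8), "random_probe")
})

test_that("autoscaling uses train statistics and round-trips y", {
  spec <- synthetic_spec(n_samples = 100, n_informative = 3, n_noise = 2,
                         coefficients = c(1, 2, 3), seed = 31)
  ds <- generate_synthetic(spec)$dataset
  pair <- autoscale(split_train_test(ds, 0.7, seed = 13))
  expect_equal(unname(colMeans(pair$train$X)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(pair$train$X, 2, sd)), rep(1, 5),
               tolerance = 1e-12)
  # test columns scaled with TRAIN stats: mean generally differs from 0
  expect_gt(max(abs(colMeans(pair$test$X))), 0.01)
  # inverse transform recovers original y
  orig <- split_train_test(ds, 0.7, seed = 13)
  expect_equal(unscale_y(pair$train$y, pair), orig$train$y, tolerance = 1e-12)
})

test_that("the preprocessing pipeline spikes to twice the surviving columns", {
  spec <- synthetic_spec(n_samples = 80, n_informative = 4, n_noise = 6,
                         coefficients = rep(1, 4), seed = 77)
  ds <- generate_synthetic(spec)$dataset
  pair <- preprocess(ds, seed = 3)
  expect_equal(ncol(pair$train$X), 20L)
  expect_equal(sum(pair$train$origin == "original"),
               sum(pair$train$origin == "random_probe"))
  expect_identical(colnames(pair$train$X), colnames(pair$test$X))
})
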