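test_that("selection ratios divide by the original column count", {
  nm <- c(paste0("x", 1:75), paste0("rand_", 1:75))
  ds <- withr::with_seed(1, vsb_dataset(matrix(rnorm(10 * 150), 10,
                                               dimnames = list(NULL, nm)),
                                        rnorm(10),
                                        rep(c("original", "random_probe"),
                                            each = 75)))
  sel <- selection_result("m", c(1:30, 76:90), nm)
  expect_equal(ratio_selected(sel, ds), 30 / 75) # 0.4
  expect_equal(ratio_random(sel, ds), 15 / 75)   # 0.2
  all_orig <- selection_result("m", 1:75, nm)
  expect_equal(ratio_selected(all_orig, ds), 1)
  expect_equal(ratio_random(all_orig, ds), 0)
  none <- suppressWarnings(selection_result("m", integer(0), nm))
  expect_equal(ratio_selected(none, ds), 0)
  # probes missing -> error
  ds_orig <- withr::with_seed(2, vsb_dataset(matrix(rnorm(50), 10), rnorm(10)))
  expect_error(ratio_random(selection_result("m", 1:2,
                                             colnames(ds_orig$X)), ds_orig),
               "no random_probe")
})

test_that("run_benchmark emits one consistent record per method and repeat", {
  spec <- synthetic_spec(n_samples = 60, n_informative = 3, n_noise = 7,
                         coefficients = c(2, 1.5, 1), noise_sd = 0.5, seed = 5)
  selectors <- list(lasso = list(),
                    boruta = list(rf_trees = 100, max_iter = 20))
  rec <- run_benchmark(spec, selectors, n_repeats = 3, base_seed = 7,
                       suite_profile = "none")
  expect_equal(nrow(rec), 6L)
  expect_setequal(rec$method, c("lasso", "boruta"))
  expect_equal(unname(table(rec$method)), c(3L, 3L), ignore_attr = TRUE)
  expect_true(all(rec$ratio_selected >= 0 & rec$ratio_selected <= 1))
  expect_true(all(rec$ratio_random >= 0 & rec$ratio_random <= 1))
  expect_true(all(is.na(rec$mae_p10))) # suite disabled
  # counts consistent with the stored selections
  sels <- attr(rec, "selections")
  for (i in seq_len(nrow(rec))) {
    s <- sels[[paste0(rec$method[i], ".", rec$repeat_[i])]]
    expect_equal(rec$n_selected_original[i] + rec$n_selected_random[i],
                 length(s$selected))
  }
  # end-to-end determinism
  rec2 <- run_benchmark(spec, selectors, n_repeats = 3, base_seed = 7,
                        suite_profile = "none")
  expect_identical(rec, rec2)
})

test_that("an empty selection yields a flagged record, not an abort", {
  spec <- synthetic_spec(n_samples = 60, n_informative = 2, n_noise = 4,
                         coefficients = c(1, 1), seed = 9)
  rec <- suppressWarnings(
    run_benchmark(spec, list(lasso = list(lambda_grid = 1e6)),
                  n_repeats = 2, base_seed = 3, suite_profile = "fast"))
  expect_equal(nrow(rec), 2L)
  expect_true(all(rec$empty_selection))
  expect_true(all(rec$ratio_selected == 0))
  expect_true(all(is.na(rec$mae_p10)))
})

test_that("benchmark records attach a suite MAE in original units", {
  spec <- synthetic_spec(n_samples = 80, n_informative = 3, n_noise = 5,
                         coefficients = c(3, 2, 1), noise_sd = 0.5, seed = 11)
  rec <- run_benchmark(spec, list(lasso = list()), n_repeats = 1,
                       base_seed = 2, suite_profile = "fast")
  expect_false(is.na(rec$mae_p10))
  expect_gt(rec$mae_p10, 0)
  expect_lt(rec$mae_p10, 3) # far below the response spread (~sd 4)
})

test_that("results round-trip through CSV with a JSON sidecar", {
  spec <- synthetic_spec(n_samples = 60, n_informative = 2, n_noise = 3,
                         coefficients = c(2, 1), seed = 4)
  rec <- run_benchmark(spec, list(lasso = list()), n_repeats = 2,
                       base_seed = 5, suite_profile = "none")
  path <- withr::local_tempfile(fileext = ".csv")
  write_results(rec, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 2L)
  expect_equal(back$ratio_selected, rec$ratio_selected, tolerance = 1e-15)
  expect_equal(back$ratio_random, rec$ratio_random, tolerance = 1e-15)
  side <- jsonlite::read_json(sub("\\.csv$", ".json", path))
  expect_equal(side$base_seed, 5L)
  expect_equal(side$n_records, 2L)
})

test_that("selection results serialize to JSON", {
  sel <- selection_result("lasso", c(1, 3), c("a", "b", "c"),
                          meta = list(lambda = 0.25))
  path <- withr::local_tempfile(fileext = ".json")
  write_selection(sel, path)
  back <- jsonlite::read_json(path)
  expect_equal(unlist(back$selected), c("a", "c"))
  expect_equal(back$meta$lambda, 0.25)
  expect_equal(back$status$b, "rejected")
})
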