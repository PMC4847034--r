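test_that("folds partition the chemicals into balanced random portions", {
  folds <- make_folds(125, 5, seed = 3)
  expect_equal(lengths(folds), rep(25L, 5))
  expect_setequal(unlist(folds), 1:125)

  uneven <- make_folds(7, 5, seed = 3)
  expect_equal(sort(lengths(uneven), decreasing = TRUE), c(2L, 2L, 1L, 1L, 1L))
  expect_setequal(unlist(uneven), 1:7)

  expect_identical(make_folds(40, 5, seed = 9), make_folds(40, 5, seed = 9))
  expect_error(make_folds(4, 5), "fewer chemicals")
})

test_that("stratified folds preserve the class balance", {
  labels <- c(rep(1L, 20), rep(0L, 30))
  folds <- make_folds(50, 5, labels = labels, seed = 2)
  expect_setequal(unlist(folds), 1:50)
  for (f in folds) expect_equal(sum(labels[f] == 1L), 4L)
})

test_that("cross-validation covers every chemical once per repeat", {
  g <- generate_synthetic_dataset(small_spec())
  cv <- cross_validate(g$dataset, n_repeats = 3, seed = 5)
  for (r in 1:3) {
    rep_preds <- cv$predictions[cv$predictions$repeat_index == r, ]
    expect_setequal(rep_preds$chemical_id, g$dataset$chemical_ids)
    expect_equal(nrow(rep_preds), 60)
  }
  expect_length(cv$model_descriptors, 3 * 5)
  expect_equal(dim(cv$repeat_metrics), c(3L, 5L))
})

test_that("well-separated noiseless data is cross-validated near-perfectly", {
  spec <- small_spec(signal_strength = 8)
  g <- generate_synthetic_dataset(spec)
  cv <- cross_validate(g$dataset, n_repeats = 3, seed = 8)
  expect_gte(mean(cv$repeat_metrics$accuracy), 0.97)
})

test_that("cross-validation reruns are identical under a fixed seed", {
  g <- generate_synthetic_dataset(small_spec())
  cv1 <- cross_validate(g$dataset, n_repeats = 2, seed = 123)
  cv2 <- cross_validate(g$dataset, n_repeats = 2, seed = 123)
  expect_identical(cv1$predictions, cv2$predictions)
  expect_identical(cv1$repeat_metrics, cv2$repeat_metrics)
  expect_identical(cv1$model_descriptors, cv2$model_descriptors)
})

test_that("validation helpers leave the caller's RNG stream untouched", {
  g <- generate_synthetic_dataset(small_spec())
  set.seed(77)
  before <- runif(1)
  set.seed(77)
  invisible(cross_validate(g$dataset, n_repeats = 1, seed = 4))
  expect_identical(runif(1), before)
})

test_that("permutation runs are reproducible and sized correctly", {
  g <- generate_synthetic_dataset(small_spec())
  pm1 <- permutation_test(g$dataset, n_permutations = 3, seed = 6)
  pm2 <- permutation_test(g$dataset, n_permutations = 3, seed = 6)
  expect_identical(pm1$metrics, pm2$metrics)
  expect_equal(nrow(pm1$metrics), 3)
  expect_length(pm1$model_descriptors, 3 * 5)
  expect_error(permutation_test(g$dataset, n_permutations = 0), ">= 1")
})

test_that("the empirical p-value uses the add-one rule", {
  expect_equal(perm_p_value(c(0.4, 0.5, 0.6), 0.7), 1 / 4)
  expect_equal(perm_p_value(c(0.4, 0.5, 0.6), 0.5), 3 / 4)
  expect_equal(perm_p_value(rep(0.9, 99), 0.1), 1)
})

test_that("confidence bins are even, half-open, and conserve predictions", {
  preds <- data.frame(
    confidence = c(0, 0.04999, 0.05, 0.5, 0.949, 0.95, 1, 1),
    call = c(1, 1, 0, 0, 1, 1, 0, 1),
    actual = c(1, 0, 0, 1, 1, 0, 0, 0))
  prof <- confidence_profile(preds)
  expect_equal(nrow(prof), 20)
  expect_equal(sum(prof$n), nrow(preds))
  expect_equal(prof$n_correct + prof$n_incorrect, prof$n)
  expect_equal(prof$n[1], 2)    # 0 and 0.04999
  expect_equal(prof$n[2], 1)    # 0.05 opens the second bin
  expect_equal(prof$n[20], 3)   # 0.95, 1, 1: last bin is closed
  expect_equal(prof$accuracy[1], 0.5)
  expect_true(is.na(prof$accuracy[10]))
})

test_that("the permutation background threshold flags strict exceedances", {
  # all background frequencies equal, one descriptor one model higher
  universe <- paste0("D", 1:10)
  perm_usage <- rep(list(universe[1:5]), 8)      # D1..D5 in all 8 models
  cv_usage <- c(rep(list(universe[1:5]), 8), list("D1"))
  imp <- informative_descriptors(cv_usage, perm_usage,
                                 descriptors = universe)
  expect_equal(attr(imp, "threshold"), 8)
  expect_equal(imp$descriptor[imp$informative], "D1")

  # identical usage in both arms -> at most ~alpha of descriptors flagged
  set.seed(44)
  usage <- replicate(60, sample(universe, 3), simplify = FALSE)
  null_imp <- informative_descriptors(usage, usage, alpha = 0.05,
                                      descriptors = universe)
  expect_lte(sum(null_imp$informative), 1)

  expect_error(informative_descriptors(list("X9"), usage,
                                       descriptors = universe),
               "X9")
  expect_error(informative_descriptors(list(), usage), "non-empty")
})
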