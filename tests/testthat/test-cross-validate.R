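test_that("an exact learner yields R^2 = 1 in every fold", {
  # targets constructed as an exact linear function of the inputs, so the
  # linear learner acts as an oracle for the generating function
  configs <- sample_configs(12, seed = 21)
  samples <- lapply(configs, function(cf) {
    tt <- seq(0, 10000, length.out = 100)
    inp <- config_inputs(cf)
    v <- 0.01 * inp[["side_length"]] - 0.001 * tt + 0.002 * inp[["ampa_density"]]
    data.frame(config_id = cf$config_id, time_us = tt, percent_open = v,
               section = rep(c("peak", "tail"), each = 50))
  })
  folds <- make_folds(1:12, k = 4, seed = 2)
  rep <- cross_validate(configs, samples, folds, learner_linear())
  expect_true(all(abs(rep$per_fold$r2 - 1) < 1e-9))
  expect_true(all(rep$per_fold$rmse < 1e-6))
})

test_that("no configuration leaks between train and test in any fold", {
  sc <- small_corpus()
  folds <- make_folds(1:20, k = 5, seed = 31)
  rep <- cross_validate(sc$configs, sc$samples, folds, learner_linear())
  # every configuration predicted exactly once, by its assigned fold
  by_cfg <- unique(rep$predictions[, c("config_id", "fold")])
  expect_identical(nrow(by_cfg), 20L)
  expect_identical(by_cfg$fold[order(by_cfg$config_id)],
                   unname(folds[as.character(1:20)]))
  # union of test sets is the whole corpus and folds are disjoint
  expect_identical(sort(unique(rep$predictions$config_id)), 1:20)
  expect_identical(sum(rep$per_fold$n), nrow(rep$predictions))
})

test_that("missing samples and unknown folds are reported", {
  sc <- small_corpus()
  folds <- make_folds(1:19, k = 5, seed = 1)
  expect_error(cross_validate(sc$configs, sc$samples, folds, learner_linear()),
               "missing configuration")
  samples <- sc$samples
  samples[3] <- list(NULL)
  expect_error(cross_validate(sc$configs, samples,
                              make_folds(1:20, 5, 1), learner_linear()),
               "missing curve sample")
})

test_that("the model tree generalizes across held-out configurations", {
  sc <- small_corpus()
  folds <- make_folds(1:20, k = 5, seed = 31)
  rep <- cross_validate(sc$configs, sc$samples, folds, learner_model_tree(),
                        seed = 77)
  expect_gt(rep$aggregate$r2_mean, 0.9)
  # metric scale: RMSE in percentage points of the 0-100 open fraction
  expect_lt(rep$aggregate$rmse_mean, 10)
  expect_gt(rep$aggregate$rmse_mean, 0)
})
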