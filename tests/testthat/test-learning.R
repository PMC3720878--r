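test_that("RMSE and R^2 match hand arithmetic", {
  expect_identical(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  # SS_res = 2, SS_tot = 2
  expect_equal(rmse(c(0, 1, 2), c(1, 1, 1)), sqrt(2 / 3))
  expect_equal(r_squared(c(0, 1, 2), c(1, 1, 1)), 0)
  expect_identical(rmse(c(0, 0), c(1, 1)), 1)
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "constant")
})

test_that("fold assignment partitions configurations evenly and reproducibly", {
  f <- make_folds(1:1000, k = 10, seed = 4)
  expect_identical(sort(unique(as.integer(f))), 1:10)
  expect_true(all(table(f) == 100))
  expect_identical(sort(as.integer(names(f))), 1:1000)
  expect_identical(make_folds(1:1000, k = 10, seed = 4), f)
  expect_false(identical(make_folds(1:1000, k = 10, seed = 5), f))
  # uneven sizes differ by at most one
  f2 <- make_folds(1:23, k = 5, seed = 1)
  expect_lte(diff(range(table(f2))), 1)
  expect_error(make_folds(1, k = 2), "folds")
  expect_error(make_folds(c(1, 1, 2), k = 2), "unique")
})

test_that("model tree reproduces a noiseless piecewise-linear target exactly", {
  x <- matrix(seq(0, 1, length.out = 200), ncol = 1)
  y <- ifelse(x[, 1] < 0.437, 2 * x[, 1], 2 * 0.437 - 4 * (x[, 1] - 0.437))
  tree <- train_model_tree(x, y, m5_control(min_leaf = 2, stop_fraction = 0,
                                            smoothing = 0))
  expect_lt(rmse(y, predict(tree, x)), 1e-6)
})

test_that("constant targets give a single-leaf constant model", {
  tree <- train_model_tree(matrix(runif(20), ncol = 2), rep(5, 10))
  expect_true(tree$root$leaf)
  expect_equal(predict(tree, matrix(c(-3, 100), 1)), 5)
})

test_that("identical inputs with varying targets degrade to a single leaf with warning", {
  x <- matrix(1, nrow = 10, ncol = 2)
  expect_warning(tree <- train_model_tree(x, rnorm(10)), "single-leaf")
  expect_true(tree$root$leaf)
})

test_that("first split maximizes SDR against brute-force enumeration", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(6:12, 1)
    x <- matrix(round(runif(n), 2), ncol = 1)
    y <- round(rnorm(n), 2)
    tree <- train_model_tree(x, y, m5_control(min_leaf = 1, stop_fraction = 0,
                                              prune = FALSE))
    if (tree$root$leaf) next
    xs <- sort(unique(x[, 1]))
    if (length(xs) < 2) next
    cand <- (xs[-1] + xs[-length(xs)]) / 2
    best_brute <- max(vapply(cand, function(th) sd_reduction(x[, 1], y, th), 1))
    got <- sd_reduction(x[, 1], y, tree$root$threshold)
    expect_equal(got, best_brute, tolerance = 1e-12)
  }
})

test_that("pruning never grows the tree", {
  set.seed(3)
  x <- matrix(runif(400), ncol = 2)
  y <- sin(4 * x[, 1]) + 0.5 * x[, 2] + rnorm(200, sd = 0.2)
  n_pruned <- synsurr:::.count_nodes(
    train_model_tree(x, y, m5_control(prune = TRUE))$root)[["nodes"]]
  n_full <- synsurr:::.count_nodes(
    train_model_tree(x, y, m5_control(prune = FALSE))$root)[["nodes"]]
  expect_lte(n_pruned, n_full)
})

test_that("smoothed predictions are continuous except at finitely many splits", {
  set.seed(8)
  x <- matrix(runif(300), ncol = 1)
  y <- exp(-3 * x[, 1]) * 10 + rnorm(300, sd = 0.05)
  tree <- train_model_tree(x, y)
  tt <- seq(0.01, 0.99, length.out = 1000)
  p <- predict(tree, matrix(tt, ncol = 1))
  step <- abs(diff(p))
  # a jump is a step far exceeding the local trend of the smooth parts
  jumps <- sum(step > 10 * median(step) + 1e-8)
  cnt <- synsurr:::.count_nodes(tree$root)
  expect_lte(jumps, cnt[["nodes"]] - cnt[["leaves"]])
})

test_that("input dimension mismatches are rejected by all learners", {
  x <- matrix(runif(60), ncol = 2)
  y <- x[, 1] + x[, 2]
  for (model in list(train_model_tree(x, y), train_knn(x, y, 3),
                     train_linear(x, y)))
    expect_error(predict(model, matrix(1, 2, 3)), "attributes")
})

test_that("KNN honors k = 1 identity, tie rule and k bounds", {
  x <- matrix(c(0, 2, 10), ncol = 1)
  y <- c(5, 9, 4)
  expect_identical(predict(train_knn(x, y, 1), x), y)
  # query equidistant from examples 1 and 2: stable order -> lowest index
  expect_identical(predict(train_knn(x, y, 1), matrix(1, 1)), 5)
  expect_error(train_knn(x, y, 4), "k_neighbors")
  w <- train_knn(x, y, 2, weighting = "inverse_distance")
  expect_equal(predict(w, matrix(0, 1)), 5)  # on-point: weight collapses
})

test_that("the linear learner is exact on linear data", {
  set.seed(2)
  x <- matrix(runif(90), ncol = 3)
  y <- 2 + x %*% c(1, -4, 0.5)
  expect_lt(rmse(y, predict(train_linear(x, y), x)), 1e-9)
})
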