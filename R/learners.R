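#' Baseline surrogate learners: k-nearest neighbors and linear regression
#'
#' `train_knn` stores the training examples with per-attribute z-score
#' normalization; prediction averages the targets of the `k_neighbors`
#' nearest training points (Euclidean distance in normalized space),
#' weighted uniformly or by inverse distance. Exact distance ties resolve
#' to the lowest training-example index. `train_linear` fits an ordinary
#' least-squares model on all attributes.
#'
#' @param x numeric matrix or data.frame of input attributes.
#' @param y numeric target vector.
#' @param k_neighbors number of neighbors (<= number of training examples).
#' @param weighting `"uniform"` or `"inverse_distance"`.
#' @return objects of class `knn_model` / `linear_model` (both
#'   `surrogate_model`) with [predict()] methods.
#' @export
train_knn <- function(x, y, k_neighbors = 5L, weighting = c("uniform", "inverse_distance")) {
  x <- as.matrix(x); storage.mode(x) <- "double"
  weighting <- match.arg(weighting)
  stopifnot(nrow(x) == length(y))
  if (k_neighbors > nrow(x))
    stop("k_neighbors exceeds the number of training examples", call. = FALSE)
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  structure(list(x = sweep(sweep(x, 2, ctr), 2, scl, "/"), y = y,
                 center = ctr, scale = scl,
                 k = as.integer(k_neighbors), weighting = weighting, p = ncol(x)),
            class = c("knn_model", "surrogate_model"))
}

#' @export
predict.knn_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata); storage.mode(X) <- "double"
  if (ncol(X) != object$p)
    stop(sprintf("input has %d attributes but the model was trained on %d",
                 ncol(X), object$p), call. = FALSE)
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  tr <- object$x
  k <- object$k
  out <- numeric(nrow(Xs))
  chunk <- max(1L, floor(2e6 / nrow(tr)))
  for (start in seq(1, nrow(Xs), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(Xs))
    # squared Euclidean distances, chunked to bound memory
    d2 <- outer(rowSums(Xs[rows, , drop = FALSE]^2), rowSums(tr^2), "+") -
      2 * Xs[rows, , drop = FALSE] %*% t(tr)
    for (i in seq_along(rows)) {
      # order() is stable: ties go to the lowest training index
      nn <- order(d2[i, ])[seq_len(k)]
      if (object$weighting == "uniform") {
        out[rows[i]] <- mean(object$y[nn])
      } else {
        w <- 1 / pmax(sqrt(pmax(d2[i, nn], 0)), 1e-12)
        out[rows[i]] <- sum(w * object$y[nn]) / sum(w)
      }
    }
  }
  out
}

#' @rdname train_knn
#' @export
train_linear <- function(x, y) {
  x <- as.matrix(x); storage.mode(x) <- "double"
  stopifnot(nrow(x) == length(y))
  cf <- lm.fit(cbind(`(Intercept)` = 1, x), y)$coefficients
  cf[is.na(cf)] <- 0
  structure(list(coef = cf, p = ncol(x)),
            class = c("linear_model", "surrogate_model"))
}

#' @export
predict.linear_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata); storage.mode(X) <- "double"
  if (ncol(X) != object$p)
    stop(sprintf("input has %d attributes but the model was trained on %d",
                 ncol(X), object$p), call. = FALSE)
  drop(cbind(1, X) %*% object$coef)
}

#' Learner constructors for the cross-validation pipeline
#'
#' A learner is a function `function(x, y, seed)` returning a fitted
#' `surrogate_model`. These constructors wrap the package learners with
#' fixed hyperparameters; any function with the same contract (for example
#' an adapter around an external MLP, MARS or PPR implementation) can be
#' used in [cross_validate()] and [run_pipeline()] in their place.
#'
#' @param control,k_neighbors,weighting hyperparameters forwarded to the
#'   respective training function.
#' @return a learner function.
#' @export
learner_model_tree <- function(control = m5_control()) {
  function(x, y, seed = NULL) train_model_tree(x, y, control)
}

#' @rdname learner_model_tree
#' @export
learner_knn <- function(k_neighbors = 5L, weighting = "uniform") {
  function(x, y, seed = NULL) train_knn(x, y, k_neighbors, weighting)
}

#' @rdname learner_model_tree
#' @export
learner_linear <- function() {
  function(x, y, seed = NULL) train_linear(x, y)
}

#' Look up a named learner
#'
#' @param name one of `"model_tree"`, `"knn"`, `"linear"`.
#' @param ... forwarded to the learner constructor.
#' @return a learner function.
#' @export
get_learner <- function(name, ...) {
  switch(name,
         model_tree = learner_model_tree(...),
         knn = learner_knn(...),
         linear = learner_linear(...),
         stop(sprintf("unknown learner '%s' (available: model_tree, knn, linear)",
                      name), call. = FALSE))
}
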