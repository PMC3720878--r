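#' Control parameters for the model-tree learner
#'
#' Standard M5'-style defaults: splitting stops when a node holds fewer than
#' `min_leaf` cases or its target standard deviation falls below
#' `stop_fraction` of the root standard deviation; pruning compares each
#' node's linear model against its subtree using the adjusted error factor
#' `(n + v) / (n - v)` on the mean absolute error; predictions are smoothed
#' along the root path with smoothing constant `smoothing`.
#'
#' @param min_leaf minimum number of cases for a node to be split.
#' @param stop_fraction fraction of the root standard deviation below which
#'   a node is not split.
#' @param smoothing smoothing constant k; 0 disables smoothing.
#' @param prune logical; prune the grown tree bottom-up.
#' @return list of class `m5_control`.
#' @export
m5_control <- function(min_leaf = 4L, stop_fraction = 0.05, smoothing = 15,
                       prune = TRUE) {
  stopifnot(min_leaf >= 1, stop_fraction >= 0, smoothing >= 0)
  structure(list(min_leaf = as.integer(min_leaf),
                 stop_fraction = stop_fraction,
                 smoothing = smoothing, prune = prune),
            class = "m5_control")
}

# sample standard deviation from sufficient statistics; 0 for n < 2
.sd_from_sums <- function(s, s2, n) {
  v <- ifelse(n >= 2, pmax(0, (s2 - s^2 / n) / (n - 1)), 0)
  sqrt(v)
}

#' Standard deviation reduction of a candidate split
#'
#' `sd(T) - |T_L|/|T| * sd(T_L) - |T_R|/|T| * sd(T_R)` for the partition of
#' `y` by `x <= threshold`, the split-selection criterion of the model tree.
#'
#' @param x numeric attribute values.
#' @param y numeric targets.
#' @param threshold split point.
#' @return the reduction (larger is better).
#' @export
sd_reduction <- function(x, y, threshold) {
  left <- x <= threshold
  n <- length(y)
  sdv <- function(v) if (length(v) >= 2) sd(v) else 0
  sdv(y) - sum(left) / n * sdv(y[left]) - sum(!left) / n * sdv(y[!left])
}

# best split of one attribute: returns list(sdr, threshold) or NULL
.best_split_attr <- function(xj, y, min_leaf) {
  n <- length(y)
  ord <- order(xj)
  xs <- xj[ord]; ys <- y[ord]
  cs <- cumsum(ys); cs2 <- cumsum(ys^2)
  i <- seq_len(n - 1L)
  ok <- xs[i] < xs[i + 1L]
  if (!any(ok)) return(NULL)
  i <- i[ok]
  nl <- i; nr <- n - i
  sd_l <- .sd_from_sums(cs[i], cs2[i], nl)
  sd_r <- .sd_from_sums(cs[n] - cs[i], cs2[n] - cs2[i], nr)
  sd_t <- .sd_from_sums(cs[n], cs2[n], n)
  sdr <- sd_t - (nl / n) * sd_l - (nr / n) * sd_r
  k <- which.max(sdr)
  list(sdr = sdr[k], threshold = (xs[i[k]] + xs[i[k] + 1L]) / 2)
}

# fit an OLS model on a subset of attributes with greedy term elimination by
# adjusted error; returns list(coef = c(intercept, per selected attr),
# attrs, adj_err, mae)
.fit_node_model <- function(X, y, attrs, greedy = TRUE) {
  n <- length(y)
  yr <- range(y)
  fit_on <- function(a) {
    Z <- cbind(`(Intercept)` = 1, X[, a, drop = FALSE])
    cf <- tryCatch(lm.fit(Z, y)$coefficients, error = function(e) NULL)
    if (is.null(cf)) cf <- c(mean(y), rep(0, length(a)))
    cf[is.na(cf)] <- 0
    res <- y - drop(Z %*% cf)
    v <- length(cf)
    factor <- if (n > v) (n + v) / (n - v) else 1e6
    mae <- mean(abs(res))
    # y_range caps the model's predictions at the targets it was fitted on
    # (Cubist-style), so sparse corners of the input space cannot drive a
    # linear model into wild extrapolation
    list(coef = cf, attrs = a, mae = mae, adj_err = mae * factor,
         y_range = yr)
  }
  best <- fit_on(attrs)
  if (greedy && length(attrs)) {
    repeat {
      improved <- FALSE
      for (drop1 in seq_along(best$attrs)) {
        cand <- fit_on(best$attrs[-drop1])
        if (cand$adj_err < best$adj_err) { best <- cand; improved <- TRUE; break }
      }
      if (!improved) break
    }
  }
  best
}

#' Train an M5-style model tree
#'
#' Grows a regression tree by maximizing the standard deviation reduction
#' (SDR) of the target over all attributes and thresholds, fits multivariate
#' linear models at the nodes, prunes bottom-up by comparing each node
#' model's adjusted error against its subtree, and (at prediction time)
#' smooths leaf predictions along the path to the root. This is the
#' surrogate regressor mapping the synapse parameters and the time instant
#' to the percentage of open receptors.
#'
#' @param x numeric matrix or data.frame of input attributes (one row per
#'   training example); columns are the synapse parameters plus time.
#' @param y numeric target vector (percent open receptors).
#' @param control an [m5_control()].
#' @return Object of class `m5_tree` with a [predict()] method.
#' @examples
#' x <- matrix(runif(200), ncol = 1)
#' y <- ifelse(x[, 1] < 0.5, 2 * x[, 1], 3 - 4 * x[, 1])
#' tree <- train_model_tree(x, y, m5_control(min_leaf = 2, smoothing = 0))
#' @export
train_model_tree <- function(x, y, control = m5_control()) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  stopifnot(nrow(x) == length(y), nrow(x) >= 2)
  p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))
  sd_root <- if (length(y) >= 2) sd(y) else 0
  sd_stop <- control$stop_fraction * sd_root

  grow <- function(idx) {
    n <- length(idx)
    yi <- y[idx]
    sd_here <- if (n >= 2) sd(yi) else 0
    if (n < control$min_leaf || sd_here <= sd_stop || sd_here == 0)
      return(list(leaf = TRUE, idx = idx, n = n))
    best <- NULL
    for (j in seq_len(p)) {
      s <- .best_split_attr(x[idx, j], yi, control$min_leaf)
      if (!is.null(s) && (is.null(best) || s$sdr > best$sdr))
        best <- c(s, list(attr = j))
    }
    if (is.null(best)) return(list(leaf = TRUE, idx = idx, n = n, no_split = TRUE))
    left <- idx[x[idx, best$attr] <= best$threshold]
    right <- idx[x[idx, best$attr] > best$threshold]
    list(leaf = FALSE, idx = idx, n = n,
         attr = best$attr, threshold = best$threshold, sdr = best$sdr,
         left = grow(left), right = grow(right))
  }

  root <- grow(seq_along(y))
  if (isTRUE(root$no_split) && sd_root > 0)
    warning("inputs carry no usable split; returning a single-leaf model",
            call. = FALSE)

  # bottom-up: attach linear models, prune
  finalize <- function(node) {
    Xn <- x[node$idx, , drop = FALSE]
    yn <- y[node$idx]
    if (node$leaf) {
      node$model <- .fit_node_model(Xn, yn, integer(0), greedy = FALSE)
      node$err <- node$model$adj_err
      node$subtree_attrs <- integer(0)
      return(node)
    }
    node$left <- finalize(node$left)
    node$right <- finalize(node$right)
    node$subtree_attrs <- sort(unique(c(node$attr, node$left$subtree_attrs,
                                        node$right$subtree_attrs)))
    node$model <- .fit_node_model(Xn, yn, node$subtree_attrs)
    subtree_err <- (node$left$n * node$left$err +
                      node$right$n * node$right$err) / node$n
    if (control$prune && node$model$adj_err <= subtree_err) {
      node <- list(leaf = TRUE, idx = node$idx, n = node$n,
                   model = node$model, err = node$model$adj_err,
                   subtree_attrs = node$subtree_attrs)
    } else {
      node$err <- subtree_err
    }
    node
  }
  root <- finalize(root)
  strip <- function(node) {
    node$idx <- NULL
    if (!node$leaf) { node$left <- strip(node$left); node$right <- strip(node$right) }
    node
  }
  root <- strip(root)

  structure(list(root = root, control = control, p = p,
                 attr_names = colnames(x), n_train = length(y)),
            class = c("m5_tree", "surrogate_model"))
}

.eval_model <- function(model, X) {
  p <- drop(cbind(1, X[, model$attrs, drop = FALSE]) %*% model$coef)
  if (!is.null(model$y_range))
    p <- pmin(pmax(p, model$y_range[1]), model$y_range[2])
  p
}

.count_nodes <- function(node) {
  if (node$leaf) return(c(nodes = 1L, leaves = 1L))
  c(nodes = 1L, leaves = 0L) + .count_nodes(node$left) + .count_nodes(node$right)
}

#' @export
print.m5_tree <- function(x, ...) {
  cnt <- .count_nodes(x$root)
  cat(sprintf("<m5_tree>: %d nodes (%d leaves), %d attributes, %d training examples\n",
              cnt[["nodes"]], cnt[["leaves"]], x$p, x$n_train))
  invisible(x)
}

#' Predict from a trained model tree
#'
#' Routes each input vector to a leaf, evaluates the leaf's linear model and
#' smooths the prediction along the path to the root:
#' `p <- (n_child * p_child + k * p_node) / (n_child + k)` at every internal
#' node, where `n_child` is the training size of the child the input fell
#' into and `k` the smoothing constant. Every node model's output is capped
#' at the target range the model was fitted on, so queries in sparse
#' corners of the input space cannot be driven far outside the observed
#' response by linear extrapolation.
#'
#' @param object an `m5_tree`.
#' @param newdata numeric matrix or data.frame with the training dimension.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.m5_tree <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  if (ncol(X) != object$p)
    stop(sprintf("input has %d attributes but the model was trained on %d",
                 ncol(X), object$p), call. = FALSE)
  k <- object$control$smoothing
  rec <- function(node, rows) {
    if (!length(rows)) return(numeric(0))
    if (node$leaf) return(.eval_model(node$model, X[rows, , drop = FALSE]))
    go_left <- X[rows, node$attr] <= node$threshold
    out <- numeric(length(rows))
    pl <- rec(node$left, rows[go_left])
    pr <- rec(node$right, rows[!go_left])
    if (k > 0) {
      q <- .eval_model(node$model, X[rows, , drop = FALSE])
      if (length(pl)) pl <- (node$left$n * pl + k * q[go_left]) / (node$left$n + k)
      if (length(pr)) pr <- (node$right$n * pr + k * q[!go_left]) / (node$right$n + k)
    }
    out[go_left] <- pl
    out[!go_left] <- pr
    out
  }
  rec(object$root, seq_len(nrow(X)))
}
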