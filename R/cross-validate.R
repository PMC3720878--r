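#' Input vector of a synapse configuration
#'
#' The attribute order used throughout the learning stages:
#' `[AMPA], [T], L_s, H_c, E` and, in the extended scenario, `D_g`; the
#' time instant `t` is appended per sample point.
#'
#' @param config a [synapse_config()].
#' @param include_dg include the diffusion coefficient (extended scenario).
#' @return named numeric vector.
#' @export
config_inputs <- function(config, include_dg = FALSE) {
  v <- c(ampa_density = config$ampa_density,
         transporter_density = config$transporter_density,
         side_length = config$side_length,
         cleft_height = config$cleft_height,
         apposition_factor = config$apposition_factor)
  if (include_dg) v <- c(v, glu_diffusion = config$glu_diffusion)
  v
}

# stack per-configuration curve samples into a training design
.assemble_examples <- function(configs, samples, include_dg = FALSE) {
  ids <- vapply(configs, function(c) as.integer(c$config_id), 1L)
  rows <- lapply(seq_along(configs), function(i) {
    s <- samples[[i]]
    inp <- config_inputs(configs[[i]], include_dg)
    X <- matrix(rep(inp, each = nrow(s)), nrow = nrow(s),
                dimnames = list(NULL, names(inp)))
    cbind(X, t = s$time_us)
  })
  list(x = do.call(rbind, rows),
       y = unlist(lapply(samples, `[[`, "percent_open"), use.names = FALSE),
       config_id = rep(ids, vapply(samples, nrow, 1L)),
       time_us = unlist(lapply(samples, `[[`, "time_us"), use.names = FALSE))
}

#' Cross-validated training and validation (Stages 3--4)
#'
#' For each fold, trains the learner on the sample points of all training
#' configurations and predicts the points of the held-out configurations,
#' so every configuration's predicted points come from a model that never
#' saw that configuration. RMSE and R^2 are computed per fold over the
#' pooled held-out points, then aggregated as mean and standard deviation
#' across folds; pooled metrics over all points are reported alongside.
#'
#' @param configs list of [synapse_config()] objects.
#' @param samples list of [sample_curve()] outputs, parallel to `configs`.
#' @param folds a [make_folds()] assignment covering every configuration.
#' @param learner a learner function `function(x, y, seed)`; see
#'   [learner_model_tree()].
#' @param include_dg include the diffusion coefficient in the input vector.
#' @param seed forwarded to the learner per fold (`seed + fold`).
#' @return list of class `validation_report`: `per_fold` data.frame,
#'   `aggregate` (mean/sd of each metric), `pooled`, and `predictions`
#'   (config_id, time_us, y_true, y_pred, fold).
#' @export
cross_validate <- function(configs, samples, folds, learner,
                           include_dg = FALSE, seed = 1L) {
  stopifnot(length(configs) == length(samples))
  ids <- vapply(configs, function(c) as.integer(c$config_id), 1L)
  missing <- setdiff(as.character(ids), names(folds))
  if (length(missing))
    stop("fold assignment missing configuration(s): ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  if (any(vapply(samples, is.null, TRUE)))
    stop("missing curve sample for at least one configuration", call. = FALSE)
  d <- .assemble_examples(configs, samples, include_dg)
  row_fold <- unname(folds[as.character(d$config_id)])
  k <- attr(folds, "k")
  per_fold <- data.frame(fold = seq_len(k), rmse = NA_real_, r2 = NA_real_,
                         n = NA_integer_)
  y_pred <- numeric(length(d$y))
  for (f in seq_len(k)) {
    test <- row_fold == f
    train_ids <- unique(d$config_id[!test])
    test_ids <- unique(d$config_id[test])
    if (length(intersect(train_ids, test_ids)))
      stop("leakage: a configuration appears in both train and test of fold ",
           f, call. = FALSE)
    model <- learner(d$x[!test, , drop = FALSE], d$y[!test], seed = seed + f)
    p <- predict(model, d$x[test, , drop = FALSE])
    y_pred[test] <- p
    per_fold$rmse[f] <- rmse(d$y[test], p)
    per_fold$r2[f] <- r_squared(d$y[test], p)
    per_fold$n[f] <- sum(test)
  }
  structure(list(
    per_fold = per_fold,
    aggregate = list(rmse_mean = mean(per_fold$rmse), rmse_sd = sd(per_fold$rmse),
                     r2_mean = mean(per_fold$r2), r2_sd = sd(per_fold$r2)),
    pooled = list(rmse = rmse(d$y, y_pred), r2 = r_squared(d$y, y_pred)),
    predictions = data.frame(config_id = d$config_id, time_us = d$time_us,
                             y_true = d$y, y_pred = y_pred, fold = row_fold)
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report>: %d folds; RMSE %.4f +/- %.4f, R^2 %.4f +/- %.4f (per-fold mean +/- sd)\n",
              nrow(x$per_fold), x$aggregate$rmse_mean, x$aggregate$rmse_sd,
              x$aggregate$r2_mean, x$aggregate$r2_sd))
  cat(sprintf("  pooled over all points: RMSE %.4f, R^2 %.4f\n",
              x$pooled$rmse, x$pooled$r2))
  invisible(x)
}
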