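#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run: corpus generation (number of
#' configurations, runs per configuration, parameter ranges, optional
#' diffusion-coefficient variable), fold creation, learner choice, final
#' curve family and output directory. All randomness flows from `seed`;
#' per-stage seeds are derived from it by fixed offsets so a rerun with an
#' identical configuration is bit-identical.
#'
#' @param n_configs number of synapse configurations in the corpus.
#' @param runs_per_config stochastic runs averaged per configuration
#'   (default 200).
#' @param ranges parameter ranges, see [default_ranges()].
#' @param include_dg extended scenario: sample the glutamate diffusion
#'   coefficient as a sixth variable.
#' @param k_folds folds for cross-validation (default 10).
#' @param learner learner name (`"model_tree"`, `"knn"`, `"linear"`) or a
#'   learner function.
#' @param learner_args arguments for the named learner's constructor.
#' @param final_family `"rational"` (4/4), `"fourier"` (8 terms) or
#'   `"both"`; the extended scenario always reports both.
#' @param steps,dt simulation grid (default 10000 steps of 1 us).
#' @param seed master seed.
#' @param out_dir optional artifact directory; `NULL` keeps everything in
#'   memory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_configs, runs_per_config = 200L,
                            ranges = default_ranges(include_dg),
                            include_dg = FALSE, k_folds = 10L,
                            learner = "model_tree", learner_args = list(),
                            final_family = c("rational", "fourier", "both"),
                            steps = 10000L, dt = 1, seed = 1L,
                            out_dir = NULL) {
  final_family <- match.arg(final_family)
  if (is.character(learner)) {
    # fail fast on an unknown learner, before any simulation
    do.call(get_learner, c(list(learner), learner_args))
  } else if (!is.function(learner)) {
    stop("learner must be a name or a function(x, y, seed)", call. = FALSE)
  }
  # partial range lists override the defaults parameter-wise
  ranges <- utils::modifyList(default_ranges(include_dg), ranges)
  validate_ranges(ranges)
  stopifnot(n_configs >= 1, runs_per_config >= 1, k_folds >= 2)
  structure(list(n_configs = as.integer(n_configs),
                 runs_per_config = as.integer(runs_per_config),
                 ranges = ranges, include_dg = include_dg,
                 k_folds = as.integer(k_folds),
                 learner = learner, learner_args = learner_args,
                 final_family = final_family,
                 steps = as.integer(steps), dt = dt,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

.final_specs <- function(final_family) {
  specs <- list(rational = family_spec("rational", c(4, 4)),
                fourier = family_spec("fourier", 8))
  if (final_family == "both") specs else specs[final_family]
}

#' Run the five-stage surrogate pipeline end to end
#'
#' Simulates the corpus (mean activation curve per configuration), samples
#' each curve to 100 points, builds configuration-level folds,
#' cross-validates the learner, fits the final curve family to each
#' configuration's cross-validated predicted points and scores the fit
#' against the configuration's full simulated curve. A final surrogate is
#' also trained on all configurations for [predict_curve()]. When
#' `config$out_dir` is set, all artifacts are written as CSV/JSON under it
#' (`manifest.csv`, `curves/`, `samples.csv`, `folds.csv`,
#' `predictions.csv`, `fits.csv`, `report.json`).
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return list of class `run_report`: corpus, samples, validation report,
#'   per-config final metrics (one row per configuration and family) with
#'   mean/sd summary, the full-data surrogate, and stage timings.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  timing <- c()
  tic <- function() Sys.time()
  toc <- function(t0, stage) {
    timing[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }
  learner <- if (is.function(config$learner)) config$learner
             else do.call(get_learner, c(list(config$learner), config$learner_args))

  # corpus generation
  t0 <- tic()
  configs <- sample_configs(config$n_configs, config$ranges,
                            include_dg = config$include_dg,
                            seed = config$seed + 101L)
  say("simulating %d configurations x %d runs ...", length(configs),
      config$runs_per_config)
  sim_seed0 <- config$seed + 202L
  curves <- lapply(configs, function(cf) {
    mean_activation(cf, n_runs = config$runs_per_config,
                    seed = sim_seed0 + (cf$config_id - 1L) * config$runs_per_config,
                    steps = config$steps, dt = config$dt)
  })
  toc(t0, "simulate")

  # stage 1: sampling
  t0 <- tic()
  samples <- lapply(curves, sample_curve)
  toc(t0, "sample")

  # stage 2: folds
  t0 <- tic()
  ids <- vapply(configs, function(c) as.integer(c$config_id), 1L)
  folds <- make_folds(ids, k = config$k_folds, seed = config$seed + 303L)
  toc(t0, "folds")

  # stages 3-4: cross-validated learning
  t0 <- tic()
  say("cross-validating the %s learner over %d folds ...",
      if (is.character(config$learner)) config$learner else "custom",
      config$k_folds)
  report <- cross_validate(configs, samples, folds, learner,
                           include_dg = config$include_dg,
                           seed = config$seed + 505L)
  toc(t0, "validate")

  # stage 5: final curve fits per configuration
  t0 <- tic()
  specs <- .final_specs(if (config$include_dg) "both" else config$final_family)
  say("fitting final curve famil%s to predicted points ...",
      if (length(specs) > 1) "ies" else "y")
  fit_rows <- list()
  fits <- list()
  for (i in seq_along(configs)) {
    pts <- report$predictions[report$predictions$config_id == ids[i], ]
    for (fam in names(specs)) {
      fit <- fit_final_curve(pts, specs[[fam]], full_curve = curves[[i]],
                             seed = config$seed + 404L)
      fits[[paste0(fam, "_", ids[i])]] <- fit
      fit_rows[[length(fit_rows) + 1L]] <- data.frame(
        config_id = ids[i], family = fam, rmse = fit$rmse, r2 = fit$r2,
        converged = fit$converged)
    }
  }
  final_metrics <- do.call(rbind, fit_rows)
  final_summary <- do.call(rbind, lapply(split(final_metrics, final_metrics$family),
    function(d) data.frame(family = d$family[1],
                           rmse_mean = mean(d$rmse), rmse_sd = sd(d$rmse),
                           r2_mean = mean(d$r2), r2_sd = sd(d$r2),
                           n_failed = sum(!d$converged))))
  rownames(final_summary) <- NULL
  toc(t0, "final_fit")

  # full-data surrogate for predicting unseen configurations
  t0 <- tic()
  d <- .assemble_examples(configs, samples, config$include_dg)
  full_model <- learner(d$x, d$y, seed = config$seed + 606L)
  toc(t0, "final_model")

  out <- structure(list(
    pipeline_config = config, configs = configs, curves = curves,
    samples = samples, folds = folds, validation = report,
    final_metrics = final_metrics, final_summary = final_summary,
    final_fits = fits, model = full_model, timings = unlist(timing)
  ), class = "run_report")
  if (!is.null(config$out_dir)) write_artifacts(out, config$out_dir)
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report>: %d configurations x %d runs, %d folds\n",
              length(x$configs), x$pipeline_config$runs_per_config,
              x$pipeline_config$k_folds))
  cat(sprintf("  validation (per-fold mean): RMSE %.4f, R^2 %.4f\n",
              x$validation$aggregate$rmse_mean, x$validation$aggregate$r2_mean))
  for (i in seq_len(nrow(x$final_summary)))
    cat(sprintf("  final full-curve fit (%s): RMSE %.4f +/- %.4f, R^2 %.4f +/- %.4f\n",
                x$final_summary$family[i], x$final_summary$rmse_mean[i],
                x$final_summary$rmse_sd[i], x$final_summary$r2_mean[i],
                x$final_summary$r2_sd[i]))
  invisible(x)
}

#' Run the extended six-variable scenario
#'
#' Identical pipeline with the glutamate diffusion coefficient as a sixth
#' input variable (7-dimensional training inputs including time); the
#' report carries final fits for both the rational and the Fourier family
#' so the better one can be chosen.
#'
#' @param config a [pipeline_config()]; `include_dg` is forced on.
#' @param quiet suppress progress messages.
#' @return a `run_report`.
#' @export
run_extended_scenario <- function(config, quiet = FALSE) {
  config$include_dg <- TRUE
  if (is.null(config$ranges$glu_diffusion))
    config$ranges$glu_diffusion <- c(0.25, 0.75)
  run_pipeline(config, quiet = quiet)
}

#' Write pipeline artifacts to a directory
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_artifacts <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "curves"), showWarnings = FALSE)
  cfg <- report$pipeline_config
  write.csv(configs_to_manifest(report$configs, seed = cfg$seed),
            file.path(dir, "manifest.csv"), row.names = FALSE)
  for (cv in report$curves)
    write_curve_csv(cv, file.path(dir, "curves",
                                  sprintf("config_%d.csv", cv$meta$config_id)))
  write.csv(do.call(rbind, report$samples), file.path(dir, "samples.csv"),
            row.names = FALSE)
  write.csv(data.frame(config_id = names(report$folds),
                       fold = as.integer(report$folds)),
            file.path(dir, "folds.csv"), row.names = FALSE)
  write.csv(report$validation$predictions, file.path(dir, "predictions.csv"),
            row.names = FALSE)
  write.csv(report$final_metrics, file.path(dir, "fits.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    n_configs = length(report$configs),
    runs_per_config = cfg$runs_per_config,
    k_folds = cfg$k_folds,
    validation = list(per_fold = report$validation$per_fold,
                      aggregate = report$validation$aggregate,
                      pooled = report$validation$pooled),
    final = report$final_summary,
    timings_sec = as.list(report$timings)
  ), file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
  dataframe = "rows")
  invisible(dir)
}

#' Predict the activation curve of an unseen synapse configuration
#'
#' Evaluates the trained surrogate for a new configuration without any new
#' simulation. Because a new configuration has no simulated curve to define
#' its peak interval, prediction is two-pass: the surrogate is first
#' evaluated on a uniform 1000-point grid to locate the predicted peak
#' interval, the 100-point Stage-1 sampling scheme is applied to that
#' predicted curve, the final family is fitted to those points, and a dense
#' curve on the full grid is returned. Parameters outside the training
#' ranges produce a warning, not a refusal.
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param new_config a [synapse_config()].
#' @param family `"rational"` or `"fourier"`.
#' @param grid_points size of the first-pass uniform grid.
#' @return list: `fit` (a `fitted_curve`), `curve` (dense
#'   [activation_curve()] on the simulation grid), `sample` (the 100
#'   two-pass points).
#' @export
predict_curve <- function(report, new_config,
                          family = c("rational", "fourier"),
                          grid_points = 1000L) {
  stopifnot(inherits(report, "run_report"))
  family <- match.arg(family)
  if (is.null(report$model))
    stop("report carries no trained surrogate model", call. = FALSE)
  cfg <- report$pipeline_config
  for (p in names(cfg$ranges)) {
    r <- cfg$ranges[[p]]
    if (new_config[[p]] < r[1] || new_config[[p]] > r[2])
      warning(sprintf("parameter '%s' = %g outside the training range [%g, %g]; extrapolating",
                      p, new_config[[p]], r[1], r[2]), call. = FALSE)
  }
  t_max <- cfg$steps * cfg$dt
  inp <- config_inputs(new_config, cfg$include_dg)
  eval_at <- function(tt) {
    X <- cbind(matrix(rep(inp, each = length(tt)), nrow = length(tt),
                      dimnames = list(NULL, names(inp))), t = tt)
    predict(report$model, X)
  }
  coarse_t <- seq(0, t_max, length.out = grid_points)
  coarse <- activation_curve(coarse_t, pmax(0, eval_at(coarse_t)),
                             config_id = new_config$config_id)
  pts <- sample_curve(coarse)
  pts$percent_open <- eval_at(pts$time_us)
  spec <- .final_specs(family)[[1]]
  fit <- fit_function(pts$time_us, pts$percent_open, spec,
                      seed = cfg$seed + 404L, t_scale = t_max)
  dense_t <- seq(0, t_max, by = cfg$dt)
  dense <- activation_curve(dense_t, predict(fit, dense_t),
                            config_id = new_config$config_id)
  list(fit = fit, curve = dense, sample = pts)
}
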