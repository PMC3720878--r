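#' Function family specifications
#'
#' A family spec names one of the six candidate function families and its
#' order: polynomial degree 1--9, Fourier / Gauss / sum-of-sine term count
#' 1--8, exponential term count 1--2, or rational numerator degree 0--5
#' with denominator degree 1--5. Time enters every family through the
#' normalized variable `u = t / t_scale`, where `t_scale` is recorded by
#' the fit (conditioning: raw microsecond times up to 10^4 raised to the
#' 9th power would be numerically hopeless).
#'
#' @param family one of `"polynomial"`, `"fourier"`, `"gauss"`,
#'   `"sum_of_sine"`, `"exponential"`, `"rational"`.
#' @param order integer order (degree or term count); for `"rational"` a
#'   length-2 vector (numerator degree, denominator degree).
#' @return Object of class `family_spec`.
#' @export
family_spec <- function(family, order) {
  family <- match.arg(family, c("polynomial", "fourier", "gauss",
                                "sum_of_sine", "exponential", "rational"))
  order <- as.integer(order)
  ok <- switch(family,
    polynomial = length(order) == 1 && order >= 1 && order <= 9,
    fourier = ,
    gauss = ,
    sum_of_sine = length(order) == 1 && order >= 1 && order <= 8,
    exponential = length(order) == 1 && order >= 1 && order <= 2,
    rational = length(order) == 2 && order[1] >= 0 && order[1] <= 5 &&
      order[2] >= 1 && order[2] <= 5)
  if (!ok) stop(sprintf("invalid order for family '%s'", family), call. = FALSE)
  structure(list(family = family, order = order), class = "family_spec")
}

#' @export
print.family_spec <- function(x, ...) {
  cat(sprintf("<family_spec>: %s\n", spec_label(x)))
  invisible(x)
}

#' Human-readable label of a family spec
#' @param spec a [family_spec()].
#' @return character scalar such as `"rational 4/4"`.
#' @export
spec_label <- function(spec) {
  if (spec$family == "rational")
    sprintf("rational %d/%d", spec$order[1], spec$order[2])
  else sprintf("%s %d", spec$family, spec$order[1])
}

#' Number of free coefficients of a family spec
#'
#' Polynomial degree d has d+1; a k-term Fourier series has 2k+2 (constant,
#' k sine and k cosine amplitudes, shared fundamental frequency; 18 for
#' k = 8); Gauss and sum-of-sine have 3 per term; exponential 2 per term; a
#' rational m/n (monic denominator) has m+n+1 (9 for 4/4).
#'
#' @param spec a [family_spec()].
#' @return integer.
#' @export
n_coefficients <- function(spec) {
  o <- spec$order
  switch(spec$family,
         polynomial = o + 1L,
         fourier = 2L * o + 2L,
         gauss = 3L * o,
         sum_of_sine = 3L * o,
         exponential = 2L * o,
         rational = o[1] + o[2] + 1L)
}

#' Enumerate the 65 candidate function families
#'
#' Polynomial degrees 1--9, Fourier terms 1--8, Gauss terms 1--8,
#' sum-of-sine terms 1--8, exponential terms 1--2, and the full rational
#' grid of numerator degree 0--5 by denominator degree 1--5: 65 candidate
#' specs in total.
#'
#' @return list of [family_spec()] objects.
#' @export
enumerate_candidates <- function() {
  out <- list()
  for (d in 1:9) out[[length(out) + 1L]] <- family_spec("polynomial", d)
  for (k in 1:8) out[[length(out) + 1L]] <- family_spec("fourier", k)
  for (k in 1:8) out[[length(out) + 1L]] <- family_spec("gauss", k)
  for (k in 1:8) out[[length(out) + 1L]] <- family_spec("sum_of_sine", k)
  for (k in 1:2) out[[length(out) + 1L]] <- family_spec("exponential", k)
  for (m in 0:5) for (n in 1:5)
    out[[length(out) + 1L]] <- family_spec("rational", c(m, n))
  out
}

# evaluate without pole guard (used inside the optimizer)
.eval_family <- function(spec, coef, u, guard = TRUE) {
  o <- spec$order
  switch(spec$family,
    polynomial = {
      acc <- rep(coef[o + 1], length(u))
      for (i in o:1) acc <- acc * u + coef[i]
      acc
    },
    fourier = {
      k <- o
      w <- coef[2 * k + 2]
      acc <- rep(coef[1], length(u))
      for (i in seq_len(k))
        acc <- acc + coef[2 * i] * cos(i * w * u) + coef[2 * i + 1] * sin(i * w * u)
      acc
    },
    gauss = {
      acc <- numeric(length(u))
      for (i in seq_len(o)) {
        a <- coef[3 * i - 2]; b <- coef[3 * i - 1]; cc <- coef[3 * i]
        acc <- acc + a * exp(-((u - b) / cc)^2)
      }
      acc
    },
    sum_of_sine = {
      acc <- numeric(length(u))
      for (i in seq_len(o)) {
        a <- coef[3 * i - 2]; b <- coef[3 * i - 1]; cc <- coef[3 * i]
        acc <- acc + a * sin(b * u + cc)
      }
      acc
    },
    exponential = {
      acc <- numeric(length(u))
      for (i in seq_len(o)) acc <- acc + coef[2 * i - 1] * exp(coef[2 * i] * u)
      acc
    },
    rational = {
      m <- o[1]; n <- o[2]
      num <- rep(coef[m + 1], length(u))
      if (m >= 1) for (i in m:1) num <- num * u + coef[i]
      den <- rep(1, length(u))
      q <- coef[(m + 2):(m + n + 1)]
      for (j in n:1) den <- den * u + q[j]
      if (guard) {
        if (any(abs(den) < 1e-12))
          stop("rational function pole: denominator vanishes in the requested range",
               call. = FALSE)
      } else {
        den <- ifelse(abs(den) < 1e-12, sign(den + (den == 0)) * 1e-12, den)
      }
      num / den
    })
}

# analytic Jacobian of .eval_family wrt coef (n x ncoef)
.jac_family <- function(spec, coef, u) {
  o <- spec$order
  n <- length(u)
  switch(spec$family,
    polynomial = outer(u, 0:o, `^`),
    fourier = {
      k <- o; w <- coef[2 * k + 2]
      J <- matrix(0, n, 2 * k + 2)
      J[, 1] <- 1
      dw <- numeric(n)
      for (i in seq_len(k)) {
        ci <- cos(i * w * u); si <- sin(i * w * u)
        J[, 2 * i] <- ci
        J[, 2 * i + 1] <- si
        dw <- dw + i * u * (-coef[2 * i] * si + coef[2 * i + 1] * ci)
      }
      J[, 2 * k + 2] <- dw
      J
    },
    gauss = {
      J <- matrix(0, n, 3 * o)
      for (i in seq_len(o)) {
        a <- coef[3 * i - 2]; b <- coef[3 * i - 1]; cc <- coef[3 * i]
        z <- (u - b) / cc
        e <- exp(-z^2)
        J[, 3 * i - 2] <- e
        J[, 3 * i - 1] <- a * e * 2 * z / cc
        J[, 3 * i] <- a * e * 2 * z^2 / cc
      }
      J
    },
    sum_of_sine = {
      J <- matrix(0, n, 3 * o)
      for (i in seq_len(o)) {
        a <- coef[3 * i - 2]; b <- coef[3 * i - 1]; cc <- coef[3 * i]
        s <- sin(b * u + cc); cs <- cos(b * u + cc)
        J[, 3 * i - 2] <- s
        J[, 3 * i - 1] <- a * u * cs
        J[, 3 * i] <- a * cs
      }
      J
    },
    exponential = {
      J <- matrix(0, n, 2 * o)
      for (i in seq_len(o)) {
        e <- exp(coef[2 * i] * u)
        J[, 2 * i - 1] <- e
        J[, 2 * i] <- coef[2 * i - 1] * u * e
      }
      J
    },
    rational = {
      m <- o[1]; nn <- o[2]
      num <- .eval_family(family_spec("polynomial", max(m, 1)),
                          c(coef[1:(m + 1)], rep(0, max(0, 1 - m))), u)
      den <- rep(1, n)
      q <- coef[(m + 2):(m + nn + 1)]
      for (j in nn:1) den <- den * u + q[j]
      den <- ifelse(abs(den) < 1e-12, sign(den + (den == 0)) * 1e-12, den)
      J <- matrix(0, n, m + nn + 1)
      for (i in 0:m) J[, i + 1] <- u^i / den
      for (j in 0:(nn - 1)) J[, m + 2 + j] <- -num * u^j / den^2
      J
    })
}

#' Evaluate a fitted function family
#'
#' @param spec a [family_spec()].
#' @param coefficients coefficient vector of length [n_coefficients()].
#' @param t time values (same units as the fit, microseconds by default).
#' @param t_scale time normalization recorded by the fit (`u = t/t_scale`).
#' @return numeric vector. A rational denominator smaller than 1e-12 in
#'   magnitude at any requested `t` raises a pole error.
#' @export
evaluate_function <- function(spec, coefficients, t, t_scale = 1) {
  if (length(coefficients) != n_coefficients(spec))
    stop(sprintf("spec '%s' needs %d coefficients, got %d", spec_label(spec),
                 n_coefficients(spec), length(coefficients)), call. = FALSE)
  .eval_family(spec, coefficients, t / t_scale, guard = TRUE)
}

# family-specific initializations (see vignette for rationale)
.init_family <- function(spec, u, v) {
  o <- spec$order
  span <- max(u) - min(u)
  if (span <= 0) span <- 1
  switch(spec$family,
    polynomial = {
      cf <- lm.fit(outer(u, 0:o, `^`), v)$coefficients
      cf[is.na(cf)] <- 0
      cf
    },
    fourier = {
      # profile the fundamental frequency: for fixed w the model is linear,
      # so scan a grid of w and keep the best linear solution as the seed
      w0 <- 2 * pi / span
      best <- NULL
      for (w in w0 * seq(0.25, 4, by = 0.25)) {
        X <- matrix(1, length(u), 2 * o + 1)
        for (i in seq_len(o)) {
          X[, 2 * i] <- cos(i * w * u); X[, 2 * i + 1] <- sin(i * w * u)
        }
        sol <- lm.fit(X, v)
        cf <- sol$coefficients
        cf[is.na(cf)] <- 0
        sse <- sum(sol$residuals^2)
        if (is.null(best) || sse < best$sse)
          best <- list(cf = c(cf, w), sse = sse)
      }
      best$cf
    },
    gauss = {
      # seed components at the largest values, width span/(4k)
      ord <- order(v, decreasing = TRUE)
      centers <- u[ord[seq_len(o)]]
      heights <- v[ord[seq_len(o)]] / seq_len(o)
      as.vector(rbind(heights, centers, rep(span / (4 * o), o)))
    },
    sum_of_sine = {
      w0 <- 2 * pi / span
      amp <- max(abs(v)) / o
      as.vector(rbind(rep(amp, o), seq_len(o) * w0, rep(0, o)))
    },
    exponential = {
      # slow term from a log-linear fit on the decaying tail, fast term
      # from the residual at the origin
      tail_idx <- u >= min(u) + span / 2 & v > 0
      if (sum(tail_idx) >= 2) {
        lf <- lm.fit(cbind(1, u[tail_idx]), log(v[tail_idx]))$coefficients
        a1 <- exp(lf[1]); b1 <- lf[2]
      } else { a1 <- max(abs(v)); b1 <- -1 / span }
      if (o == 1) c(a1, b1)
      else c(a1, b1, v[1] - a1, -10 / span)
    },
    rational = {
      # linearized least squares: v * den(u) = num(u), monic denominator
      m <- o[1]; n <- o[2]
      A <- cbind(outer(u, 0:m, `^`), -v * outer(u, 0:(n - 1), `^`))
      cf <- lm.fit(A, v * u^n)$coefficients
      cf[is.na(cf)] <- 0
      cf
    })
}

#' Fit a function family to points by nonlinear least squares
#'
#' Levenberg--Marquardt fits with analytic Jacobians, family-specific
#' initialization and `n_starts` seeded multi-starts (the first start is
#' the deterministic initialization, the rest perturb it); the start with
#' the smallest residual sum of squares wins. Polynomials are solved in
#' closed form. Non-convergence is reported through the `converged` flag,
#' never silently.
#'
#' @param t,v point coordinates (time, value); at least as many points as
#'   coefficients.
#' @param spec a [family_spec()].
#' @param n_starts number of multi-starts (default 5).
#' @param seed RNG seed for the perturbed starts.
#' @param t_scale time normalization; defaults to `max(t)` (so `u` spans
#'   about \[0, 1\]).
#' @return Object of class `fitted_curve`: spec, coefficients, `t_scale`,
#'   `rmse`/`r2` against the input points, `converged`.
#' @export
fit_function <- function(t, v, spec, n_starts = 5L, seed = 1L, t_scale = NULL) {
  nc <- n_coefficients(spec)
  if (length(t) < nc)
    stop(sprintf("under-determined fit: %d points for %d coefficients (%s)",
                 length(t), nc, spec_label(spec)), call. = FALSE)
  stopifnot(length(t) == length(v))
  if (is.null(t_scale)) t_scale <- if (max(t) > 0) max(t) else 1
  u <- t / t_scale

  if (spec$family == "polynomial") {
    cf <- .init_family(spec, u, v)
    fit <- .make_fitted(spec, cf, t_scale, u, v, converged = TRUE)
    return(fit)
  }

  init0 <- .init_family(spec, u, v)
  resid_fn <- function(par) .eval_family(spec, par, u, guard = FALSE) - v
  jac_fn <- function(par) .jac_family(spec, par, u)

  # a rational solution is only admissible if its denominator keeps sign
  # and magnitude over the whole fitted span: the activation curve is
  # finite everywhere, so a pole between sample points is a spurious fit
  # (slightly extended: grid-snapped samples may stop just short of the
  # dense evaluation span)
  u_dense <- seq(min(u), max(u) + 0.05 * (max(u) - min(u)), length.out = 512L)
  admissible <- function(par) {
    if (spec$family != "rational") return(TRUE)
    m <- spec$order[1]; n <- spec$order[2]
    den <- rep(1, length(u_dense))
    q <- par[(m + 2):(m + n + 1)]
    for (j in n:1) den <- den * u_dense + q[j]
    all(is.finite(den)) && min(abs(den)) > 1e-9 && !any(diff(sign(den)) != 0)
  }

  best <- NULL; best_any <- NULL
  ss_tot <- sum((v - mean(v))^2)
  set.seed(seed)
  for (s in seq_len(n_starts)) {
    par0 <- if (s == 1) init0
            else init0 * (1 + 0.3 * rnorm(nc)) + 0.01 * rnorm(nc)
    res <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = par0, fn = resid_fn, jac = jac_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = if (length(u) <= 500) 400L else 150L,
                             ptol = 1e-10, ftol = 1e-10))),
      error = function(e) NULL)
    if (is.null(res)) next
    sse <- sum(res$fvec^2)
    if (!is.finite(sse)) next
    cand <- list(par = res$par, sse = sse, info = res$info)
    if (is.null(best_any) || sse < best_any$sse) best_any <- cand
    if (admissible(res$par) && (is.null(best) || sse < best$sse)) best <- cand
    # remaining restarts cannot improve a numerically exhausted fit
    if (!is.null(best) && best$sse <= 1e-10 * max(ss_tot, 1e-300)) break
  }
  if (is.null(best) && is.null(best_any))
    return(.make_fitted(spec, init0, t_scale, u, v, converged = FALSE))
  # an inadmissible best is reported, but flagged as not converged
  if (is.null(best))
    return(.make_fitted(spec, best_any$par, t_scale, u, v, converged = FALSE))
  .make_fitted(spec, best$par, t_scale, u, v, converged = best$info %in% 1:4)
}

.make_fitted <- function(spec, coef, t_scale, u, v, converged) {
  pred <- tryCatch(.eval_family(spec, coef, u, guard = FALSE),
                   error = function(e) rep(NA_real_, length(u)))
  structure(list(
    spec = spec, coefficients = unname(coef), t_scale = t_scale,
    rmse = rmse(v, pred),
    r2 = tryCatch(r_squared(v, pred), error = function(e) NA_real_),
    converged = converged
  ), class = "fitted_curve")
}

#' @export
print.fitted_curve <- function(x, ...) {
  cat(sprintf("<fitted_curve>: %s, %d coefficients, RMSE %.4g, R^2 %.6g%s\n",
              spec_label(x$spec), length(x$coefficients), x$rmse, x$r2,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Evaluate a fitted curve at new times
#'
#' @param object a `fitted_curve`.
#' @param t time values in the units of the original fit.
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.fitted_curve <- function(object, t, ...) {
  evaluate_function(object$spec, object$coefficients, t, object$t_scale)
}

#' Stage 5: fit the final activation function to predicted points
#'
#' Fits the chosen family (rational 4/4 or 8-term Fourier) to the 100
#' predicted sample points of one configuration, then recomputes the fit
#' metrics against the configuration's full simulated mean curve, giving
#' the end-to-end measure of how well the surrogate reproduces the
#' simulation it never saw.
#'
#' @param predicted_points data.frame with columns `time_us` and a
#'   prediction column (`y_pred`, or `percent_open`).
#' @param spec a [family_spec()]; conventionally `rational 4/4` or
#'   `fourier 8`.
#' @param full_curve optional [activation_curve()]; when supplied, `rmse`
#'   and `r2` of the returned fit are computed against this full curve
#'   rather than the input points.
#' @param ... passed to [fit_function()].
#' @return a `fitted_curve`.
#' @export
fit_final_curve <- function(predicted_points, spec, full_curve = NULL, ...) {
  v <- predicted_points$y_pred %||% predicted_points$percent_open
  t <- predicted_points$time_us
  t_scale <- if (!is.null(full_curve)) max(full_curve$times) else NULL
  fit <- fit_function(t, v, spec, t_scale = t_scale, ...)
  if (!is.null(full_curve)) {
    pred <- tryCatch(predict(fit, full_curve$times),
                     error = function(e) rep(NA_real_, length(full_curve$times)))
    fit$rmse <- rmse(full_curve$values, pred)
    fit$r2 <- tryCatch(r_squared(full_curve$values, pred),
                       error = function(e) NA_real_)
  }
  fit
}

#' Rank the candidate function families over a corpus (Table-2 style study)
#'
#' Fits every candidate spec to every curve and tabulates the mean RMSE and
#' mean R^2 per family, with rank columns under each metric. Failed fits
#' (errors or non-convergence) are excluded from the means and counted.
#'
#' @param curves list of [activation_curve()] objects (typically mean
#'   curves, possibly downsampled for speed).
#' @param specs candidate list (default [enumerate_candidates()]).
#' @param seed multi-start seed forwarded to [fit_function()].
#' @param n_starts multi-starts per fit.
#' @return data.frame: `label`, `family`, `rmse`, `rank_rmse`, `r2`,
#'   `rank_r2`, `n_fit`, `n_failed`, sorted by `rank_rmse`.
#' @export
rank_candidates <- function(curves, specs = enumerate_candidates(),
                            seed = 1L, n_starts = 5L) {
  stopifnot(length(curves) >= 1)
  rows <- lapply(specs, function(spec) {
    rmses <- r2s <- numeric(0)
    failed <- 0L
    for (cv in curves) {
      fit <- tryCatch(fit_function(cv$times, cv$values, spec,
                                   n_starts = n_starts, seed = seed),
                      error = function(e) NULL)
      # a fit that merely stopped at the iteration cap still describes the
      # curve; failure means an error or a non-finite metric
      if (is.null(fit) || !is.finite(fit$rmse) || !is.finite(fit$r2)) {
        failed <- failed + 1L
      } else {
        rmses <- c(rmses, fit$rmse); r2s <- c(r2s, fit$r2)
      }
    }
    data.frame(label = spec_label(spec), family = spec$family,
               rmse = if (length(rmses)) mean(rmses) else Inf,
               r2 = if (length(r2s)) mean(r2s) else -Inf,
               n_fit = length(rmses), n_failed = failed)
  })
  tab <- do.call(rbind, rows)
  tab$rank_rmse <- rank(tab$rmse, ties.method = "first")
  tab$rank_r2 <- rank(-tab$r2, ties.method = "first")
  tab[order(tab$rank_rmse),
      c("label", "family", "rmse", "rank_rmse", "r2", "rank_r2",
        "n_fit", "n_failed")]
}

#' Linear model from synapse parameters to fitted coefficients
#'
#' The preliminary coefficient-estimation study: regresses each fitted
#' coefficient of a shared function family linearly on the five synapse
#' parameters, returning the slope matrix V (one row per coefficient, one
#' column per parameter), the intercepts, and the Pearson correlation of
#' each coefficient with each parameter.
#'
#' @param configs list of [synapse_config()] objects (>= 6).
#' @param fits list of `fitted_curve` objects sharing one spec, parallel to
#'   `configs`.
#' @return list of class `coefficient_linear_model`: `spec`, `V`
#'   (n_coef x 5 slopes), `intercept`, `correlations` (n_coef x 5).
#' @export
fit_coefficient_linear_model <- function(configs, fits) {
  stopifnot(length(configs) == length(fits), length(configs) >= 6)
  labels <- vapply(fits, function(f) spec_label(f$spec), "")
  if (length(unique(labels)) != 1)
    stop("all fits must share one function family spec", call. = FALSE)
  P <- t(vapply(configs, config_inputs, numeric(5)))
  C <- t(vapply(fits, function(f) f$coefficients,
                numeric(length(fits[[1]]$coefficients))))
  X <- cbind(1, P)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design: synapse parameters do not vary enough",
         call. = FALSE)
  B <- qr.solve(X, C)  # (1+5) x n_coef
  corr <- suppressWarnings(cor(C, P))
  corr[!is.finite(corr)] <- NA_real_
  structure(list(
    spec = fits[[1]]$spec,
    V = t(B[-1, , drop = FALSE]),         # n_coef x 5
    intercept = unname(B[1, ]),
    correlations = corr
  ), class = "coefficient_linear_model")
}

#' Pearson correlation of each synapse parameter with the peak amplitude
#'
#' Computes the peak value of each mean activation curve and correlates it
#' with each synapse parameter across the corpus. Parameters that are held
#' constant have no defined correlation and are reported absent (dropped),
#' not zero.
#'
#' @param configs list of [synapse_config()] objects (>= 3).
#' @param curves parallel list of [activation_curve()] objects.
#' @param include_dg also consider the diffusion coefficient.
#' @return named numeric vector of correlations for the varying parameters.
#' @export
peak_parameter_correlations <- function(configs, curves, include_dg = FALSE) {
  stopifnot(length(configs) == length(curves), length(configs) >= 3)
  P <- t(vapply(configs, config_inputs, include_dg = include_dg,
                numeric(if (include_dg) 6 else 5)))
  peaks <- vapply(curves, function(cv) max(cv$values), 1)
  varying <- apply(P, 2, function(col) sd(col) > 0)
  if (sd(peaks) == 0)
    stop("peak amplitudes are constant across the corpus", call. = FALSE)
  vapply(colnames(P)[varying], function(p) cor(peaks, P[, p]), 1)
}
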