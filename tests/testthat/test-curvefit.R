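test_that("the candidate enumeration has 65 distinct specs", {
  cands <- enumerate_candidates()
  expect_length(cands, 65)
  labels <- vapply(cands, spec_label, "")
  expect_identical(anyDuplicated(labels), 0L)
  expect_identical(sum(grepl("^rational", labels)), 30L)
  expect_identical(sum(grepl("^polynomial", labels)), 9L)
})

test_that("coefficient counts match the family definitions", {
  expect_identical(n_coefficients(family_spec("fourier", 8)), 18L)
  expect_identical(n_coefficients(family_spec("rational", c(4, 4))), 9L)
  expect_identical(n_coefficients(family_spec("polynomial", 9)), 10L)
  expect_identical(n_coefficients(family_spec("exponential", 2)), 4L)
  expect_identical(n_coefficients(family_spec("gauss", 8)), 24L)
  expect_error(family_spec("rational", c(6, 4)), "order")
  expect_error(family_spec("polynomial", 0), "order")
})

test_that("function evaluation matches simple closed forms and guards poles", {
  expect_identical(evaluate_function(family_spec("polynomial", 1), c(0, 1), 3), 3)
  f8 <- c(2.5, rep(0, 16), 1)  # all harmonic amplitudes zero
  expect_identical(evaluate_function(family_spec("fourier", 8), f8, c(0, 5, 9)),
                   rep(2.5, 3))
  # denominator u - 0.5 has a root inside the evaluated range
  expect_error(
    evaluate_function(family_spec("rational", c(0, 1)), c(1, -0.5),
                      seq(0, 1, by = 0.01)),
    "pole")
  expect_error(evaluate_function(family_spec("fourier", 8), c(1, 2), 0),
               "coefficients")
})

test_that("fits are rejected when under-determined", {
  expect_error(fit_function(1:5, rnorm(5), family_spec("fourier", 8)),
               "under-determined")
})

test_that("noiseless self-family round trips recover the generating curve", {
  t <- seq(0, 10000, length.out = 400)
  cases <- list(
    list(spec = family_spec("polynomial", 3), coef = c(1, -2, 0.5, 0.3),
         tol = 1e-6),
    list(spec = family_spec("exponential", 2), coef = c(5, -3, -4, -0.5),
         tol = 1e-6),
    list(spec = family_spec("rational", c(4, 4)), coef = rational_test_coefs()[[1]],
         tol = 1e-4),
    list(spec = family_spec("gauss", 2), coef = c(3, 0.3, 0.1, 1, 0.6, 0.2),
         tol = 1e-4),
    list(spec = family_spec("sum_of_sine", 2), coef = c(2, 3, 0.5, 1, 7, 0.2),
         tol = 1e-4),
    list(spec = family_spec("fourier", 3),
         coef = c(0.5, 1, -0.3, 0.3, 0.2, -0.1, 0.05, 5.5), tol = 1e-4))
  for (cs in cases) {
    v <- evaluate_function(cs$spec, cs$coef, t, t_scale = 10000)
    fit <- fit_function(t, v, cs$spec)
    expect_gte(fit$r2, 1 - cs$tol)
  }
  # polynomial coefficients are recovered, not just the curve
  v <- evaluate_function(family_spec("polynomial", 3), c(1, -2, 0.5, 0.3), t,
                         t_scale = 10000)
  fit <- fit_function(t, v, family_spec("polynomial", 3))
  expect_lt(max(abs(fit$coefficients - c(1, -2, 0.5, 0.3))), 1e-6)
})

test_that("fits with fixed seeds are bit-reproducible", {
  cv <- reference_curve()$curve
  f1 <- fit_function(cv$times, cv$values, family_spec("rational", c(4, 4)),
                     seed = 5)
  f2 <- fit_function(cv$times, cv$values, family_spec("rational", c(4, 4)),
                     seed = 5)
  expect_identical(f1$coefficients, f2$coefficients)
})

test_that("curve-fit metrics agree with the shared RMSE/R^2 implementation", {
  cv <- reference_curve()$curve
  fit <- fit_function(cv$times, cv$values, family_spec("polynomial", 5))
  pred <- predict(fit, cv$times)
  expect_equal(fit$rmse, rmse(cv$values, pred))
  expect_equal(fit$r2, r_squared(cv$values, pred))
})

test_that("rational curves are recognized as their own family in the ranking", {
  t <- seq(0, 10000, length.out = 201)
  spec44 <- family_spec("rational", c(4, 4))
  curves <- lapply(rational_test_coefs(), function(cf)
    activation_curve(t, evaluate_function(spec44, cf, t, t_scale = 10000)))
  # one candidate per family: the nested higher-order rationals that fit a
  # 4/4 curve equally well are excluded so optimality is unambiguous
  specs <- list(spec44, family_spec("fourier", 8), family_spec("gauss", 8),
                family_spec("sum_of_sine", 8), family_spec("exponential", 2),
                family_spec("polynomial", 9))
  tab <- rank_candidates(curves, specs = specs, n_starts = 2)
  expect_identical(tab$label[tab$rank_rmse == 1], "rational 4/4")
  expect_lt(tab$rmse[tab$label == "rational 4/4"], 1e-6)
})

test_that("family ranking on simulated curves mirrors the selection study", {
  sc <- small_corpus()
  idx <- seq(1, 10001, by = 50)
  curves <- lapply(sc$curves[1:8], function(cv)
    activation_curve(cv$times[idx], cv$values[idx]))
  tab <- rank_candidates(curves, n_starts = 2)
  expect_identical(sort(tab$rank_rmse), 1:65)
  expect_identical(sort(tab$rank_r2), 1:65)
  # the two families used in the final stage describe these curves nearly
  # perfectly and sit in the upper part of the ranking; compact low-order
  # families trail far behind, as in the published selection study. The
  # compartmental mean curves are smoother than particle-simulation
  # averages, so flexible high-order families (gauss, nested rationals)
  # can edge out rational 4/4 here; its exact rank is not asserted.
  r2_44 <- tab$r2[tab$label == "rational 4/4"]
  expect_gt(r2_44, 0.99)
  expect_lte(tab$rank_r2[tab$label == "rational 4/4"], 25)
  expect_lte(tab$rank_r2[tab$label == "fourier 8"], 12)
  expect_gt(r2_44, tab$r2[tab$label == "polynomial 2"])
  expect_gt(r2_44, tab$r2[tab$label == "exponential 1"])
})

test_that("coefficient linear models recover an exactly linear construction", {
  configs <- sample_configs(15, seed = 77)
  P <- t(vapply(configs, config_inputs, numeric(5)))
  spec <- family_spec("polynomial", 2)
  W <- matrix(c(0.5, -0.2, 0.001, 0.01, 0.1,
                0, 0.3, -0.004, 0.02, -0.5,
                1, 0, 0.002, -0.03, 0.25), nrow = 3, byrow = TRUE)
  intercepts <- c(1, -2, 0.5)
  C <- sweep(P %*% t(W), 2, intercepts, "+")
  fits <- lapply(seq_len(nrow(P)), function(i)
    structure(list(spec = spec, coefficients = C[i, ], t_scale = 1,
                   rmse = 0, r2 = 1, converged = TRUE),
              class = "fitted_curve"))
  clm <- fit_coefficient_linear_model(configs, fits)
  expect_identical(dim(clm$V), c(3L, 5L))
  expect_lt(max(abs(clm$V - W)), 1e-8)
  expect_lt(max(abs(clm$intercept - intercepts)), 1e-8)

  # a coefficient equal to the side length correlates perfectly with it
  C2 <- C; C2[, 1] <- P[, "side_length"]
  fits2 <- lapply(seq_len(nrow(P)), function(i)
    structure(list(spec = spec, coefficients = C2[i, ], t_scale = 1,
                   rmse = 0, r2 = 1, converged = TRUE),
              class = "fitted_curve"))
  clm2 <- fit_coefficient_linear_model(configs, fits2)
  expect_equal(unname(clm2$correlations[1, "side_length"]), 1)

  # identical configurations cannot support the regression
  same <- replicate(8, configs[[1]], simplify = FALSE)
  expect_error(fit_coefficient_linear_model(same, fits[1:8]),
               "rank-deficient")
})

test_that("peak correlations flag the dominant negative geometry effect", {
  # constructed corpus: only L_s varies and the peak falls with it
  ls_vals <- seq(150, 750, length.out = 10)
  configs <- lapply(seq_along(ls_vals), function(i)
    synapse_config(2000, 5000, ls_vals[i], 15, 1.5, config_id = i))
  curves <- lapply(seq_along(ls_vals), function(i) {
    peak <- 30 - 0.03 * ls_vals[i]
    activation_curve(0:100, c(seq(0, peak, length.out = 51),
                              seq(peak, 0, length.out = 51)[-1]))
  })
  cors <- peak_parameter_correlations(configs, curves)
  expect_lte(cors[["side_length"]], -0.9)
  # constant parameters are absent, not zero
  expect_false("ampa_density" %in% names(cors))

  # on the simulated corpus the synapse size dominates, inversely
  sc <- small_corpus()
  cors2 <- peak_parameter_correlations(sc$configs, sc$curves)
  expect_identical(names(which.max(abs(cors2))), "side_length")
  expect_lt(cors2[["side_length"]], 0)
})
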