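test_that("geometry reduction gives the documented receptor counts and volumes", {
  m <- build_model(synapse_config(2000, 5000, 500, 15, 1.5))
  expect_identical(m$receptor_count, 500L)   # 2000 / um^2 x 0.25 um^2
  m2 <- build_model(synapse_config(1000, 0, 150, 15, 1))
  expect_identical(m2$receptor_count, 23L)   # round(1000 x 0.0225), half up
  # E = 1: no perisynaptic annulus, cleft feeds the outer compartment
  expect_identical(m2$peri_volume, 0)
  expect_true(m2$cleft_to_outer)
  expect_identical(m2$transporter_counts[["peri"]], 0L)
  expect_identical(m$cleft_volume, 500^2 * 15)
  expect_gt(m$peri_volume, 0)
})

test_that("extracellular space is 20% of the enclosing volume", {
  for (cfg in list(synapse_config(1000, 0, 150, 20, 1),
                   synapse_config(3000, 10000, 750, 15, 2),
                   synapse_config(2000, 5000, 450, 18, 1.3))) {
    expect_equal(extracellular_fraction(build_model(cfg)), 20, tolerance = 1e-6)
  }
})

test_that("simulation starts closed, conserves molecules, and is seeded", {
  m <- build_model(synapse_config(2000, 5000, 300, 15, 1.5))
  cv <- simulate_once(m, seed = 11, keep_full = TRUE)
  expect_identical(cv$values[1], 0)
  expect_true(all(cv$values >= 0 & cv$values <= 100))
  expect_length(cv$values, 10001)

  # receptor conservation at every step
  expect_true(all(rowSums(cv$full$receptor_counts) == m$receptor_count))
  # transporter conservation per compartment
  expect_true(all(rowSums(cv$full$transporter_peri) ==
                    m$transporter_counts[["peri"]]))
  expect_true(all(rowSums(cv$full$transporter_outer) ==
                    m$transporter_counts[["outer"]]))
  # glutamate: free + receptor-bound + transporter-bound + absorbed = N_glu
  rsch <- m$receptor_scheme
  tsch <- m$transporter_scheme
  r_bound <- cv$full$receptor_counts %*% rsch$bound_glu
  t_bound <- (cv$full$transporter_peri + cv$full$transporter_outer) %*%
    tsch$bound_glu
  total <- rowSums(cv$full$glutamate) + r_bound + t_bound
  expect_true(all(total == m$config$vesicle_count))

  # seeded determinism / seed sensitivity
  expect_identical(simulate_once(m, seed = 11)$values, cv$values)
  expect_false(identical(simulate_once(m, seed = 12)$values, cv$values))
})

test_that("no ligand means no activation", {
  cfg <- synapse_config(2000, 5000, 300, 15, 1.5, vesicle_count = 0)
  cv <- simulate_once(build_model(cfg), seed = 1)
  expect_true(all(cv$values == 0))
})

test_that("a kinetic scheme too fast for the step is reported, not silently capped", {
  fast <- kinetic_scheme(
    c("A", "O"), c(0, 0), "A", "O",
    data.frame(from = c("A", "O"), to = c("O", "A"), rate = c(1e7, 1e7),
               ligand_order = 0, consumes = FALSE))
  m <- build_model(synapse_config(2000, 0, 500, 15, 1), receptor_scheme = fast)
  expect_error(simulate_once(m, seed = 1, steps = 100), "smaller dt")
})

test_that("mean_activation averages runs and n_runs = 1 is a single run", {
  cfg <- synapse_config(2000, 5000, 300, 15, 1.5)
  one <- mean_activation(cfg, n_runs = 1, seed = 5)
  expect_equal(one$values, simulate_once(build_model(cfg), seed = 5)$values)
  expect_identical(one$meta$n_runs_averaged, 1L)
  m3 <- mean_activation(cfg, n_runs = 3, seed = 5)
  runs <- sapply(5:7, function(s) simulate_once(build_model(cfg), seed = s)$values)
  expect_equal(m3$values, rowMeans(runs))
})

test_that("averaging more runs shrinks the spread of the peak estimate", {
  m <- build_model(synapse_config(1500, 2000, 200, 15, 1.2))
  peaks <- function(n_runs, reps)
    vapply(seq_len(reps), function(r)
      max(mean_activation(m, n_runs = n_runs, seed = 30000 + r * n_runs)$values), 1)
  expect_lt(sd(peaks(20, 8)), sd(peaks(3, 8)))
})

test_that("stochastic mean approaches the mean-field ODE at high copy numbers", {
  m <- build_model(synapse_config(3000, 2000, 500, 15, 1.5))
  # x10 copy numbers: the tau-leap law is unchanged, fluctuations shrink
  m$receptor_count <- m$receptor_count * 10L
  m$config$vesicle_count <- m$config$vesicle_count * 10L
  ode <- ode_reference(m)
  acc <- numeric(10001)
  n_runs <- 60
  for (i in seq_len(n_runs))
    acc <- acc + simulate_once(m, seed = 800 + i)$values
  expect_lt(max(abs(acc / n_runs - ode$values)), 1)  # percentage points
})

test_that("mean-field curve is smooth and single-peaked; peak falls with synapse size", {
  peaks <- vapply(c(150, 300, 450, 600, 750), function(ls) {
    oc <- ode_reference(build_model(synapse_config(2000, 5000, ls, 15, 2)))
    d <- diff(oc$values)
    s <- sign(d[abs(d) > 1e-9])
    expect_lte(sum(diff(s) != 0), 2)
    max(oc$values)
  }, 1)
  expect_true(all(diff(peaks) < 0))
})

test_that("without ligand drive the mean-field curve is identically zero", {
  gated <- kinetic_scheme(
    c("C0", "O"), c(0, 1), "C0", "O",
    data.frame(from = c("C0", "O"), to = c("O", "C0"), rate = c(1e7, 1e3),
               ligand_order = c(1, 0), consumes = FALSE))
  cfg <- synapse_config(2000, 0, 500, 15, 1, vesicle_count = 0)
  oc <- ode_reference(build_model(cfg, receptor_scheme = gated), steps = 100)
  expect_true(all(abs(oc$values) < 1e-10))
})

test_that("curve CSV round trip is bit exact", {
  cv <- simulate_once(build_model(synapse_config(2000, 5000, 300, 15, 1.5)),
                      seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_curve_csv(cv, path)
  back <- read_curve_csv(path)
  expect_identical(back$times, cv$times)
  expect_identical(back$values, cv$values)
})
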