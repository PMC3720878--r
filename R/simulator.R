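#' Build the reduced compartmental model for a synapse configuration
#'
#' Reduces the 3D synapse geometry to three well-mixed extracellular
#' compartments in series with a perfect sink: the synaptic cleft (side
#' `L_s`, height `H_c`), the perisynaptic apposition annulus (area
#' `(E^2 - 1) * L_s^2`, same height), and an outer extracellular compartment
#' sized so that the total extracellular space is exactly 20% of the
#' enclosing tissue volume (taken as a cube of side `2 * E * L_s`).
#' Glutamate escapes cleft -> peri -> outer -> sink with first-order rate
#' constants derived from the diffusion coefficient and the compartment
#' dimensions (cleft: `8 D / L_s^2`, i.e. a characteristic radial escape
#' time `r^2 / (4D)` with `r = L_s / 2` and a fixed factor 2 for the two
#' membrane exits; peri and outer analogous with their own characteristic
#' radii). With `E = 1` the annulus vanishes and the cleft feeds the outer
#' compartment directly.
#'
#' Receptor count is `round([AMPA] * L_s^2)` (L_s in um). Transporters are
#' placed on the extrasynaptic membranes: the two apposed faces of the
#' annulus, and the outer membranes whose area is the outer volume divided
#' by half the intercellular gap. The gap is interpolated linearly from
#' 38 nm to 65 nm as `L_s` runs from 150 to 750 nm.
#'
#' @param config a [synapse_config()].
#' @param receptor_scheme kinetic scheme for the receptors (default the
#'   bundled 7-state AMPA scheme).
#' @param transporter_scheme kinetic scheme for the transporters (default
#'   the bundled 3-state cycle).
#' @return Object of class `compartment_model`.
#' @examples
#' m <- build_model(synapse_config(2000, 5000, 500, 15, 1.5))
#' m$receptor_count  # 500
#' @export
build_model <- function(config,
                        receptor_scheme = default_ampa_scheme(),
                        transporter_scheme = default_transporter_scheme()) {
  validate_config(config)
  if (is.na(receptor_scheme$open))
    stop("receptor scheme must designate an open state", call. = FALSE)
  ls_nm <- config$side_length
  hc <- config$cleft_height
  e <- config$apposition_factor
  d_nm2_us <- config$glu_diffusion * 1000  # um^2/ms -> nm^2/us

  cleft_volume <- ls_nm^2 * hc
  peri_area_nm2 <- (e^2 - 1) * ls_nm^2
  peri_volume <- peri_area_nm2 * hc
  enclosing_volume <- (2 * e * ls_nm)^3
  ecs_volume <- 0.20 * enclosing_volume
  outer_volume <- ecs_volume - cleft_volume - peri_volume
  if (outer_volume <= 0)
    stop("degenerate geometry: outer compartment volume non-positive",
         call. = FALSE)

  gap_nm <- 38 + (65 - 38) * (ls_nm - 150) / (750 - 150)
  gap_nm <- min(max(gap_nm, 38), 65)

  # half-up rounding (not banker's): a density that lands exactly on .5
  # receptors rounds up
  half_up <- function(x) floor(x + 0.5)
  receptor_count <- max(1L, as.integer(half_up(
    config$ampa_density * (ls_nm / 1000)^2)))
  peri_membrane_um2 <- 2 * peri_area_nm2 / 1e6  # both apposed faces
  outer_membrane_um2 <- (outer_volume / (gap_nm / 2)) / 1e6
  transporter_counts <- c(
    peri = as.integer(half_up(config$transporter_density * peri_membrane_um2)),
    outer = as.integer(half_up(config$transporter_density * outer_membrane_um2)))

  k_cleft <- 8 * d_nm2_us / ls_nm^2
  r_peri <- (e - 1) * ls_nm / 2 + gap_nm
  k_peri <- if (e > 1) 2 * d_nm2_us / r_peri^2 else 0
  r_outer <- e * ls_nm
  k_outer <- 4 * d_nm2_us / r_outer^2

  structure(list(
    config = config,
    cleft_volume = cleft_volume,
    peri_volume = peri_volume,
    outer_volume = outer_volume,
    enclosing_volume = enclosing_volume,
    gap_nm = gap_nm,
    receptor_count = receptor_count,
    transporter_counts = transporter_counts,
    escape_rates = c(cleft_peri = k_cleft, peri_outer = k_peri,
                     outer_sink = k_outer),
    cleft_to_outer = (e <= 1),
    receptor_scheme = receptor_scheme,
    transporter_scheme = transporter_scheme
  ), class = "compartment_model")
}

#' @export
print.compartment_model <- function(x, ...) {
  cat(sprintf(paste0("<compartment_model>: N_R=%d, transporters peri=%d outer=%d,\n",
                     "  volumes (nm^3) cleft=%.3g peri=%.3g outer=%.3g (ECS = 20%% of %.3g)\n"),
              x$receptor_count, x$transporter_counts[["peri"]],
              x$transporter_counts[["outer"]], x$cleft_volume, x$peri_volume,
              x$outer_volume, x$enclosing_volume))
  invisible(x)
}

#' Extracellular volume fraction of a compartment model
#'
#' Ratio of the total extracellular compartment volume (cleft + perisynaptic
#' + outer) to the enclosing tissue volume, in percent. The geometry builder
#' constructs the outer compartment so that this is 20%.
#'
#' @param model a `compartment_model`.
#' @return numeric percentage.
#' @export
extracellular_fraction <- function(model) {
  100 * (model$cleft_volume + model$peri_volume + model$outer_volume) /
    model$enclosing_volume
}

# translate a kinetic scheme into the flat arrays the engine consumes;
# rates converted from per-second to per-microsecond
scheme_arrays <- function(scheme) {
  tr <- scheme$transitions
  idx <- function(s) match(s, scheme$states) - 1L
  list(
    n_states = length(scheme$states),
    from = idx(tr$from), to = idx(tr$to),
    rate = tr$rate * 1e-6,
    order = as.integer(tr$ligand_order),
    dglu = as.integer(scheme$bound_glu[match(tr$to, scheme$states)] -
                        scheme$bound_glu[match(tr$from, scheme$states)]),
    consumes = tr$consumes,
    initial = idx(scheme$initial),
    open = if (is.na(scheme$open)) -1L else idx(scheme$open),
    bound_glu = scheme$bound_glu
  )
}

#' Construct an activation curve object
#'
#' @param times time grid in microseconds.
#' @param values percentage of receptors in the open state at each time.
#' @param config_id,n_runs_averaged,seed metadata carried in `meta`.
#' @return Object of class `activation_curve`.
#' @export
activation_curve <- function(times, values, config_id = NA_integer_,
                             n_runs_averaged = 1L, seed = NA_integer_) {
  stopifnot(length(times) == length(values))
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 meta = list(config_id = config_id,
                             n_runs_averaged = n_runs_averaged, seed = seed)),
            class = "activation_curve")
}

#' @export
print.activation_curve <- function(x, ...) {
  cat(sprintf("<activation_curve>: %d points over [%g, %g] us, peak %.3f%% at t=%g us (mean of %d run%s)\n",
              length(x$times), min(x$times), max(x$times), max(x$values),
              x$times[which.max(x$values)], x$meta$n_runs_averaged,
              if (x$meta$n_runs_averaged == 1) "" else "s"))
  invisible(x)
}

#' Simulate one stochastic run of a compartment model
#'
#' Fixed-step binomial tau-leap over the receptor states, transporter states
#' and glutamate pools. `vesicle_count` glutamate molecules are placed in
#' the cleft at t = 0 with all receptors in the initial (unliganded, closed)
#' state, and the system is advanced for `steps` iterations of `dt`
#' microseconds. Per-channel transition probabilities are capped at 1; the
#' run errors out if capped transitions exceed 10% of all transitions,
#' which signals a scheme/time-step mismatch.
#'
#' @param model a `compartment_model` from [build_model()].
#' @param seed integer seed; runs are bit-reproducible given the seed.
#' @param steps number of iterations (default 10000, i.e. 10 ms at 1 us).
#' @param dt time step in microseconds (default 1).
#' @param keep_full also return full per-step state count trajectories
#'   (receptors, transporters, glutamate pools) for diagnostics.
#' @return An [activation_curve()]; with `keep_full = TRUE` the curve has an
#'   additional `full` element with the count matrices.
#' @export
simulate_once <- function(model, seed = 1L, steps = 10000L, dt = 1,
                          keep_full = FALSE) {
  r <- scheme_arrays(model$receptor_scheme)
  t <- scheme_arrays(model$transporter_scheme)
  r_init <- integer(r$n_states); r_init[r$initial + 1L] <- model$receptor_count
  tp_init <- integer(t$n_states)
  to_init <- integer(t$n_states)
  tp_init[t$initial + 1L] <- model$transporter_counts[["peri"]]
  to_init[t$initial + 1L] <- model$transporter_counts[["outer"]]
  set.seed(seed)
  res <- sim_tauleap_cpp(
    as.integer(steps), dt,
    r_init, r$from, r$to, r$rate, r$order, r$dglu, r$consumes, r$open,
    tp_init, to_init, t$from, t$to, t$rate, t$order, t$dglu, t$consumes,
    model$config$vesicle_count,
    c(model$cleft_volume, model$peri_volume, model$outer_volume),
    unname(model$escape_rates), model$cleft_to_outer, keep_full)
  if (res$total_events > 0 && res$cap_events / res$total_events > 0.10)
    stop(sprintf(paste0("transition probabilities capped for %.1f%% of events; ",
                        "the kinetic rates are too fast for the time step - ",
                        "use a smaller dt"),
                 100 * res$cap_events / res$total_events), call. = FALSE)
  curve <- activation_curve(
    times = seq(0, by = dt, length.out = steps + 1),
    values = 100 * res$open_counts / model$receptor_count,
    config_id = model$config$config_id, n_runs_averaged = 1L, seed = seed)
  if (keep_full)
    curve$full <- res[c("receptor_counts", "transporter_peri",
                        "transporter_outer", "glutamate")]
  curve
}

#' Mean activation curve over repeated stochastic runs
#'
#' Pointwise mean of `n_runs` independent [simulate_once()] curves with
#' consecutive seeds starting at `seed`. This is the corpus-generating
#' operation: each synapse configuration in a corpus is represented by the
#' average of its repeated runs (default 200).
#'
#' @param config a [synapse_config()], or a prebuilt `compartment_model`.
#' @param n_runs number of runs to average (default 200).
#' @param seed base seed; run i uses `seed + i - 1`.
#' @param steps,dt time grid, as in [simulate_once()].
#' @param receptor_scheme,transporter_scheme kinetic schemes passed to
#'   [build_model()] when `config` is a configuration.
#' @return An [activation_curve()] with `meta$n_runs_averaged = n_runs`.
#' @export
mean_activation <- function(config, n_runs = 200L, seed = 1L,
                            steps = 10000L, dt = 1,
                            receptor_scheme = default_ampa_scheme(),
                            transporter_scheme = default_transporter_scheme()) {
  stopifnot(n_runs >= 1)
  model <- if (inherits(config, "compartment_model")) config
           else build_model(config, receptor_scheme, transporter_scheme)
  acc <- numeric(steps + 1)
  for (i in seq_len(n_runs)) {
    acc <- acc + simulate_once(model, seed = seed + i - 1L,
                               steps = steps, dt = dt)$values
  }
  activation_curve(seq(0, by = dt, length.out = steps + 1), acc / n_runs,
                   config_id = model$config$config_id,
                   n_runs_averaged = as.integer(n_runs), seed = seed)
}

#' Write / read an activation curve as CSV
#'
#' Columns `time_us`, `percent_open`. The round trip is bit-exact (values
#' are written with full precision).
#'
#' @param curve an [activation_curve()].
#' @param path CSV path.
#' @export
write_curve_csv <- function(curve, path) {
  df <- data.frame(time_us = curve$times,
                   percent_open = format(curve$values, digits = 17,
                                         scientific = TRUE, trim = TRUE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  df <- read.csv(path)
  activation_curve(df$time_us, df$percent_open)
}
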