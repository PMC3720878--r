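#' Default synapse parameter ranges
#'
#' The sampling ranges for the five (optionally six) physical parameters of a
#' model synapse: AMPA receptor density on the PSD, glutamate transporter
#' density on extrasynaptic membranes, synapse side length, synaptic cleft
#' height, apposition factor (total apposition side = E times the synapse
#' side) and, when the extended scenario is enabled, the glutamate diffusion
#' coefficient.
#'
#' @param include_dg logical; include the `glu_diffusion` range used by the
#'   extended six-variable scenario (0.25--0.75 um^2/ms).
#' @return Named list of length-2 numeric ranges. Units: densities per um^2,
#'   lengths nm, diffusion um^2/ms.
#' @export
default_ranges <- function(include_dg = FALSE) {
  r <- list(
    ampa_density        = c(1000, 3000),
    transporter_density = c(0, 10000),
    side_length         = c(150, 750),
    cleft_height        = c(15, 20),
    apposition_factor   = c(1, 2)
  )
  if (include_dg) r$glu_diffusion <- c(0.25, 0.75)
  r
}

# hard validity bounds for each parameter (ranges may be narrowed, not widened)
.param_bounds <- list(
  ampa_density        = c(1000, 3000),
  transporter_density = c(0, 10000),
  side_length         = c(150, 750),
  cleft_height        = c(15, 20),
  apposition_factor   = c(1, 2),
  glu_diffusion       = c(1e-6, Inf)
)

#' Construct a synapse configuration
#'
#' @param ampa_density AMPA receptor density on the PSD, receptors per um^2
#'   (1000--3000).
#' @param transporter_density glutamate transporter density on extrasynaptic
#'   membranes, molecules per um^2 (0--10000).
#' @param side_length side length of the square synaptic junction, nm
#'   (150--750).
#' @param cleft_height synaptic cleft height, nm (15--20).
#' @param apposition_factor dimensionless factor E in \[1, 2\]; the total
#'   apposition of pre- and postsynaptic membranes has side `E * side_length`.
#' @param glu_diffusion glutamate diffusion coefficient, um^2/ms (> 0;
#'   default 0.4).
#' @param vesicle_count glutamate molecules released at t = 0 (default 5000).
#' @param config_id optional identifier carried through pipeline artifacts.
#' @return Object of class `synapse_config`.
#' @examples
#' cfg <- synapse_config(2000, 5000, 600, 15, 2)
#' @export
synapse_config <- function(ampa_density, transporter_density, side_length,
                           cleft_height, apposition_factor,
                           glu_diffusion = 0.4, vesicle_count = 5000,
                           config_id = NA_integer_) {
  cfg <- structure(list(
    ampa_density = as.numeric(ampa_density),
    transporter_density = as.numeric(transporter_density),
    side_length = as.numeric(side_length),
    cleft_height = as.numeric(cleft_height),
    apposition_factor = as.numeric(apposition_factor),
    glu_diffusion = as.numeric(glu_diffusion),
    vesicle_count = as.integer(round(vesicle_count)),
    config_id = config_id
  ), class = "synapse_config")
  validate_config(cfg)
  cfg
}

#' @export
print.synapse_config <- function(x, ...) {
  cat("<synapse_config>",
      sprintf("[AMPA]=%g /um^2, [T]=%g /um^2, Ls=%g nm, Hc=%g nm, E=%g, Dg=%g um^2/ms, Nglu=%d",
              x$ampa_density, x$transporter_density, x$side_length,
              x$cleft_height, x$apposition_factor, x$glu_diffusion,
              x$vesicle_count), "\n")
  invisible(x)
}

validate_config <- function(cfg) {
  for (p in names(.param_bounds)) {
    v <- cfg[[p]]
    b <- .param_bounds[[p]]
    if (!is.finite(v) || v < b[1] || v > b[2])
      stop(sprintf("synapse parameter '%s' = %g outside valid bounds [%g, %g]",
                   p, v, b[1], b[2]), call. = FALSE)
  }
  if (cfg$vesicle_count < 0)
    stop("vesicle_count must be a non-negative integer", call. = FALSE)
  invisible(cfg)
}

validate_ranges <- function(ranges) {
  for (p in names(ranges)) {
    b <- .param_bounds[[p]]
    if (is.null(b))
      stop(sprintf("unknown synapse parameter '%s' in ranges", p), call. = FALSE)
    r <- ranges[[p]]
    if (length(r) != 2 || !all(is.finite(r)) || r[1] > r[2])
      stop(sprintf("range for parameter '%s' is empty or inverted", p),
           call. = FALSE)
    if (r[1] < b[1] || r[2] > b[2])
      stop(sprintf("range [%g, %g] for parameter '%s' outside valid bounds [%g, %g]",
                   r[1], r[2], p, b[1], b[2]), call. = FALSE)
  }
  invisible(ranges)
}

#' Sample a corpus of synapse configurations
#'
#' Draws each parameter independently and uniformly from its range, the
#' scheme used to cover the parameter space when building a simulation
#' corpus. Sampling is deterministic given `seed`.
#'
#' @param n number of configurations (>= 0).
#' @param ranges named list of per-parameter ranges; see [default_ranges()].
#' @param include_dg logical; also sample `glu_diffusion` (extended
#'   scenario). When `FALSE`, `glu_diffusion` is fixed at 0.4 um^2/ms.
#' @param seed integer RNG seed.
#' @param vesicle_count glutamate molecules per vesicle (default 5000).
#' @return List of [synapse_config()] objects with `config_id` 1..n.
#' @export
sample_configs <- function(n, ranges = default_ranges(include_dg),
                           include_dg = FALSE, seed = 1L,
                           vesicle_count = 5000) {
  stopifnot(n >= 0)
  if (include_dg && is.null(ranges$glu_diffusion))
    ranges$glu_diffusion <- c(0.25, 0.75)
  validate_ranges(ranges)
  if (n == 0) return(list())
  params <- c("ampa_density", "transporter_density", "side_length",
              "cleft_height", "apposition_factor")
  if (include_dg) params <- c(params, "glu_diffusion")
  missing <- setdiff(params, names(ranges))
  if (length(missing))
    stop("ranges missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  set.seed(seed)
  draws <- lapply(params, function(p) {
    r <- ranges[[p]]
    runif(n, r[1], r[2])
  })
  names(draws) <- params
  lapply(seq_len(n), function(i) {
    synapse_config(
      ampa_density = draws$ampa_density[i],
      transporter_density = draws$transporter_density[i],
      side_length = draws$side_length[i],
      cleft_height = draws$cleft_height[i],
      apposition_factor = draws$apposition_factor[i],
      glu_diffusion = if (include_dg) draws$glu_diffusion[i] else 0.4,
      vesicle_count = vesicle_count,
      config_id = i
    )
  })
}

#' Convert a configuration corpus to a manifest data frame
#'
#' @param configs list of [synapse_config()] objects.
#' @param seed corpus-level seed recorded alongside each row.
#' @return data.frame with one row per configuration.
#' @export
configs_to_manifest <- function(configs, seed = NA_integer_) {
  data.frame(
    config_id = vapply(configs, function(c) as.integer(c$config_id), 1L),
    ampa_density = vapply(configs, `[[`, 1, "ampa_density"),
    transporter_density = vapply(configs, `[[`, 1, "transporter_density"),
    side_length_nm = vapply(configs, `[[`, 1, "side_length"),
    cleft_height_nm = vapply(configs, `[[`, 1, "cleft_height"),
    apposition_factor = vapply(configs, `[[`, 1, "apposition_factor"),
    glu_diffusion = vapply(configs, `[[`, 1, "glu_diffusion"),
    vesicle_count = vapply(configs, function(c) as.integer(c$vesicle_count), 1L),
    seed = seed
  )
}

#' Read a corpus manifest back into configuration objects
#'
#' @param path CSV file written from [configs_to_manifest()].
#' @return list of [synapse_config()] objects.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path)
  lapply(seq_len(nrow(m)), function(i) {
    synapse_config(
      ampa_density = m$ampa_density[i],
      transporter_density = m$transporter_density[i],
      side_length = m$side_length_nm[i],
      cleft_height = m$cleft_height_nm[i],
      apposition_factor = m$apposition_factor[i],
      glu_diffusion = m$glu_diffusion[i],
      vesicle_count = m$vesicle_count[i],
      config_id = m$config_id[i]
    )
  })
}
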