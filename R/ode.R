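#' Deterministic mean-field reference curve
#'
#' Integrates the same reaction network as [simulate_once()] treating all
#' molecule counts as continuous, on the same time grid. Serves as a
#' law-of-large-numbers oracle for the stochastic engine: as receptor,
#' transporter and glutamate copy numbers grow, the mean of many stochastic
#' runs converges to this curve.
#'
#' @param model a `compartment_model` from [build_model()].
#' @param steps,dt time grid, as in [simulate_once()].
#' @return An [activation_curve()].
#' @export
ode_reference <- function(model, steps = 10000L, dt = 1) {
  r <- scheme_arrays(model$receptor_scheme)
  tt <- scheme_arrays(model$transporter_scheme)
  nR <- r$n_states; nT <- tt$n_states
  mol <- 0.6022140857  # molecules per nm^3 per molar
  vols <- c(model$cleft_volume, model$peri_volume, model$outer_volume)
  esc <- unname(model$escape_rates)
  cleft_to_outer <- model$cleft_to_outer

  y0 <- numeric(nR + 2 * nT + 4)
  y0[r$initial + 1L] <- model$receptor_count
  y0[nR + tt$initial + 1L] <- model$transporter_counts[["peri"]]
  y0[nR + nT + tt$initial + 1L] <- model$transporter_counts[["outer"]]
  y0[nR + 2 * nT + 1L] <- model$config$vesicle_count  # cleft free glu

  pool_flux <- function(counts, arr, conc, glu_idx) {
    # returns list(dcounts, dglu_free, dglu_sink)
    k <- ifelse(arr$order == 1, arr$rate * conc, arr$rate)
    flux <- k * counts[arr$from + 1L]
    dcounts <- numeric(length(counts))
    dfree <- 0; dsink <- 0
    for (j in seq_along(flux)) {
      f <- flux[j]
      dcounts[arr$from[j] + 1L] <- dcounts[arr$from[j] + 1L] - f
      dcounts[arr$to[j] + 1L] <- dcounts[arr$to[j] + 1L] + f
      if (arr$dglu[j] > 0) dfree <- dfree - f * arr$dglu[j]
      else if (arr$dglu[j] < 0) {
        if (arr$consumes[j]) dsink <- dsink - f * arr$dglu[j]
        else dfree <- dfree - f * arr$dglu[j]
      }
    }
    list(dcounts = dcounts, dfree = dfree, dsink = dsink)
  }

  deriv <- function(t, y, parms) {
    rc <- y[seq_len(nR)]
    tp <- y[nR + seq_len(nT)]
    tu <- y[nR + nT + seq_len(nT)]
    g <- y[nR + 2 * nT + 1:4]  # cleft, peri, outer, sink
    conc <- ifelse(vols > 0, g[1:3] / (mol * vols), 0)
    fr <- pool_flux(rc, r, conc[1], 1)
    fp <- pool_flux(tp, tt, conc[2], 2)
    fo <- pool_flux(tu, tt, conc[3], 3)
    dg <- numeric(4)
    dg[1] <- fr$dfree - esc[1] * g[1]
    if (cleft_to_outer) dg[3] <- dg[3] + esc[1] * g[1]
    else dg[2] <- dg[2] + esc[1] * g[1]
    dg[2] <- dg[2] + fp$dfree - esc[2] * g[2]
    dg[3] <- dg[3] + fo$dfree + esc[2] * g[2] - esc[3] * g[3]
    dg[4] <- esc[3] * g[3] + fr$dsink + fp$dsink + fo$dsink
    list(c(fr$dcounts, fp$dcounts, fo$dcounts, dg))
  }

  times <- seq(0, steps * dt, by = dt)
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-8)
  if (attr(sol, "istate")[1] < 0)
    stop("mean-field ODE integration failed", call. = FALSE)
  open_col <- 1L + r$open + 1L  # first column of sol is time
  activation_curve(times, 100 * sol[, open_col] / model$receptor_count,
                   config_id = model$config$config_id)
}
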