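#' Locate the peak interval of an activation curve
#'
#' The peak interval starts at t = 0, contains the rise to the global
#' maximum, and ends at the first time after the peak where the value has
#' fallen to 50% of the peak amplitude. Ties at the maximum resolve to the
#' earliest time; if the curve never falls to half the peak, the interval
#' extends to the last time (fallback).
#'
#' @param curve an [activation_curve()].
#' @return list with `t_start` (0), `t_end`, `peak_time`, `peak_value`,
#'   class `peak_interval`.
#' @export
find_peak_interval <- function(curve) {
  v <- curve$values
  t <- curve$times
  if (length(v) == 0 || max(v) <= 0)
    stop("degenerate curve: no positive values, peak interval undefined",
         call. = FALSE)
  ipk <- which.max(v)  # first index on ties
  half <- v[ipk] / 2
  after <- which(v <= half & seq_along(v) > ipk)
  iend <- if (length(after)) after[1] else length(v)
  structure(list(t_start = t[1], t_end = t[iend],
                 peak_time = t[ipk], peak_value = v[ipk]),
            class = "peak_interval")
}

# snap segment-start times up to the grid, advancing duplicates to the next
# unused grid point so exactly `length(starts)` distinct times come back
snap_to_grid <- function(starts, grid, used = numeric(0)) {
  out <- numeric(length(starts))
  taken <- used
  for (i in seq_along(starts)) {
    j <- which(grid >= starts[i] - 1e-9)[1]
    if (is.na(j)) j <- length(grid)
    while (j <= length(grid) && grid[j] %in% taken) j <- j + 1L
    if (j > length(grid))
      stop("not enough grid points to place all sample times", call. = FALSE)
    out[i] <- grid[j]
    taken <- c(taken, grid[j])
  }
  out
}

#' Reduce a curve to 100 representative points (Stage 1)
#'
#' Takes 50 points from the peak interval and 50 from the tail, in both
#' cases the beginnings of equal time segments, so that half of the sample
#' budget covers the short high-variability segment around the peak
#' (oversampling) and half covers the long quiet tail. Segment starts are
#' snapped up to the curve's time grid; collisions (possible when the peak
#' interval is shorter than 50 grid steps) advance to the next unused grid
#' point. When the peak interval extends to the end of the curve (fallback),
#' the whole curve is divided into 100 segments instead and a warning is
#' emitted.
#'
#' @param curve an [activation_curve()].
#' @param n_points total sample size (default 100, split evenly).
#' @return data.frame with columns `config_id`, `time_us`, `percent_open`,
#'   `section` (`"peak"` or `"tail"`), class `curve_sample`.
#' @export
sample_curve <- function(curve, n_points = 100L) {
  stopifnot(n_points >= 2, n_points %% 2 == 0)
  pk <- find_peak_interval(curve)
  grid <- curve$times
  t_last <- grid[length(grid)]
  half <- n_points %/% 2L
  if (pk$t_end >= t_last) {
    warning("peak interval extends to the end of the curve; sampling all ",
            n_points, " points from it", call. = FALSE)
    starts <- pk$t_end * (seq_len(n_points) - 1) / n_points
    times <- snap_to_grid(starts, grid)
    section <- rep("peak", n_points)
  } else {
    peak_starts <- pk$t_end * (seq_len(half) - 1) / half
    peak_times <- snap_to_grid(peak_starts, grid)
    tail_starts <- pk$t_end + (t_last - pk$t_end) * (seq_len(half) - 1) / half
    # the tail is open at t_end: marking t_end used advances the first tail
    # point to the next grid time
    tail_times <- snap_to_grid(tail_starts, grid, used = c(peak_times, pk$t_end))
    times <- c(peak_times, tail_times)
    section <- rep(c("peak", "tail"), each = half)
  }
  idx <- match(times, grid)
  out <- data.frame(
    config_id = rep(curve$meta$config_id %||% NA_integer_, n_points),
    time_us = times,
    percent_open = curve$values[idx],
    section = section)
  class(out) <- c("curve_sample", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
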