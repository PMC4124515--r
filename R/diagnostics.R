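#' Cumulative difference M(s, t) between a density and the stationary state
#'
#' `M(s, t) = int_0^s [n(x, t) - A(x)] dx`, evaluated at the right cell
#' edges by a running cumulative sum.  Since both profiles carry unit
#' mass, the last entry is (numerically) zero; `M` is the quantity whose
#' weighted L1 norm decays exponentially in the relaxation theory.
#'
#' @param state a `density_state`, or a plain vector of cell values on the
#'   same grid as `A_values` (then `ds` must be given).
#' @param A_values stationary density cell values.
#' @param ds cell width when `state` is a plain vector.
#' @return vector of `M` values at the right cell edges.
#' @export
cumulative_difference <- function(state, A_values, ds = NULL) {
  if (inherits(state, "density_state")) {
    v <- state$values; ds <- state$grid$ds
  } else {
    v <- state
    if (is.null(ds)) stop("ds is required when state is a plain vector")
  }
  if (length(v) != length(A_values))
    stop("grid mismatch: state and A have different cell counts")
  cumsum(v - A_values) * ds
}

#' Time derivative J(s, t) of the cumulative difference
#'
#' Finite-differences `M(s, t)` in time across stored snapshots: centered
#' differences in the interior, one-sided at the ends (exact on data
#' affine in time).
#'
#' @param traj a `trajectory` with at least two snapshots at uniform
#'   spacing.
#' @param A_values stationary density cell values.
#' @return matrix with one column of `J` values per snapshot time;
#'   snapshot times as column names.
#' @export
time_derivative_J <- function(traj, A_values) {
  k <- length(traj$snapshots)
  if (k < 2L) stop("at least two snapshots are required")
  tt <- traj$snapshot_times
  dts <- diff(tt)
  if (max(abs(dts - dts[1L])) > 1e-9 * max(dts))
    stop("snapshots must be uniformly spaced in time")
  ds <- traj$grid$ds
  Ms <- vapply(traj$snapshots,
               function(v) cumulative_difference(v, A_values, ds),
               numeric(traj$grid$n_cells))
  J <- Ms
  h <- dts[1L]
  J[, 1L] <- (Ms[, 2L] - Ms[, 1L]) / h
  J[, k] <- (Ms[, k] - Ms[, k - 1L]) / h
  if (k > 2L)
    J[, 2:(k - 1L)] <- (Ms[, 3:k] - Ms[, 1:(k - 2L)]) / (2 * h)
  colnames(J) <- format(tt)
  J
}

# time series of a decay functional evaluated on a trajectory
decay_functional_series <- function(traj, A_values, P_values = NULL,
                                    functional, A_star = NULL) {
  ds <- traj$grid$ds
  n <- traj$grid$n_cells
  edgeP <- function() {
    if (is.null(P_values)) stop(sprintf("%s requires P_values", functional))
    if (length(P_values) == n + 1L) P_values[-1L]     # node -> right edges
    else if (length(P_values) == n) P_values
    else stop("P_values length does not match the grid")
  }
  switch(functional,
    weighted_L1_M = {
      P <- edgeP()
      y <- vapply(traj$snapshots, function(v)
        ds * sum(P * abs(cumulative_difference(v, A_values, ds))),
        numeric(1))
      list(t = traj$snapshot_times, y = y)
    },
    L1_m = {
      y <- vapply(traj$snapshots, function(v)
        ds * sum(abs(v - A_values)), numeric(1))
      list(t = traj$snapshot_times, y = y)
    },
    weighted_L1_J = {
      P <- edgeP()
      J <- time_derivative_J(traj, A_values)
      list(t = traj$snapshot_times,
           y = apply(J, 2L, function(col) ds * sum(P * abs(col))))
    },
    activity_gap = {
      if (is.null(A_star)) stop("activity_gap requires A_star")
      list(t = traj$times, y = abs(traj$N - A_star))
    },
    stop("unknown functional: ", functional))
}

#' Fit an exponential decay rate to a relaxation functional
#'
#' Computes the chosen functional along the trajectory and fits a
#' least-squares line to its logarithm over the requested time window;
#' the estimated rate is minus the slope.  Times where the functional has
#' reached the double-precision floor (1e-13) are excluded, shrinking the
#' window if necessary.
#'
#' @param traj a `trajectory` (converged-regime).
#' @param A_values stationary density cell values.
#' @param P_values dual weight on the grid nodes or edges (for the
#'   weighted functionals).
#' @param functional one of `"weighted_L1_M"`, `"L1_m"`,
#'   `"weighted_L1_J"`, `"activity_gap"`.
#' @param window numeric `c(t0, t1)` fit window (default: all times).
#' @param A_star stationary activity (for `"activity_gap"`).
#' @return object of class `decay_report` with fields `nu_hat`,
#'   `functional`, `fit_window`, `r_squared`, `n_points`,
#'   `window_shrunk`.
#' @export
estimate_decay_rate <- function(traj, A_values = NULL, P_values = NULL,
                                functional = c("weighted_L1_M", "L1_m",
                                               "weighted_L1_J",
                                               "activity_gap"),
                                window = NULL, A_star = NULL) {
  functional <- match.arg(functional)
  ser <- decay_functional_series(traj, A_values, P_values, functional, A_star)
  t <- ser$t; y <- ser$y
  if (is.null(window)) window <- range(t)
  keep <- t >= window[1L] & t <= window[2L]
  floor_hit <- y <= 1e-13
  shrunk <- any(floor_hit & keep)
  keep <- keep & !floor_hit
  if (sum(keep) < 3L)
    stop("fewer than 3 usable points in the fit window")
  fit <- stats::lm(log(y[keep]) ~ t[keep])
  r2 <- suppressWarnings(summary(fit)$r.squared)   # exact fits warn
  structure(
    list(nu_hat = -unname(stats::coef(fit)[2L]),
         functional = functional,
         fit_window = range(t[keep]),
         r_squared = r2,
         n_points = sum(keep),
         window_shrunk = shrunk),
    class = "decay_report")
}

#' @export
print.decay_report <- function(x, ...) {
  cat(sprintf(
    "<decay_report> %s: nu_hat = %.6g (R^2 = %.4f, %d pts, window [%g, %g]%s)\n",
    x$functional, x$nu_hat, x$r_squared, x$n_points,
    x$fit_window[1L], x$fit_window[2L],
    if (x$window_shrunk) ", shrunk" else ""))
  invisible(x)
}

#' Classify the long-time regime of the activity trace
#'
#' Analyzes the last `late_fraction` of `N(t)`.  If the relative
#' amplitude (max minus min over the late-window mean) is below
#' `convergence_tol` the regime is `"converged"` with the mean as
#' plateau.  Otherwise peaks are detected as the maxima of excursions of
#' `N` above the mid-range level; at least 3 peaks with a spacing
#' coefficient of variation under 5% classify the trace as `"periodic"`
#' with the mean spacing as period, anything else as `"irregular"`.
#'
#' @param traj a `trajectory` covering at least 20 time units.
#' @param late_fraction fraction of the trace analyzed (default 0.5).
#' @param convergence_tol relative amplitude below which the trace counts
#'   as converged (default 1e-3).
#' @return object of class `oscillation_report` with fields `regime`,
#'   `period`, `amplitude`, `plateau`, `n_peaks`, `peak_times`.
#' @export
oscillation_analysis <- function(traj, late_fraction = 0.5,
                                 convergence_tol = 1e-3) {
  t <- traj$times; N <- traj$N
  if (max(t) - min(t) < 20)
    stop("trajectory too short: at least 20 time units are required")
  from <- max(t) - late_fraction * (max(t) - min(t))
  sel <- t >= from
  t <- t[sel]; N <- N[sel]
  amp <- max(N) - min(N)
  mu <- mean(N)
  if (amp < convergence_tol * max(abs(mu), .Machine$double.eps)) {
    return(structure(
      list(regime = "converged", period = NA_real_, amplitude = amp,
           plateau = mu, n_peaks = 0L, peak_times = numeric(0)),
      class = "oscillation_report"))
  }
  thr <- (max(N) + min(N)) / 2
  above <- N > thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  peak_times <- numeric(0)
  for (r in which(runs$values)) {
    i0 <- starts[r]; i1 <- ends[r]
    if (i0 == 1L || i1 == length(N)) next     # clipped excursions
    peak_times <- c(peak_times, t[i0 - 1L + which.max(N[i0:i1])])
  }
  period <- NA_real_; regime <- "irregular"
  if (length(peak_times) >= 3L) {
    sp <- diff(peak_times)
    if (stats::sd(sp) / mean(sp) < 0.05) {
      regime <- "periodic"; period <- mean(sp)
    }
  }
  structure(
    list(regime = regime, period = period, amplitude = amp,
         plateau = if (regime == "converged") mu else NA_real_,
         n_peaks = length(peak_times), peak_times = peak_times),
    class = "oscillation_report")
}

#' @export
print.oscillation_report <- function(x, ...) {
  cat(sprintf("<oscillation_report> regime = %s", x$regime))
  if (x$regime == "periodic")
    cat(sprintf(", period = %.4g (%d peaks)", x$period, x$n_peaks))
  if (x$regime == "converged")
    cat(sprintf(", plateau = %.6g", x$plateau))
  cat(sprintf(", amplitude = %.4g\n", x$amplitude))
  invisible(x)
}

#' Late-window discrepancy between two activity traces
#'
#' Maximum pointwise difference of `N(t)` over the common late window,
#' used to decide whether two initial profiles relax onto the same
#' long-time activity.  Because the dynamics is autonomous, two
#' trajectories on the same orbit are generally offset in phase;
#' `align_window > 0` searches time shifts up to that length and reports
#' the minimum discrepancy over shifts.  The difference is normalized by
#' `scale` — pass the rate ceiling `p_max` to measure on the activity
#' scale, or leave `NULL` to normalize by the late-window mean level.
#'
#' @param traj1,traj2 trajectories on the same time grid.
#' @param late_fraction fraction of the trace compared.
#' @param align_window maximum time shift searched (0: no alignment).
#' @param scale normalization (default: late-window mean level).
#' @return relative max discrepancy (scalar).
#' @export
late_discrepancy <- function(traj1, traj2, late_fraction = 0.5,
                             align_window = 0, scale = NULL) {
  if (length(traj1$times) != length(traj2$times) ||
      max(abs(traj1$times - traj2$times)) > 1e-9)
    stop("trajectories are on different time grids")
  t <- traj1$times
  sel <- t >= max(t) - late_fraction * (max(t) - min(t))
  N1 <- traj1$N[sel]; N2 <- traj2$N[sel]
  if (is.null(scale)) scale <- max(mean(c(N1, N2)), .Machine$double.eps)
  dt <- t[2L] - t[1L]
  K <- round(align_window / dt)
  n <- length(N1)
  best <- Inf
  for (k in -K:K) {
    i1 <- max(1L, 1L + k):min(n, n + k)
    d <- max(abs(N1[i1] - N2[i1 - k]))
    if (d < best) best <- d
  }
  best / scale
}
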