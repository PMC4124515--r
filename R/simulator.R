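#' Initial probability density on the elapsed-time axis
#'
#' Builds a nonnegative cell-average profile normalized so that the
#' discrete mass `ds * sum(values)` is exactly 1.
#' * `"exp_decay"`: the profile `e^{-s}` (the classical resting profile of
#'   a unit-rate renewal population);
#' * `"multi_bump"`: a sum of Gaussian bumps, a structured profile standing
#'   in for a partially synchronized population split into discharge
#'   clusters (parameters `centers`, `widths`, `weights`).
#'
#' @param kind `"exp_decay"` or `"multi_bump"`.
#' @param grid a [sim_grid()].
#' @param params list of parameters for `multi_bump`: `centers` (default
#'   `c(1, 5)`, two well-separated clusters), `widths` (default `0.2`,
#'   recycled), `weights` (default equal).
#' @return object of class `density_state` with fields `values`, `grid`,
#'   `time`.
#' @export
initial_data <- function(kind = c("exp_decay", "multi_bump"), grid,
                         params = list()) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "sim_grid"))
  s <- grid$centers
  if (kind == "exp_decay") {
    v <- exp(-s)
  } else {
    ctr <- params$centers %||% c(1, 5)
    wid <- rep_len(params$widths %||% 0.2, length(ctr))
    wgt <- rep_len(params$weights %||% 1, length(ctr))
    v <- numeric(grid$n_cells)
    for (k in seq_along(ctr))
      v <- v + wgt[k] * exp(-((s - ctr[k])^2) / (2 * wid[k]^2))
  }
  m <- grid$ds * sum(v)
  if (m <= 0) stop("normalization error: profile has zero mass")
  density_state(v / m, grid, time = 0)
}

density_state <- function(values, grid, time = 0) {
  structure(list(values = values, grid = grid, time = time),
            class = "density_state")
}

#' Discrete mass of a density state
#' @param state a `density_state`.
#' @return `ds * sum(values)`.
#' @export
state_mass <- function(state) state$grid$ds * sum(state$values)

#' @export
print.density_state <- function(x, ...) {
  cat(sprintf("<density_state> t = %g, mass = %.12g, %d cells\n",
              x$time, state_mass(x), x$grid$n_cells))
  invisible(x)
}

# integral of the piecewise-constant density over [x, s_max]; vectorized in x.
# accumulated from the right so the value at x = s_max is exactly zero
tail_mass <- function(values, grid, x) {
  ds <- grid$ds
  n <- grid$n_cells
  rcum <- c(rev(cumsum(rev(values))), 0) * ds  # mass from edge k to the end
  x <- pmin(pmax(x, 0), grid$s_max)
  k <- pmin(floor(x / ds), n - 1)              # 0-based cell containing x
  pmax(rcum[k + 1L] - (x - k * ds) * values[k + 1L], 0)
}

#' Solve the implicit total-activity equation
#'
#' The network activity at a given instant solves
#' `N = ds * sum( p(s_i, N) * n_i )`.  For rates with a constant threshold
#' the right-hand side does not depend on `N` and the solution is direct.
#' For the step family the equation is solved by scanning
#' `G(N) = p_max * tail(sigma(N)) - N` for sign changes on `[0, p_max]`
#' (with fractional-cell tail masses so `G` is continuous) and refining
#' each bracket by bisection; in the synchronized regime several roots may
#' coexist and the root closest to `previous_N` is returned
#' (`root_rule = "continuation"`, which reproduces hysteresis-driven
#' oscillations) or the largest root (`root_rule = "largest"`).  For the
#' regularized family a damped fixed-point iteration is used, with the
#' scan as a fallback.
#'
#' @param state a `density_state`.
#' @param rate a [firing_rate()].
#' @param previous_N activity at the previous step (continuation seed).
#' @param root_rule `"continuation"` or `"largest"`.
#' @param fp_tol solver tolerance.
#' @return the activity `N` in `[0, p_max]`.
#' @export
solve_total_activity <- function(state, rate, previous_N = 0,
                                 root_rule = c("continuation", "largest"),
                                 fp_tol = 1e-12, .sig_cache = NULL) {
  root_rule <- match.arg(root_rule)
  v <- state$values; grid <- state$grid
  pM <- rate$p_max
  ds <- grid$ds; n <- grid$n_cells

  # right-accumulated mass at the cell edges, computed once per call
  rcum <- c(rev(cumsum(rev(v))), 0) * ds
  tailx <- function(x) {          # integral over [x, s_max], O(1) per point
    x <- pmin(pmax(x, 0), grid$s_max)
    k <- pmin(floor(x / ds), n - 1)
    pmax(rcum[k + 1L] - (x - k * ds) * v[k + 1L], 0)
  }
  activity <- function(N)
    ds * sum(firing_rate_eval(rate, grid$centers, N) * v)

  if (rate$constant_sigma) {
    N <- if (rate$family == "step") pM * tailx(sigma_of(0, rate$threshold))
         else activity(0)
    return(min(max(N, 0), pM))
  }

  if (rate$family == "regularized") {
    N <- min(max(previous_N, 0), pM)
    for (it in seq_len(500L)) {
      N_new <- 0.5 * N + 0.5 * activity(N)
      if (abs(N_new - N) < fp_tol) return(N_new)
      N <- N_new
    }
    # fall through to the scan if the damped iteration stalls
  }

  g <- if (rate$family == "step") {
    function(N) pM * tailx(sigma_of(N, rate$threshold)) - N
  } else {
    function(N) activity(N) - N
  }
  n_scan <- if (rate$family == "step") 2049L else 257L
  if (!is.null(.sig_cache)) {
    Ns <- .sig_cache$Ns; n_scan <- length(Ns); sig <- .sig_cache$sig
  } else {
    Ns <- seq(0, pM, length.out = n_scan)
    sig <- if (rate$family == "step") sigma_of(Ns, rate$threshold)
  }
  gs <- if (rate$family == "step") {
    pM * tailx(sig) - Ns
  } else vapply(Ns, g, numeric(1))
  if (rate$family == "step") {   # lean scalar evaluation for the bisection
    thr <- rate$threshold
    a2 <- 2 * thr$alpha; a1 <- thr$alpha
    Nm <- thr$N_minus; Np <- thr$N_plus; lNm <- log(thr$N_minus)
    s_hi <- grid$s_max
    g <- function(N) {
      x <- if (N <= Nm) a2 else if (N >= Np) a1 else a2 - log(N) + lNm
      if (x > s_hi) x <- s_hi
      k <- floor(x / ds); if (k > n - 1) k <- n - 1
      pM * max(rcum[k + 1L] - (x - k * ds) * v[k + 1L], 0) - N
    }
  }
  sgn <- sign(gs)
  idx <- which(sgn[-n_scan] * sgn[-1] <= 0 & (sgn[-n_scan] != 0 | sgn[-1] != 0))
  roots <- Ns[gs == 0]
  for (i in idx) {                # bisection: G is continuous on the bracket
    lo <- Ns[i]; hi <- Ns[i + 1L]; g_lo <- gs[i]
    if (g_lo == 0) { roots <- c(roots, lo); next }
    while (hi - lo > fp_tol) {
      mid <- (lo + hi) / 2
      g_mid <- g(mid)
      if (g_mid == 0) { lo <- mid; break }
      if (sign(g_mid) == sign(g_lo)) { lo <- mid; g_lo <- g_mid }
      else hi <- mid
    }
    roots <- c(roots, (lo + hi) / 2)
  }
  roots <- sort(unique(round(roots / fp_tol) * fp_tol))
  if (length(roots) == 0) {
    if (all(gs > 0)) return(pM)
    if (all(gs < 0)) return(0)
    stop("solver error: no root of the activity equation in [0, p_max]")
  }
  N <- if (root_rule == "largest") max(roots)
       else roots[which.min(abs(roots - previous_N))]
  min(max(N, 0), pM)
}

#' Advance the density by one time step
#'
#' One step of the conservative operator splitting, in order:
#' activity solve, discharge, transport, redistribution.
#' * activity: `N` from [solve_total_activity()] on the pre-step density;
#' * discharge: each cell loses the fraction `1 - exp(-p(s_i, N) dt)` of
#'   its mass (exact exponential integrator, unconditionally positive);
#' * transport: the retained mass undergoes an exact one-cell right shift
#'   with zero inflow at `s = 0`;
#' * redistribution: the removed mass is routed through the kernel matrix
#'   and deposited after the shift — a neuron discharging during the step
#'   re-enters at its kernel state with age below `dt`, so depositing
#'   post-shift keeps the reset kernel's boundary layer in the first cell
#'   and makes the scheme first-order accurate up to the boundary.
#'
#' The tail is handled by reflection (`tail = "reflect"`: mass shifted past
#' `s_max` stays in the last cell, where it keeps discharging at the full
#' rate), which makes the step exactly conservative; `tail = "outflow"`
#' drops that mass instead and is used by the truncated eigensolver.
#'
#' @param state a `density_state`.
#' @param rate a [firing_rate()].
#' @param kd a [discretize_kernel()] result on the same grid.
#' @param previous_N continuation seed for the activity solve.
#' @param root_rule,fp_tol passed to [solve_total_activity()].
#' @param tail `"reflect"` or `"outflow"`.
#' @param inflow boundary density value fed into cell 1 (0 for the
#'   evolution problem; the eigensolver feeds `epsilon * mass`).
#' @return list with the advanced `state` and the activity `N` used.
#' @export
step_density <- function(state, rate, kd, previous_N = 0,
                         root_rule = "continuation", fp_tol = 1e-12,
                         tail = c("reflect", "outflow"), inflow = 0,
                         .sig_cache = NULL) {
  tail <- match.arg(tail)
  grid <- state$grid
  if (!same_grid(grid, kd$grid)) stop("state and kernel grids differ")
  dt <- grid$dt
  N <- solve_total_activity(state, rate, previous_N, root_rule, fp_tol,
                            .sig_cache = .sig_cache)
  p <- firing_rate_eval(rate, grid$centers, N)
  keep <- state$values * exp(-p * dt)
  loss <- state$values - keep
  n <- grid$n_cells
  shifted <- c(inflow, keep[-n])
  if (tail == "reflect") shifted[n] <- shifted[n] + keep[n]
  new_v <- shifted + as.numeric(kd$matrix %*% loss)
  list(state = density_state(new_v, grid, state$time + dt), N = N)
}

#' Run the simulator over a time horizon
#'
#' Iterates [step_density()] for `ceiling(T / dt)` steps.  The activity is
#' seeded at `t = 0` by solving the implicit equation with
#' `previous_N = 0`, then carried forward by continuation.  Runs are
#' deterministic and bit-reproducible.
#'
#' @param initial a `density_state` from [initial_data()].
#' @param rate a [firing_rate()].
#' @param kern a [fragmentation_kernel()] or a prebuilt
#'   [discretize_kernel()] result.
#' @param T_end time horizon (> 0, or 0 for the initial record only).
#' @param snapshot_times times at which to store density snapshots
#'   (rounded to the step grid).
#' @param root_rule,fp_tol passed to [solve_total_activity()].
#' @return object of class `trajectory` with fields `times`, `N`
#'   (activity per time), `snapshot_times`, `snapshots` (list of value
#'   vectors), `final_state`, `grid`, `mass_drift`.
#' @export
run_simulation <- function(initial, rate, kern, T_end,
                           snapshot_times = NULL,
                           root_rule = "continuation", fp_tol = 1e-12) {
  stopifnot(inherits(initial, "density_state"), T_end >= 0)
  grid <- initial$grid
  kd <- if (inherits(kern, "kernel_disc")) kern
        else discretize_kernel(kern, grid)
  dt <- grid$dt
  n_steps <- ceiling(round(T_end / dt, 9))
  sig_cache <- if (rate$family == "step" && rate$n_dependent) {
    Ns <- seq(0, rate$p_max, length.out = 2049L)
    list(Ns = Ns, sig = sigma_of(Ns, rate$threshold))
  }
  N0 <- solve_total_activity(initial, rate, 0, root_rule, fp_tol)
  times <- (0:n_steps) * dt
  Nv <- numeric(n_steps + 1L); Nv[1L] <- N0
  snap_idx <- integer(0)
  if (!is.null(snapshot_times))
    snap_idx <- unique(pmin(pmax(round(snapshot_times / dt), 0L), n_steps))
  snaps <- vector("list", length(snap_idx))
  names(snaps) <- format(snap_idx * dt)
  mass0 <- state_mass(initial)
  st <- initial
  if (0L %in% snap_idx) snaps[[match(0L, snap_idx)]] <- st$values
  N_prev <- N0
  if (n_steps > 0) for (k in seq_len(n_steps)) {
    res <- tryCatch(
      step_density(st, rate, kd, N_prev, root_rule, fp_tol,
                   .sig_cache = sig_cache),
      error = function(e)
        stop(sprintf("step failed at t = %.6g: %s", st$time, conditionMessage(e))))
    st <- res$state
    N_prev <- res$N
    Nv[k] <- res$N    # activity solved on the density at t_{k-1}
    if (k %in% snap_idx) snaps[[match(k, snap_idx)]] <- st$values
  }
  if (n_steps > 0)
    Nv[n_steps + 1L] <- solve_total_activity(st, rate, N_prev,
                                             root_rule, fp_tol)
  structure(
    list(times = times, N = Nv,
         snapshot_times = snap_idx * dt, snapshots = snaps,
         final_state = st, grid = grid,
         mass_drift = state_mass(st) - mass0),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> t in [0, %g], dt = %g, %d snapshots, mass drift = %.3g\n",
    max(x$times), x$grid$dt, length(x$snapshots), x$mass_drift))
  cat(sprintf("  N(t): last = %.6g, late range = [%.6g, %.6g]\n",
              x$N[length(x$N)],
              min(utils::tail(x$N, ceiling(length(x$N) / 2))),
              max(utils::tail(x$N, ceiling(length(x$N) / 2)))))
  invisible(x)
}

#' Plot the activity trace of a trajectory
#'
#' Draws `N(t)` with horizontal reference lines at the threshold bounds
#' `N_minus`, `N_plus` when the rate uses a threshold rule.
#'
#' @param x a `trajectory`.
#' @param rate optional [firing_rate()] supplying the reference lines.
#' @param ... passed to [graphics::plot()].
#' @export
plot.trajectory <- function(x, rate = NULL, ...) {
  graphics::plot(x$times, x$N, type = "l", xlab = "t", ylab = "N(t)", ...)
  if (!is.null(rate) && !rate$constant_sigma) {
    graphics::abline(h = c(rate$threshold$N_minus, rate$threshold$N_plus),
                     lty = 2, col = "grey40")
  }
  invisible(x)
}
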