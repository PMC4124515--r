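#' Truncated linear stationary eigenproblem
#'
#' Solves the discrete analogue of the truncated eigenproblem for the
#' stationary density: find `(A, lambda)` with
#' `A' + (p + lambda) A = int K(s, u) p(u) A(u) du` on `[0, R]`,
#' boundary feedback `A(0) = epsilon * int A`, positivity, and unit mass.
#' The positive discrete operator (discharge, redistribution, transport
#' with outflow at `R` and boundary inflow `epsilon * mass`) is iterated
#' with normalization each sweep — a power iteration whose fixed point is
#' the principal eigenpair.  The eigenvalue is read off from the boundary
#' identity `lambda = epsilon - A(R)` and must satisfy the a priori
#' bracket `epsilon - 2/R <= lambda <= epsilon`.
#'
#' @param p_fun frozen rate: a vectorized function of `s` (see
#'   [freeze_rate()]).
#' @param kd a [discretize_kernel()] result; its grid supplies `R = s_max`
#'   and the cell count.
#' @param epsilon boundary regularization (> 0).
#' @param init optional starting profile (cell values), e.g. a previous
#'   solution for warm starts.
#' @param tol convergence tolerance on successive eigenvalue estimates and
#'   on the profile residual.
#' @param max_sweeps iteration cap.
#' @return object of class `stationary_result` with fields `A_values`,
#'   `lambda`, `epsilon`, `R`, `residual`, `grid`, `bounds_ok`, `sweeps`,
#'   and `A_star = NA` (filled by [nonlinear_fixed_point()]).
#' @export
linear_stationary <- function(p_fun, kd, epsilon, init = NULL,
                              tol = 1e-10, max_sweeps = NULL) {
  stopifnot(inherits(kd, "kernel_disc"), epsilon > 0)
  grid <- kd$grid
  n <- grid$n_cells; ds <- grid$ds; dt <- grid$dt
  R <- grid$s_max
  p <- p_fun(grid$centers)
  if (any(p < 0)) stop("rate must be nonnegative")
  if (p[n] <= 0)
    stop("rate must be positive near the truncation boundary (p >= p* > 0 beyond s*)")
  if (is.null(max_sweeps)) max_sweeps <- max(20000L, 60L * n)
  decay <- exp(-p * dt)
  M <- kd$matrix
  v <- init %||% { w <- exp(-grid$centers); w / (ds * sum(w)) }
  lam_prev <- Inf
  lam <- NA_real_
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    keep <- v * decay
    arr <- as.numeric(M %*% (v - keep))
    new_v <- c(epsilon, keep[-n]) + arr   # outflow keep[n]; mass in is 1
    lam <- epsilon - keep[n]              # boundary identity at unit mass
    mass <- ds * sum(new_v)
    new_v <- new_v / mass
    resid <- max(abs(new_v - v)) / dt
    if (abs(lam - lam_prev) < tol && resid < max(tol, 1e-9)) {
      v <- new_v; converged <- TRUE; break
    }
    lam_prev <- lam
    v <- new_v
  }
  if (!converged)
    stop(sprintf("eigeniteration did not converge in %d sweeps (resid %.3g)",
                 max_sweeps, resid))
  bounds_ok <- (lam <= epsilon + 1e-12) && (lam >= epsilon - 2 / R - 1e-12)
  structure(
    list(A_values = v, lambda = lam, epsilon = epsilon, R = R,
         A_R = epsilon - lam, A_star = NA_real_, residual = resid,
         grid = grid, bounds_ok = bounds_ok, sweeps = sweep),
    class = "stationary_result")
}

#' @export
print.stationary_result <- function(x, ...) {
  cat(sprintf(
    "<stationary_result> lambda = %.6g (eps = %g, R = %g), mass = %.10g\n",
    x$lambda, x$epsilon, x$R, x$grid$ds * sum(x$A_values)))
  if (!is.na(x$A_star)) cat(sprintf("  A* = %.8g\n", x$A_star))
  cat(sprintf("  residual = %.3g, eigenvalue bracket %s\n", x$residual,
              if (x$bounds_ok) "holds" else "VIOLATED"))
  invisible(x)
}

#' Stationary density profile by boundary-regularization limit
#'
#' Runs [linear_stationary()] along a decreasing sequence of boundary
#' regularizations `epsilon` (default `1e-2, 1e-4, 1e-6`) at fixed
#' truncation `R`, warm-starting each solve from the previous profile,
#' and returns the last solve together with the sup-norm difference of
#' the final two profiles as a convergence indicator.
#'
#' @param p_fun frozen rate, a vectorized function of `s`.
#' @param kern a [fragmentation_kernel()] or prebuilt kernel
#'   discretization.
#' @param grid a [sim_grid()] (ignored if `kern` is already discretized).
#' @param eps_seq decreasing boundary regularizations.
#' @param ... passed to [linear_stationary()].
#' @return a `stationary_result` with an extra field `eps_diff`.
#' @export
stationary_profile <- function(p_fun, kern, grid = NULL,
                               eps_seq = c(1e-2, 1e-4, 1e-6), ...) {
  kd <- if (inherits(kern, "kernel_disc")) kern
        else discretize_kernel(kern, grid)
  res <- NULL
  prev_A <- NULL
  diff_prev <- Inf
  for (eps in eps_seq) {
    res <- linear_stationary(p_fun, kd, eps, init = prev_A, ...)
    if (!is.null(prev_A)) {
      d <- max(abs(res$A_values - prev_A))
      if (d > diff_prev)
        warning("profile differences not decreasing along the epsilon sequence")
      diff_prev <- d
    }
    prev_A <- res$A_values
  }
  res$eps_diff <- if (is.finite(diff_prev)) diff_prev else NA_real_
  res
}

#' Nonlinear stationary state (A, A*)
#'
#' The stationary activity solves the scalar fixed point
#' `N = F(N) := int p(s, N) Abar(s, N) ds`, where `Abar(., N)` is the
#' stationary profile with the rate frozen at `N`.  Because `F(0) > 0`
#' and `F <= p_max`, `G(N) = F(N) - N` changes sign on `[0, p_max]`;
#' all sign changes on a coarse scan are recorded and the first bracket
#' is refined by bisection (robust to the kinks of the step rate).
#'
#' @param rate a [firing_rate()].
#' @param kern a [fragmentation_kernel()].
#' @param grid a [sim_grid()]; its `s_max` is the truncation `R`.
#' @param tol tolerance on `|F(A*) - A*|`.
#' @param eps_seq boundary regularizations for each profile solve.
#' @param n_scan coarse scan points on `[0, p_max]`.
#' @return a `stationary_result` with `A_star` set, plus fields
#'   `F_residual` and `brackets` (all sign-change intervals found).
#' @export
nonlinear_fixed_point <- function(rate, kern, grid, tol = 1e-8,
                                  eps_seq = c(1e-2, 1e-4, 1e-6),
                                  n_scan = 17L) {
  stopifnot(inherits(rate, "firing_rate"))
  kd <- if (inherits(kern, "kernel_disc")) kern
        else discretize_kernel(kern, grid)
  pM <- rate$p_max
  warm <- NULL
  profile_at <- function(N) {
    res <- stationary_profile(freeze_rate(rate, N), kd, eps_seq = eps_seq)
    warm <<- res$A_values
    res
  }
  F_of <- function(N) {
    res <- profile_at(N)
    kd$grid$ds * sum(firing_rate_eval(rate, kd$grid$centers, N) * res$A_values)
  }

  if (!rate$n_dependent) {
    res <- profile_at(0)
    res$A_star <- kd$grid$ds *
      sum(firing_rate_eval(rate, kd$grid$centers, 0) * res$A_values)
    res$F_residual <- 0
    res$brackets <- list()
    return(res)
  }

  Ns <- seq(0, pM, length.out = n_scan)
  Gs <- vapply(Ns, function(N) F_of(N) - N, numeric(1))
  idx <- which(sign(Gs[-n_scan]) * sign(Gs[-1]) <= 0 &
               (Gs[-n_scan] != 0 | Gs[-1] != 0))
  if (length(idx) == 0)
    stop("bracketing error: G(N) = F(N) - N has no sign change on [0, p_max]")
  brackets <- lapply(idx, function(i) c(Ns[i], Ns[i + 1L]))
  lo <- brackets[[1L]][1L]; hi <- brackets[[1L]][2L]
  g_lo <- Gs[idx[1L]]
  for (it in seq_len(60L)) {
    mid <- (lo + hi) / 2
    g_mid <- F_of(mid) - mid
    if (abs(g_mid) < tol || (hi - lo) / 2 < tol / 4) break
    if (sign(g_mid) == sign(g_lo)) { lo <- mid; g_lo <- g_mid }
    else hi <- mid
  }
  A_star <- mid
  res <- profile_at(A_star)
  res$A_star <- A_star
  res$F_residual <- abs(g_mid)
  res$brackets <- brackets
  res
}
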