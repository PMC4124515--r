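#' Smallness quantity B* of the decay machinery
#'
#' With the rate frozen at the stationary activity `A*` (so
#' `p*(s) = p(s, A*)`, `sigma* = sigma(A*)`) this computes
#' \deqn{B^* = e^{\int_0^{\sigma^*} p^*}\Big[\sigma^* \int_0^{\sigma^*}
#'   |p^{*\prime}| \,ds + \theta \int_0^{\sigma^*} p^* \,ds\Big].}
#' `B* < 1` is the key certificate that the dual-weight construction (and
#' hence exponential relaxation to the stationary state) goes through.
#' For the step family the total variation of `p*` on `[0, sigma*]` is the
#' single jump `p_max` and the rate integral vanishes, giving
#' `B* = sigma* * p_max` in closed form; the regularized family is handled
#' by trapezoidal quadrature with the analytic ramp derivative.
#'
#' @param rate a [firing_rate()].
#' @param kern a [fragmentation_kernel()].
#' @param A_star nonnegative stationary activity at which to freeze.
#' @return the value of `B*` (nonnegative scalar).
#' @export
compute_B_star <- function(rate, kern, A_star) {
  stopifnot(inherits(rate, "firing_rate"), A_star >= 0)
  sg <- sigma_of(A_star, rate$threshold)
  th <- kernel_theta_value(kern)
  if (sg == 0) return(0)
  pM <- rate$p_max
  if (rate$family == "step") {
    # p* = 0 on [0, sigma*); total variation on the closed interval = p_max
    return(sg * pM)
  }
  # piecewise-linear ramp: closed-form integrals on [0, sigma*]
  dl <- rate$smoothing
  int_p <- if (dl <= sg) pM * dl / 2 else pM * sg * (2 * dl - sg) / (2 * dl)
  int_dp <- pM * min(sg, dl) / dl
  exp(int_p) * (sg * int_dp + th * int_p)
}

#' Check the model's structural and smallness assumptions
#'
#' Produces a report (never an error) on the admissibility conditions that
#' underpin the exponential-decay theory: the certificate `B* < 1` together
#' with its companion kernel inequality, the exponential-moment condition
#' requiring some `mu > 0` with
#' `sup_{u <= sigma*} p(u) [ int K(s,u) e^{mu(u-s)} ds - 1 ] < mu`,
#' the kernel contraction bound `theta < 1`, and (for point-map kernels
#' with a differentiable rate) the direct decay rate
#' `nu = inf_u [ p(u) (1 - psi'(u)) - |p'(u)| (u - psi(u)) ]`.
#'
#' @param rate a [firing_rate()].
#' @param kern a [fragmentation_kernel()].
#' @param A_star activity level at which to freeze the coefficients.
#' @param u_max upper end of the scan grids.
#' @return object of class `condition_report` with fields `B_star`,
#'   `condition_15_holds`, `mu_star`, `condition_16_holds`,
#'   `theta_estimate`, `nu_B1`, `eta`, `notes`.
#' @export
check_assumptions <- function(rate, kern, A_star = 0, u_max = NULL) {
  stopifnot(inherits(rate, "firing_rate"), inherits(kern, "frag_kernel"))
  sg <- sigma_of(A_star, rate$threshold)
  if (is.null(u_max)) u_max <- max(2 * sg, 4, 10 / rate$p_max)
  notes <- character(0)

  th <- kernel_theta_value(kern, u_max = u_max)
  B_star <- compute_B_star(rate, kern, A_star)

  # companion inequality of the B* certificate (sufficient direct form)
  companion <- if (B_star < 1) {
    int_p <- if (rate$family == "step") 0 else {
      s <- seq(0, sg, length.out = 2001L)
      sum((firing_rate_eval(rate, s, A_star)[-1] +
           firing_rate_eval(rate, s, A_star)[-2001L]) / 2) * sg / 2000
    }
    th * exp(int_p) / (1 - B_star) < rate$p_max
  } else FALSE
  condition_15 <- (B_star < 1) && companion

  # exponential-moment condition: scan mu over a logarithmic grid
  mu_grid <- exp(seq(log(1e-4), log(10), length.out = 200L))
  u <- seq(0, sg, length.out = 201L)
  pu <- firing_rate_eval(rate, u, A_star)
  mu_star <- NA_real_
  for (mu in mu_grid) {
    emom <- kernel_exp_moment(kern, u, mu)
    if (max(pu * (emom - 1)) < mu) { mu_star <- mu; break }
  }
  condition_16 <- is.finite(mu_star)

  nu_B1 <- NA_real_
  if (kern$family == "point_map" && rate_is_differentiable(rate)) {
    nu_B1 <- prop_b1_scan(rate, kern, A_star, u_max)
  } else if (kern$family == "point_map") {
    notes <- c(notes, "nu_B1 not reported: step rate is not differentiable")
  }

  if (rate$family == "step" && rate$n_dependent)
    notes <- c(notes,
      "step rate with activity-dependent threshold: |dp/dN| is a singular measure, outside the smallness hypotheses")

  structure(
    list(B_star = B_star, condition_15_holds = condition_15,
         mu_star = mu_star, condition_16_holds = condition_16,
         theta_estimate = th, nu_B1 = nu_B1, eta = rate$eta,
         sigma_star = sg, notes = notes),
    class = "condition_report")
}

# int_0^u K(s, u) e^{mu (u - s)} ds for each u (vectorized over u)
kernel_exp_moment <- function(kern, u, mu) {
  if (kern$family == "point_map") {
    exp(mu * (u - pmin(kern$psi(u), u)))
  } else {
    vapply(u, function(uu) {
      if (uu == 0) return(1)
      m <- 256L
      x <- seq(0, uu, length.out = m + 1L)
      kx <- kern$density(x, uu)
      w <- (kx[-1] + kx[-(m + 1L)]) / 2 * diff(x)
      tot <- sum(w)
      if (tot <= 0) return(1)
      xm <- (x[-1] + x[-(m + 1L)]) / 2
      sum(w * exp(mu * (uu - xm))) / tot
    }, numeric(1))
  }
}

# inf over a grid of p(u) psibar'(u) - |p'(u)| psibar(u), psibar(u) = u - psi(u)
prop_b1_scan <- function(rate, kern, A_star, u_max, n_grid = 2000L) {
  u <- seq(0, u_max, length.out = n_grid + 1L)
  pu <- firing_rate_eval(rate, u, A_star)
  dpu <- rate_abs_derivative(rate, u, A_star, width = u_max / n_grid)
  psibar <- u - pmin(kern$psi(u), u)
  psibar_p <- 1 - psi_prime_of(kern, u)
  min(pu * psibar_p - dpu * psibar)
}

# rates for which |dp/ds| is a function (not a singular measure)
rate_is_differentiable <- function(rate) {
  rate$family != "step" || (rate$constant_sigma && rate$threshold == 0)
}

#' @export
print.condition_report <- function(x, ...) {
  cat("<condition_report>\n")
  cat(sprintf("  B*              : %.6g  (certificate %s)\n", x$B_star,
              if (x$condition_15_holds) "holds" else "FAILS"))
  cat(sprintf("  exp-moment mu*  : %s  (condition %s)\n",
              if (is.finite(x$mu_star)) format(x$mu_star, digits = 4) else "none",
              if (x$condition_16_holds) "holds" else "FAILS"))
  cat(sprintf("  theta estimate  : %.6g\n", x$theta_estimate))
  if (is.finite(x$nu_B1))
    cat(sprintf("  direct rate nu  : %.6g\n", x$nu_B1))
  cat(sprintf("  eta (|dp/dN|)   : %g\n", x$eta))
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}
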