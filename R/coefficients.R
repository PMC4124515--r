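#' Threshold bounds of the activity-dependent refractory period
#'
#' For a threshold scale `alpha > 0` the two activity levels delimiting the
#' sloped branch of the refractory threshold are
#' `N_minus = 1 / (2 e^alpha - 1)` and `N_plus = e^alpha / (2 e^alpha - 1)`,
#' and they always satisfy `0 < N_minus < N_plus < 1`.
#'
#' @param alpha positive threshold scale.
#' @return named numeric vector `c(N_minus, N_plus)`.
#' @export
n_plus_minus <- function(alpha) {
  if (!is.numeric(alpha) || any(alpha <= 0))
    stop("alpha must be positive")
  d <- 2 * exp(alpha) - 1
  c(N_minus = 1 / d, N_plus = exp(alpha) / d)
}

#' Piecewise refractory threshold rule
#'
#' The refractory period sigma(N) is non-increasing in the network activity
#' N: it equals `2*alpha` for `N <= N_minus`, decreases logarithmically on
#' `[N_minus, N_plus]`, and equals `alpha` for `N >= N_plus`.  Its range is
#' therefore `[alpha, 2*alpha]`.
#'
#' @param alpha positive threshold scale.
#' @return object of class `threshold_rule`.
#' @seealso [sigma_of()]
#' @export
threshold_rule <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("alpha must be a positive scalar")
  np <- n_plus_minus(alpha)
  structure(
    list(alpha = alpha,
         N_minus = unname(np[1]), N_plus = unname(np[2]),
         sigma_minus = alpha, sigma_plus = 2 * alpha),
    class = "threshold_rule")
}

#' @export
print.threshold_rule <- function(x, ...) {
  cat(sprintf(
    "<threshold_rule> alpha = %g, N- = %.6g, N+ = %.6g, sigma in [%g, %g]\n",
    x$alpha, x$N_minus, x$N_plus, x$sigma_minus, x$sigma_plus))
  invisible(x)
}

#' Evaluate the refractory threshold sigma(N)
#'
#' @param x nonnegative activity value(s).
#' @param rule a [threshold_rule()], or a single nonnegative number for a
#'   constant (activity-independent) threshold.
#' @return threshold value(s), same length as `x`.
#' @export
sigma_of <- function(x, rule) {
  if (any(x < 0)) stop("activity x must be nonnegative")
  if (is.numeric(rule)) {
    if (length(rule) != 1L || rule < 0)
      stop("a constant threshold must be a single nonnegative number")
    return(rep(rule, length(x)))
  }
  stopifnot(inherits(rule, "threshold_rule"))
  a <- rule$alpha
  out <- rep(2 * a, length(x))
  mid <- x > rule$N_minus & x < rule$N_plus
  out[mid] <- 2 * a - log(x[mid]) + log(rule$N_minus)
  out[x >= rule$N_plus] <- a
  out
}

#' Firing (discharge) rate family
#'
#' The discharge hazard `p(s, N)` vanishes during the refractory period
#' (`s` well below `sigma(N)`) and equals the ceiling `p_max` for
#' `s >= sigma(N)`.  Two families are provided:
#' * `"step"`: the indicator `p_max * 1\{s >= sigma(N)\}` (closed at the
#'   threshold, so `p(sigma(N), N) = p_max`);
#' * `"regularized"`: a piecewise-linear ramp of width `smoothing` rising
#'   from 0 at `sigma(N) - smoothing` to `p_max` at `sigma(N)`.
#'
#' @param family `"step"` or `"regularized"`.
#' @param threshold a [threshold_rule()] or a single nonnegative number
#'   (constant threshold; 0 gives the constant rate `p = p_max`).
#' @param p_max positive rate ceiling.
#' @param smoothing ramp width of the regularized family (ignored and
#'   forced to 0 for the step family).
#' @param eta declared bound on the activity sensitivity `|dp/dN|`;
#'   computed automatically for the regularized family with a
#'   threshold rule, `0` for constant thresholds, `Inf` for the step
#'   family with a threshold rule (the sensitivity is a singular measure).
#' @return object of class `firing_rate`.
#' @export
firing_rate <- function(family = c("step", "regularized"), threshold,
                        p_max = 1, smoothing = 0, eta = NULL) {
  family <- match.arg(family)
  if (!is.numeric(p_max) || p_max <= 0) stop("p_max must be positive")
  if (family == "step") smoothing <- 0
  if (family == "regularized" && smoothing <= 0)
    stop("the regularized family requires smoothing > 0")
  constant_sigma <- is.numeric(threshold)
  if (!constant_sigma && !inherits(threshold, "threshold_rule"))
    stop("threshold must be a threshold_rule or a nonnegative number")
  if (is.null(eta)) {
    eta <- if (constant_sigma) 0
           else if (family == "step") Inf
           else (p_max / smoothing) / threshold$N_minus  # |sigma'| <= 1/N-
  }
  structure(
    list(family = family, threshold = threshold, p_max = p_max,
         smoothing = smoothing, eta = eta,
         constant_sigma = constant_sigma,
         n_dependent = !constant_sigma),
    class = "firing_rate")
}

#' @export
print.firing_rate <- function(x, ...) {
  thr <- if (x$constant_sigma) sprintf("sigma = %g (constant)", x$threshold)
         else sprintf("sigma(N), alpha = %g", x$threshold$alpha)
  cat(sprintf("<firing_rate> %s, %s, p_max = %g, smoothing = %g\n",
              x$family, thr, x$p_max, x$smoothing))
  invisible(x)
}

#' Evaluate the firing rate p(s, N)
#'
#' @param rate a [firing_rate()].
#' @param s elapsed time(s) since last discharge (vectorized).
#' @param N total network activity (scalar).
#' @return rate values in `[0, p_max]`, same length as `s`.
#' @export
firing_rate_eval <- function(rate, s, N) {
  stopifnot(inherits(rate, "firing_rate"))
  if (any(s < 0)) stop("elapsed time s must be nonnegative")
  sg <- sigma_of(N, rate$threshold)
  if (rate$family == "step") {
    rate$p_max * as.numeric(s >= sg)
  } else {
    rate$p_max * pmin(1, pmax(0, (s - (sg - rate$smoothing)) / rate$smoothing))
  }
}

#' Elapsed-time derivative |dp/ds| of a frozen rate
#'
#' For the regularized family this is `p_max / smoothing` on the ramp and 0
#' elsewhere.  The step family has a unit jump at the threshold; on a grid
#' it is represented by a single spike of height `p_max / width` over the
#' interval containing the threshold, so that its integral is `p_max`.
#'
#' @keywords internal
rate_abs_derivative <- function(rate, s, N, width = NULL) {
  sg <- sigma_of(N, rate$threshold)
  if (rate$family == "regularized") {
    slope <- rate$p_max / rate$smoothing
    slope * as.numeric(s > sg - rate$smoothing & s < sg)
  } else {
    if (is.null(width)) stop("step rate derivative needs a grid width")
    # spike over the cell containing sigma (half-open to avoid double ties)
    (rate$p_max / width) * as.numeric(s - sg > -width / 2 & s - sg <= width / 2)
  }
}

#' Freeze a rate at a fixed activity level
#'
#' Returns `p*(s) = p(s, N)` as a plain vectorized function of `s`, used by
#' the stationary and spectral solvers where the activity is held fixed.
#'
#' @param rate a [firing_rate()].
#' @param N activity level at which to freeze.
#' @return function of `s`.
#' @export
freeze_rate <- function(rate, N) {
  force(rate); force(N)
  function(s) firing_rate_eval(rate, s, N)
}
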