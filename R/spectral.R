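#' Dual weight P of the decay certificate
#'
#' Constructs the weight `P` solving the adjoint-type Volterra
#' integro-differential equation
#' \deqn{-P'(s) + (\lambda + p^*(s)) P(s) = \int_0^s [\,|p^{*\prime}(s)|
#'   f(u, s) + p^*(s) \Phi(u, s)\,] P(u)\, du, \qquad P(0) = 1,}
#' with the coefficients frozen at the stationary activity `A*`.  Because
#' the right-hand side only involves `P` on `[0, s]`, the equation is
#' marched forward in `s` on the node grid `s_j = j ds` with an
#' exponential trapezoidal predictor-corrector (exact when the memory term
#' vanishes, second order otherwise).  For point-map kernels the memory
#' term is evaluated exactly against the Dirac measure:
#' `int f P du = int_{psi(s)}^{s} P` and `int Phi P du = psi'(s) P(psi(s))`
#' with linear interpolation of `P`.  For density kernels a tabulated
#' cumulative kernel is differenced in the discharge argument.
#'
#' No admissibility judgment is made here; see [find_lambda()].
#'
#' @param lambda nonpositive spectral shift.
#' @param rate a [firing_rate()].
#' @param kern a [fragmentation_kernel()].
#' @param grid a [sim_grid()]; `P` is returned on its `n_cells + 1` nodes.
#' @param A_star activity at which the coefficients are frozen.
#' @return list with `s` (nodes), `P` (values, `P[1] = 1`), `overflow`
#'   flag (`P` truncated after exceeding 1e12).
#' @export
dual_P <- function(lambda, rate, kern, grid, A_star = 0) {
  stopifnot(lambda <= 0, inherits(rate, "firing_rate"),
            inherits(kern, "frag_kernel"), inherits(grid, "sim_grid"))
  h <- grid$ds
  n <- grid$n_cells
  s <- grid$edges                       # n + 1 nodes
  p_nodes <- firing_rate_eval(rate, s, A_star)
  dp_nodes <- rate_abs_derivative(rate, s, A_star, width = h)
  p_mid <- firing_rate_eval(rate, (s[-1] + s[-(n + 1L)]) / 2, A_star)

  point <- kern$family == "point_map"
  if (point) {
    x <- pmin(kern$psi(s), s)
    psip <- psi_prime_of(kern, s)
    m_idx <- pmin(pmax(findInterval(x, s), 1L), n)   # node index below x
  } else {
    # f(u_i, s_j) tabulated once; Phi by central differencing in s_j
    fmat <- vapply(seq_len(n + 1L),
                   function(j) kernel_cdf(kern, s, s[j]), numeric(n + 1L))
    Phimat <- matrix(0, n + 1L, n + 1L)
    Phimat[, 2:n] <- -(fmat[, 3:(n + 1L)] - fmat[, 1:(n - 1L)]) / (2 * h)
    Phimat[Phimat < 0] <- 0
  }

  P <- numeric(n + 1L); P[1L] <- 1
  C <- numeric(n + 1L)                  # cumulative integral of P
  overflow <- FALSE

  interp_P <- function(xq, j_max) {
    m <- pmin(pmax(findInterval(xq, s), 1L), j_max - 1L)
    w <- (xq - s[m]) / h
    P[m] * (1 - w) + P[m + 1L] * w
  }
  memory_Q <- function(j) {             # j = node index (1-based)
    if (point) {
      Px <- interp_P(x[j], j)
      m <- m_idx[j]
      Cx <- C[m] + (x[j] - s[m]) * (P[m] + Px) / 2
      I1 <- max(C[j] - Cx, 0)
      dp_nodes[j] * I1 + p_nodes[j] * psip[j] * Px
    } else {
      idx <- seq_len(j)
      w <- rep(h, j); w[1L] <- h / 2; w[j] <- h / 2
      if (j == 1L) w <- 0
      dp_nodes[j] * sum(w * fmat[idx, j] * P[idx]) +
        p_nodes[j] * sum(w * Phimat[idx, j] * P[idx])
    }
  }

  Q_j <- 0                              # memory term vanishes at s = 0
  for (j in seq_len(n)) {
    a <- lambda + p_mid[j]
    E <- exp(a * h)
    P_pred <- E * P[j] - h * exp(a * h / 2) * Q_j
    P[j + 1L] <- P_pred
    C[j + 1L] <- C[j] + h * (P[j] + P[j + 1L]) / 2
    Q_next <- memory_Q(j + 1L)
    P[j + 1L] <- E * P[j] - (h / 2) * (E * Q_j + Q_next)
    C[j + 1L] <- C[j] + h * (P[j] + P[j + 1L]) / 2
    Q_j <- memory_Q(j + 1L)
    if (!is.finite(P[j + 1L]) || abs(P[j + 1L]) > 1e12) {
      overflow <- TRUE
      if (j < n) P[(j + 2L):(n + 1L)] <- P[j + 1L]
      break
    }
  }
  list(s = s, P = P, overflow = overflow)
}

#' Locate an admissible negative eigenvalue for the dual weight
#'
#' The decay theory guarantees that for `lambda < 0` close enough to 0 the
#' dual weight stays positive and is nondecreasing beyond the frozen
#' threshold `sigma*`, provided the certificate `B* < 1` holds.  This scans
#' `lambda_k = -(p_max / 4) 2^{-k}`, `k = 20, ..., 0` (downward from 0) and
#' returns the most negative `lambda` whose weight is positive everywhere
#' and nondecreasing beyond `sigma*` (per-cell tolerance `1e-10` absorbs
#' roundoff).  The ratio constant `B` of the two-sided weight bounds
#' `1/B <= P(x)`, `P(x) <= B P(y)` for `x <= y` is recorded.
#'
#' @param rate a [firing_rate()].
#' @param kern a [fragmentation_kernel()].
#' @param grid a [sim_grid()].
#' @param A_star activity at which the coefficients are frozen.
#' @return object of class `dual_eigenresult` with fields `P_values`, `s`,
#'   `lambda`, `B_star`, `B_ratio`, `admissible`, `status`.
#' @export
find_lambda <- function(rate, kern, grid, A_star = 0) {
  B_star <- compute_B_star(rate, kern, A_star)
  sg <- sigma_of(A_star, rate$threshold)
  empty <- function(status) structure(
    list(P_values = NULL, s = grid$edges, lambda = NA_real_,
         B_star = B_star, B_ratio = NA_real_, admissible = FALSE,
         status = status),
    class = "dual_eigenresult")
  if (B_star >= 1) return(empty("B_star >= 1"))

  admissible_P <- function(res) {
    if (res$overflow) return(FALSE)
    if (any(res$P <= 0)) return(FALSE)
    beyond <- res$s >= sg - 1e-12
    all(diff(res$P[beyond]) >= -1e-10)
  }
  best <- NULL; best_lambda <- NA_real_
  for (k in 20:0) {
    lam <- -(rate$p_max / 4) * 2^(-k)
    res <- dual_P(lam, rate, kern, grid, A_star)
    if (admissible_P(res)) { best <- res; best_lambda <- lam }
    else break
  }
  if (is.null(best)) return(empty("scan exhausted: no admissible lambda < 0"))
  P <- best$P
  B_ratio <- max(1 / min(P), max(cummax(P) / P), 1)
  structure(
    list(P_values = P, s = best$s, lambda = best_lambda, B_star = B_star,
         B_ratio = B_ratio, admissible = TRUE, status = "ok"),
    class = "dual_eigenresult")
}

#' @export
print.dual_eigenresult <- function(x, ...) {
  cat(sprintf("<dual_eigenresult> admissible = %s, lambda = %s\n",
              x$admissible,
              if (is.finite(x$lambda)) format(x$lambda, digits = 6) else "none"))
  cat(sprintf("  B* = %.6g, B ratio = %s, status: %s\n", x$B_star,
              if (is.finite(x$B_ratio)) format(x$B_ratio, digits = 6) else "NA",
              x$status))
  invisible(x)
}

#' Direct decay rate of the unweighted L1 certificate
#'
#' For a point-map kernel and a differentiable (regularized or constant)
#' rate, the plain L1 distance of the cumulative difference decays at rate
#' `nu = inf_u [ p(u) psibar'(u) - |p'(u)| psibar(u) ]` with
#' `psibar(u) = u - psi(u)`, whenever `nu > 0`.  A nonpositive return
#' simply means the certificate is not granted.
#'
#' @param rate a [firing_rate()] (not the step family).
#' @param kern a point-map [fragmentation_kernel()].
#' @param grid a [sim_grid()] supplying the scan range.
#' @param A_star activity at which the coefficients are frozen.
#' @return the infimum `nu` over the grid.
#' @export
prop_B1_rate <- function(rate, kern, grid, A_star = 0) {
  if (kern$family != "point_map")
    stop("the direct certificate requires a point-map kernel")
  if (!rate_is_differentiable(rate))
    stop("unsupported rate: the step family is not differentiable")
  prop_b1_scan(rate, kern, A_star, u_max = grid$s_max)
}
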