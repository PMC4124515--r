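#' Fragmentation (redistribution) kernel
#'
#' `K(s, u)` is the distribution of the post-discharge state `s` of a
#' neuron that discharges at elapsed time `u`.  It is supported on
#' `s <= u` (discharge can only rejuvenate) and each column integrates to
#' one, which is what makes the dynamics conservative.  Two families:
#' * `"point_map"`: `K(s, u) = delta(s - psi(u))` with a monotone map
#'   `psi(u) <= u`; `psi = 0` is the full reset (classical age-structured
#'   case), `psi(u) = u/2` halves the elapsed time.
#' * `"density"`: `K(s, u)` given by a nonnegative function of `(s, u)`,
#'   normalized per column at discretization time.
#'
#' @param family `"point_map"` or `"density"`.
#' @param psi for `point_map`: either a single number in `[0, 1)` (the
#'   slope of the linear map `psi(u) = slope * u`) or a nondecreasing
#'   function with `psi(u) <= u`.
#' @param psi_prime optional derivative function of `psi` (numerical
#'   differencing is used when absent).
#' @param density for `density`: a function `K(s, u)`, vectorized in `s`.
#' @param theta optional declared contraction bound in `[0, 1)`; when
#'   absent it is estimated on a grid by [kernel_theta()].
#' @return object of class `frag_kernel`.
#' @export
fragmentation_kernel <- function(family = c("point_map", "density"),
                                 psi = NULL, psi_prime = NULL,
                                 density = NULL, theta = NULL) {
  family <- match.arg(family)
  if (!is.null(theta) && (theta < 0 || theta >= 1))
    stop("declared theta must lie in [0, 1)")
  if (family == "point_map") {
    if (is.null(psi)) stop("point_map kernel requires psi")
    if (is.numeric(psi)) {
      slope <- psi
      if (length(slope) != 1L || slope < 0 || slope >= 1)
        stop("a numeric psi is a slope and must lie in [0, 1)")
      psi <- function(u) slope * u
      psi_prime <- function(u) rep(slope, length(u))
    }
    obj <- list(family = family, psi = psi, psi_prime = psi_prime,
                theta = theta)
  } else {
    if (!is.function(density)) stop("density kernel requires a function K(s, u)")
    obj <- list(family = family, density = density, theta = theta)
  }
  structure(obj, class = "frag_kernel")
}

#' @export
print.frag_kernel <- function(x, ...) {
  cat(sprintf("<frag_kernel> family = %s%s\n", x$family,
              if (!is.null(x$theta)) sprintf(", theta = %g", x$theta) else ""))
  invisible(x)
}

psi_prime_of <- function(kern, u, h = 1e-6) {
  if (!is.null(kern$psi_prime)) kern$psi_prime(u)
  else (kern$psi(u + h) - kern$psi(pmax(u - h, 0))) / (h + pmin(u, h))
}

#' Cumulative kernel f(s, u)
#'
#' `f(s, u)` is the probability that a neuron discharging at elapsed time
#' `u` lands at a state `<= s`.  It is nondecreasing in `s`, lies in
#' `[0, 1]`, and equals 1 for `s >= u`.  For the point-map family it is the
#' indicator `1\{s >= psi(u)\}`.
#'
#' @param kern a [fragmentation_kernel()].
#' @param s arrival state(s) (vectorized).
#' @param u discharge state (scalar).
#' @return values in `[0, 1]`.
#' @export
kernel_cdf <- function(kern, s, u) {
  stopifnot(inherits(kern, "frag_kernel"))
  if (any(s < 0) || u < 0) stop("s and u must be nonnegative")
  if (u == 0) return(rep(1, length(s)))
  if (kern$family == "point_map") {
    pmax(as.numeric(s >= kern$psi(u)), as.numeric(s >= u))
  } else {
    # column-normalized quadrature of the density
    m <- 512L
    x <- seq(0, u, length.out = m + 1L)
    kx <- kern$density(x, u)
    cw <- c(0, cumsum((kx[-1] + kx[-(m + 1L)]) / 2 * diff(x)))
    tot <- cw[m + 1L]
    if (tot <= 0) stop("kernel density integrates to zero on [0, u]")
    f <- stats::approx(x, cw / tot, xout = pmin(s, u), rule = 2)$y
    f[s >= u] <- 1
    pmin(pmax(f, 0), 1)
  }
}

#' Contraction bound estimate theta
#'
#' Estimates `sup_u d/du [ first moment of K(., u) ]`, which for the
#' point-map family is `sup psi'(u)`.  The model requires the value to be
#' `< 1` (a discharge must significantly rejuvenate the state); an
#' estimate `>= 1` is an admissibility error.
#'
#' @param kern a [fragmentation_kernel()].
#' @param u_max upper end of the scan.
#' @param n_grid number of scan points.
#' @return the estimate (a single number `< 1`).
#' @export
kernel_theta <- function(kern, u_max = 20, n_grid = 400L) {
  stopifnot(inherits(kern, "frag_kernel"))
  u <- seq(u_max / n_grid, u_max, length.out = n_grid)
  if (kern$family == "point_map") {
    est <- max(psi_prime_of(kern, u))
  } else {
    # first moment of the normalized column, differenced in u
    m1 <- vapply(u, function(uu) {
      m <- 256L
      x <- seq(0, uu, length.out = m + 1L)
      kx <- kern$density(x, uu)
      w <- (kx[-1] + kx[-(m + 1L)]) / 2 * diff(x)
      tot <- sum(w)
      if (tot <= 0) return(0)
      sum(w * (x[-1] + x[-(m + 1L)]) / 2) / tot
    }, numeric(1))
    est <- max(diff(m1) / diff(u))
  }
  if (est >= 1)
    stop(sprintf("kernel not admissible: estimated theta = %.4g >= 1", est))
  est
}

kernel_theta_value <- function(kern, u_max = 20) {
  kern$theta %||% kernel_theta(kern, u_max = u_max)
}

#' Discretize a kernel into a column-stochastic redistribution matrix
#'
#' Column `j` holds the distribution of arrival cells for mass discharging
#' from cell `j`.  Every column sums to 1 exactly and the matrix is lower
#' triangular in the cell index (arrival state never exceeds the discharge
#' state).  For the point-map family the mass from discharge cell `j` is
#' split between the two cells whose centers bracket `psi(u_j)`, with
#' weights chosen so the discrete first moment of the deposit is exact;
#' this lets the discrete scheme inherit the continuum moment contraction.
#'
#' @param kern a [fragmentation_kernel()].
#' @param grid a [sim_grid()].
#' @return object of class `kernel_disc` with fields `matrix` (sparse
#'   `n x n` column-stochastic), `grid`, `kernel`.
#' @export
discretize_kernel <- function(kern, grid) {
  stopifnot(inherits(kern, "frag_kernel"), inherits(grid, "sim_grid"))
  n <- grid$n_cells
  ctr <- grid$centers
  ds <- grid$ds
  if (kern$family == "point_map") {
    x <- pmin(kern$psi(ctr), ctr)   # psi(u) <= u by assumption
    if (any(x < 0)) stop("psi must be nonnegative")
    k <- findInterval(x, ctr)       # 0..n ; center index at or below x
    j_all <- seq_len(n)
    k1 <- ifelse(k == 0L, 1L, pmin(k, j_all))       # primary deposit cell
    w <- ifelse(k == 0L | k >= j_all, 0,
                (x - ctr[pmax(k, 1L)]) / ds)        # share of the cell above
    w[w < 1e-15] <- 0
    two <- w > 0
    M <- Matrix::sparseMatrix(
      i = c(k1, k1[two] + 1L), j = c(j_all, j_all[two]),
      x = c(1 - w, w[two]), dims = c(n, n))
  } else {
    # cell masses from the cumulative kernel, exactly normalized per column
    M <- matrix(0, n, n)
    for (j in seq_len(n)) {
      f_edges <- kernel_cdf(kern, grid$edges[seq_len(j + 1L)], ctr[j])
      w <- diff(f_edges)
      w[w < 0] <- 0
      tot <- sum(w)
      if (tot <= 0)
        stop(sprintf("kernel column %d has zero mass; cannot normalize", j))
      M[seq_len(j), j] <- w / tot
    }
    M <- methods::as(M, "CsparseMatrix")
  }
  # support check: arrival row never exceeds discharge column
  if (any(Matrix::tril(M, k = -1) != 0))
    stop("construction error: arrival index above discharge index")
  structure(list(matrix = M, grid = grid, kernel = kern),
            class = "kernel_disc")
}

#' @export
print.kernel_disc <- function(x, ...) {
  cat(sprintf("<kernel_disc> %d x %d, family = %s, nnz = %d\n",
              x$grid$n_cells, x$grid$n_cells, x$kernel$family,
              Matrix::nnzero(x$matrix)))
  invisible(x)
}
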