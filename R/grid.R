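#' Uniform discretization grid for the elapsed-time axis
#'
#' Cells are half-open intervals `[i*ds, (i+1)*ds)`, 0-based, with the
#' state stored as cell-average density values.  Time step equals the cell
#' width (`dt = ds`), so unit-speed transport is an exact one-cell shift.
#'
#' @param s_max domain truncation (largest elapsed time represented).
#' @param n_cells number of cells.
#' @return an object of class `sim_grid` with fields `s_max`, `n_cells`,
#'   `ds`, `dt`, `centers` (cell centers) and `edges` (cell edges,
#'   length `n_cells + 1`).
#' @export
sim_grid <- function(s_max, n_cells) {
  if (!is.numeric(s_max) || length(s_max) != 1L || s_max <= 0)
    stop("s_max must be a positive number")
  n_cells <- as.integer(n_cells)
  if (n_cells < 2L) stop("n_cells must be at least 2")
  ds <- s_max / n_cells
  structure(
    list(s_max = s_max, n_cells = n_cells, ds = ds, dt = ds,
         centers = (seq_len(n_cells) - 0.5) * ds,
         edges = (0:n_cells) * ds),
    class = "sim_grid")
}

#' @export
print.sim_grid <- function(x, ...) {
  cat(sprintf("<sim_grid> [0, %g), %d cells, ds = dt = %g\n",
              x$s_max, x$n_cells, x$ds))
  invisible(x)
}

same_grid <- function(a, b) {
  a$n_cells == b$n_cells && isTRUE(all.equal(a$s_max, b$s_max))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
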