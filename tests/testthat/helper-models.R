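# shared model builders for the test suite

p_const <- function(val = 1) function(s) rep(val, length(s))

kern_reset <- function() fragmentation_kernel("point_map", psi = 0)
kern_half <- function() fragmentation_kernel("point_map", psi = 0.5)

# a smooth density kernel supported on s <= u (triangular, peaked at 0)
kern_triangular <- function() {
  fragmentation_kernel("density", density = function(s, u) {
    if (u <= 0) return(rep(0, length(s)))
    pmax(1 - s / u, 0) * 2 / u
  })
}

rate_const <- function(pM = 1) firing_rate("step", 0, p_max = pM)

# independent age-structured renewal scheme: discharge loss re-enters as
# boundary influx n(0, t) = N(t) instead of through a kernel matrix
renewal_reference <- function(values, grid, p_fun, n_steps) {
  v <- values
  n <- grid$n_cells
  p <- p_fun(grid$centers)
  decay <- exp(-p * grid$dt)
  for (k in seq_len(n_steps)) {
    keep <- v * decay
    influx <- ds_flux <- sum(v - keep)      # N * dt / ds with dt = ds
    v <- c(influx, keep[-n])
    v[n] <- v[n] + keep[n]
  }
  v
}

# synthetic trajectory skeleton for diagnostics tests
fake_trajectory <- function(times, N, grid = NULL, snapshot_times = NULL,
                            snapshots = NULL) {
  structure(
    list(times = times, N = N, snapshot_times = snapshot_times,
         snapshots = snapshots, grid = grid, mass_drift = 0),
    class = "trajectory")
}
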