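test_that("initial profiles are nonnegative and carry unit mass exactly", {
  g <- sim_grid(20, 500)
  st <- initial_data("exp_decay", g)
  expect_equal(state_mass(st), 1)
  expect_true(all(st$values >= 0))
  # density e^{-0} = 1 up to discretization at the first cell
  expect_equal(st$values[1], 1, tolerance = 0.05)

  mb <- initial_data("multi_bump", g,
                     params = list(centers = c(1, 3), widths = 0.2))
  expect_equal(state_mass(mb), 1)
  v <- mb$values
  n <- length(v)
  loc_max <- which(v > c(0, v[-n]) & v >= c(v[-1], 0))
  loc_max <- loc_max[v[loc_max] > 0.01 * max(v)]
  expect_length(loc_max, 2L)
  expect_equal(g$centers[loc_max], c(1, 3), tolerance = 0.05)
})

test_that("the activity equation is solved consistently per rate family", {
  g <- sim_grid(20, 2000)
  st <- initial_data("exp_decay", g)
  # p constant in s and N: N = c * mass = c
  expect_equal(solve_total_activity(st, rate_const(0.37)), 0.37,
               tolerance = 1e-12)
  # step rate with constant threshold: N = tail mass beyond sigma
  rc <- firing_rate("step", 2)
  expect_equal(solve_total_activity(st, rc),
               g$ds * sum(st$values[g$centers >= 2]), tolerance = 1e-3)
  # step rate, alpha = 2, n = e^{-s}: the only self-consistent branch is
  # sigma = 2 alpha = 4 (since e^{-4} < N_minus), giving N = e^{-4}
  rate <- firing_rate("step", threshold_rule(2))
  N <- solve_total_activity(st, rate, 0)
  expect_equal(N, exp(-4), tolerance = 1e-4)
  # the returned N is an actual root of the implicit equation
  expect_equal(N, g$ds * sum(firing_rate_eval(rate, g$centers, N) * st$values),
               tolerance = 1e-3)
  # regularized family fixed point agrees with a brute-force root scan
  reg <- firing_rate("regularized", threshold_rule(2), smoothing = 0.3)
  Nr <- solve_total_activity(st, reg, 0)
  act <- function(x) g$ds * sum(firing_rate_eval(reg, g$centers, x) * st$values)
  expect_equal(Nr, act(Nr), tolerance = 1e-9)
})

test_that("one step is conservative, positive, and a pure shift when p = 0", {
  g <- sim_grid(10, 200)
  st <- initial_data("exp_decay", g)
  kd <- discretize_kernel(kern_half(), g)
  off <- firing_rate("step", 100)          # sigma beyond the domain: p == 0
  r <- step_density(st, off, kd)
  expect_equal(r$N, 0)
  expect_equal(r$state$values[2:199], st$values[1:198])
  expect_equal(r$state$values[1], 0)
  # reflecting tail keeps the outgoing mass in the last cell
  expect_equal(r$state$values[200], st$values[199] + st$values[200])
  expect_equal(state_mass(r$state), 1)

  # 100 steps with active discharge: mass exact, values nonnegative
  rate <- firing_rate("step", threshold_rule(1))
  sQ <- st
  N_prev <- 0
  for (k in 1:100) {
    out <- step_density(sQ, rate, kd, N_prev)
    sQ <- out$state; N_prev <- out$N
    expect_true(all(sQ$values >= 0))
  }
  expect_lt(abs(state_mass(sQ) - 1), 1e-12)
})

test_that("constant-rate renewal profile is a discrete near-fixed point", {
  # A(s) = pM e^{-pM s} solves the continuum stationary problem for the
  # full-reset kernel; one step moves the discretized profile only at the
  # truncation tail (where the reflecting cell accumulates the remnant
  # e^{-s_max} mass), and not at all in the interior
  for (n in c(250L, 500L)) {
    g <- sim_grid(25, n)
    kd <- discretize_kernel(kern_reset(), g)
    A <- exp(-g$centers); A <- A / (g$ds * sum(A))
    st <- structure(list(values = A, grid = g, time = 0),
                    class = "density_state")
    out <- step_density(st, rate_const(1), kd)
    resid <- abs(out$state$values - A) / g$dt
    # residual is at the e^{-s_max} truncation scale, far below O(ds)
    expect_lt(max(resid), 1e-9)
  }
})

test_that("runs preserve mass, bound the activity, and honor T = 0", {
  g <- sim_grid(18, 600)
  kd <- discretize_kernel(kern_half(), g)
  rate <- firing_rate("step", threshold_rule(2))
  st <- initial_data("exp_decay", g)

  tr0 <- run_simulation(st, rate, kd, T_end = 0)
  expect_length(tr0$N, 1L)
  expect_equal(tr0$times, 0)

  for (kind in c("exp_decay", "multi_bump")) {
    tr <- run_simulation(initial_data(kind, g), rate, kd, T_end = 30)
    expect_lt(abs(tr$mass_drift), 1e-10)
    expect_true(all(tr$N >= 0 & tr$N <= rate$p_max))
    expect_true(all(tr$final_state$values >= 0))
  }

  off <- firing_rate("step", 100)
  trz <- run_simulation(st, off, kd, T_end = 5)
  expect_true(all(trz$N == 0))
})

test_that("the reset kernel reproduces an age-structured renewal solver", {
  g <- sim_grid(15, 300)
  kd <- discretize_kernel(kern_reset(), g)
  st <- initial_data("exp_decay", g)
  n_steps <- 400L
  ref <- renewal_reference(st$values, g, p_const(1), n_steps)
  tr <- run_simulation(st, rate_const(1), kd, T_end = n_steps * g$dt)
  expect_lt(max(abs(tr$final_state$values - ref)), 1e-11)
})

test_that("long-time constant-rate profile converges to the exponential", {
  sup_err <- function(n) {
    g <- sim_grid(20, n)
    kd <- discretize_kernel(kern_reset(), g)
    tr <- run_simulation(initial_data("exp_decay", g), rate_const(1), kd,
                         T_end = 30)
    max(abs(tr$final_state$values - exp(-g$centers)))
  }
  e1 <- sup_err(200); e2 <- sup_err(400)
  expect_lt(e2, e1)
  expect_gt(e1 / e2, 1.5)      # at least first-order decrease
  expect_lt(e1, 0.05)
})
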