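test_that("threshold bounds match their closed form and ordering", {
  np <- n_plus_minus(2)
  d <- 2 * exp(2) - 1
  expect_equal(unname(np), c(1 / d, exp(2) / d), tolerance = 1e-14)
  expect_equal(unname(np), c(0.07257889, 0.53628944), tolerance = 1e-7)

  # limits of the closed form
  small <- n_plus_minus(1e-9)
  expect_equal(unname(small), c(1, 1), tolerance = 1e-8)
  large <- n_plus_minus(40)
  expect_lt(large[["N_minus"]], 1e-15)
  expect_equal(large[["N_plus"]], 0.5, tolerance = 1e-12)

  set.seed(11)
  for (a in runif(50, 0.1, 10)) {
    np <- n_plus_minus(a)
    expect_true(0 < np[["N_minus"]] && np[["N_minus"]] < np[["N_plus"]] &&
                np[["N_plus"]] < 1)
  }
  expect_error(n_plus_minus(-1), "positive")
})

test_that("the refractory threshold is piecewise, continuous, non-increasing", {
  rule <- threshold_rule(2)
  expect_equal(sigma_of(0, rule), 4)                       # 2*alpha branch
  expect_equal(sigma_of(rule$N_plus, rule), 2)             # alpha branch
  expect_equal(sigma_of(1, threshold_rule(3)), 3)
  # continuity at the joins
  expect_equal(sigma_of(rule$N_minus * (1 + 1e-12), rule), 4, tolerance = 1e-9)
  expect_equal(sigma_of(rule$N_plus * (1 - 1e-12), rule), 2, tolerance = 1e-9)
  # range is [alpha, 2 alpha]
  x <- seq(0, 1, length.out = 200)
  sg <- sigma_of(x, rule)
  expect_true(all(sg >= 2 - 1e-12 & sg <= 4 + 1e-12))
  # non-increasing on random pairs
  set.seed(7)
  x1 <- runif(100); x2 <- x1 + runif(100)
  expect_true(all(sigma_of(x1, rule) >= sigma_of(x2, rule) - 1e-12))
  # constant threshold passthrough
  expect_equal(sigma_of(c(0, 0.5, 2), 1.25), rep(1.25, 3))
})

test_that("firing rate families respect the ceiling and threshold", {
  rate <- firing_rate("step", threshold_rule(2))
  expect_equal(firing_rate_eval(rate, 3.9, 0), 0)       # sigma(0) = 4
  expect_equal(firing_rate_eval(rate, 4.0, 0), 1)       # closed boundary
  expect_equal(firing_rate_eval(rate, 10, 0), 1)

  reg <- firing_rate("regularized", threshold_rule(2), smoothing = 0.2)
  sg <- sigma_of(0, reg$threshold)
  expect_equal(firing_rate_eval(reg, sg - 0.1, 0), 0.5)  # ramp midpoint
  expect_equal(firing_rate_eval(reg, sg - 0.2, 0), 0)
  expect_equal(firing_rate_eval(reg, sg, 0), 1)
  # 0 <= p <= pM everywhere, p = pM beyond sigma(N)
  s <- seq(0, 10, length.out = 500)
  for (N in c(0, 0.1, 0.6, 1)) {
    p <- firing_rate_eval(reg, s, N)
    expect_true(all(p >= 0 & p <= 1))
    expect_true(all(p[s >= sigma_of(N, reg$threshold)] == 1))
  }
  expect_error(firing_rate("regularized", 1, smoothing = 0), "smoothing")
})

test_that("cumulative kernel is the exact indicator for point maps", {
  kern <- kern_half()
  expect_equal(kernel_cdf(kern, 0.3, 0.4), 1)     # 0.3 >= 0.2
  expect_equal(kernel_cdf(kern, 0.19, 0.4), 0)
  k0 <- kern_reset()
  expect_equal(kernel_cdf(k0, 1e-9, 5), 1)        # all mass at 0
  set.seed(3)
  s <- runif(100, 0, 10); u <- runif(100, 0, 10)
  f <- mapply(function(si, ui) kernel_cdf(kern, si, ui), s, u)
  expect_equal(f, as.numeric(s >= pmin(0.5 * u, u)))
  # f = 1 for s >= u holds for any kernel family
  expect_equal(kernel_cdf(kern_triangular(), 2, 2), 1)
  expect_equal(kernel_cdf(kern_triangular(), 5, 2), 1)
  # density-family cdf is nondecreasing in s and in [0, 1]
  fd <- kernel_cdf(kern_triangular(), seq(0, 3, 0.05), 2.5)
  expect_true(all(diff(fd) >= -1e-12))
  expect_true(all(fd >= 0 & fd <= 1))
})

test_that("contraction bound estimates match psi' and reject theta >= 1", {
  expect_equal(kernel_theta(kern_half()), 0.5, tolerance = 1e-12)
  expect_equal(kernel_theta(kern_reset()), 0, tolerance = 1e-12)
  expect_equal(kernel_theta(fragmentation_kernel("point_map", psi = 0.9)),
               0.9, tolerance = 1e-12)
  expect_error(
    kernel_theta(fragmentation_kernel("point_map",
                                      psi = function(u) u,
                                      psi_prime = function(u) rep(1, length(u)))),
    "admissible")
  # triangular density kernel: first moment u/3, slope 1/3
  expect_equal(kernel_theta(kern_triangular()), 1 / 3, tolerance = 1e-3)
})

test_that("kernel discretization is column-stochastic and causal", {
  for (kern in list(kern_reset(), kern_half(),
                    fragmentation_kernel("point_map", psi = 0.3),
                    kern_triangular())) {
    for (n in c(37L, 100L, 256L)) {
      g <- sim_grid(8, n)
      kd <- discretize_kernel(kern, g)
      cs <- Matrix::colSums(kd$matrix)
      expect_lt(max(abs(cs - 1)), 1e-12)
      expect_true(all(Matrix::tril(kd$matrix, -1) == 0))
      expect_true(all(kd$matrix@x >= 0))
    }
  }
  # full reset deposits everything in the first cell
  g <- sim_grid(4, 40)
  kd0 <- discretize_kernel(kern_reset(), g)
  expect_equal(as.numeric(kd0$matrix[1, ]), rep(1, 40))
  # psi(u) = u/2 with u on an even-indexed center lands on a single cell,
  # and interior deposits preserve the first moment exactly
  kdh <- discretize_kernel(kern_half(), g)
  mom <- as.numeric(g$centers %*% kdh$matrix)
  expect_lt(max(abs(mom - 0.5 * g$centers)[5:40]), 1e-12)
})

test_that("B* matches closed forms and a finer quadrature oracle", {
  kern <- kern_half()
  # constant rate: sigma* = 0, both bracket terms vanish
  expect_equal(compute_B_star(rate_const(), kern, 0), 0)
  # step family closed form sigma* * pM
  step <- firing_rate("step", threshold_rule(2))
  expect_equal(compute_B_star(step, kern, 0), 4)             # sigma(0) = 4
  expect_equal(compute_B_star(step, kern, 1), 2)             # sigma(1) = 2
  st2 <- firing_rate("step", 0.4, p_max = 2)
  expect_equal(compute_B_star(st2, kern, 0), 0.8)
  # regularized family against an independent adaptive-quadrature oracle
  reg <- firing_rate("regularized", 0.6, smoothing = 0.25)
  b1 <- compute_B_star(reg, kern, 0)
  int_p <- stats::integrate(function(s) firing_rate_eval(reg, s, 0),
                            0, 0.6, rel.tol = 1e-10)$value
  int_dp <- stats::integrate(
    function(s) ifelse(s > 0.35 & s < 0.6, 1 / 0.25, 0),
    0, 0.6, rel.tol = 1e-10, subdivisions = 500L)$value
  expect_equal(b1, exp(int_p) * (0.6 * int_dp + 0.5 * int_p),
               tolerance = 1e-6)
  # ramp wider than the refractory window (delta > sigma*)
  reg2 <- firing_rate("regularized", 0.3, smoothing = 0.5)
  ip2 <- stats::integrate(function(s) firing_rate_eval(reg2, s, 0),
                          0, 0.3, rel.tol = 1e-10)$value
  expect_equal(compute_B_star(reg2, kern, 0),
               exp(ip2) * (0.3 * 1 * 0.3 / 0.5 + 0.5 * ip2),
               tolerance = 1e-6)
})

test_that("assumption report covers certificates, moments and flags", {
  # p == 1, psi = u/2: direct rate nu = p * psibar' = 1/2
  rep1 <- check_assumptions(rate_const(), kern_half())
  expect_equal(rep1$nu_B1, 0.5, tolerance = 1e-10)
  expect_true(rep1$condition_15_holds)
  expect_lt(rep1$B_star, 1)
  expect_true(rep1$condition_16_holds)
  expect_gt(rep1$mu_star, 0)

  # full reset, p == 1: theta = 0, nu = 1
  rep0 <- check_assumptions(rate_const(), kern_reset())
  expect_equal(rep0$theta_estimate, 0, tolerance = 1e-12)
  expect_equal(rep0$nu_B1, 1, tolerance = 1e-10)

  # large sigma* with theta = 0.9: B* >= 1, certificate fails
  big <- firing_rate("step", 5)
  k9 <- fragmentation_kernel("point_map", psi = 0.9)
  repb <- check_assumptions(big, k9)
  expect_gte(repb$B_star, 1)
  expect_false(repb$condition_15_holds)

  # step rate with activity-dependent threshold is flagged, not rejected
  reps <- check_assumptions(firing_rate("step", threshold_rule(2)),
                            kern_half())
  expect_true(any(grepl("outside the smallness hypotheses", reps$notes)))
  expect_true(is.na(reps$nu_B1))

  # condition-16 witness actually satisfies the inequality (point kernel)
  mu <- rep1$mu_star
  u <- seq(0, rep1$sigma_star, length.out = 400)
  lhs <- max(1 * (exp(mu * (u - 0.5 * u)) - 1))
  expect_lt(lhs, mu)
})
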