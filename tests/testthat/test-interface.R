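test_that("presets expand to the documented experiment parameters", {
  expected <- list(fig1_left = c(2, 0), fig1_right = c(2, 0.5),
                   fig2 = c(4, 0), fig3 = c(4, 0.5), fig4 = c(3, 0.5))
  for (nm in names(expected)) {
    cfg <- load_config(list(preset = nm))
    expect_equal(cfg$rate$alpha, expected[[nm]][1], info = nm)
    expect_equal(cfg$kernel$psi_slope, expected[[nm]][2], info = nm)
    expect_identical(cfg$kernel$family, "point_map")
    expect_identical(cfg$init$kind, "exp_decay")
  }
  # reset-kernel presets ride the hysteresis branch, proportional-kernel
  # presets take the maximal self-consistent activity
  expect_identical(load_config(list(preset = "fig2"))$solver$root_rule,
                   "continuation")
  expect_identical(load_config(list(preset = "fig3"))$solver$root_rule,
                   "largest")
  expect_error(load_config(list(preset = "fig9")), "unknown preset")
  expect_length(describe_presets(), 5L)
})

test_that("config files load with defaults, overrides and validation", {
  # empty file: all defaults
  f <- tempfile(fileext = ".yaml"); writeLines(character(0), f)
  cfg <- load_config(f)
  expect_identical(cfg$rate$family, "step")
  expect_equal(cfg$run$T, 100)

  # yaml and json overrides on top of a preset
  fy <- tempfile(fileext = ".yaml")
  writeLines(c("preset: fig1_right", "grid:", "  s_max: 10.5",
               "run:", "  T: 7"), fy)
  cy <- load_config(fy)
  expect_equal(cy$grid$s_max, 10.5)
  expect_equal(cy$run$T, 7)
  expect_equal(cy$rate$alpha, 2)

  fj <- tempfile(fileext = ".json")
  writeLines('{"rate": {"alpha": 3.5}, "kernel": {"psi_slope": 0.25}}', fj)
  cj <- load_config(fj)
  expect_equal(cj$rate$alpha, 3.5)
  expect_equal(cj$kernel$psi_slope, 0.25)

  # all violations are reported together
  err <- tryCatch(
    load_config(list(rate = list(alpha = -1, pM = 0),
                     kernel = list(psi_slope = 1.5),
                     extras = list(x = 1))),
    error = conditionMessage)
  expect_match(err, "alpha must be positive")
  expect_match(err, "pM must be positive")
  expect_match(err, "psi_slope")
  expect_match(err, "unknown block: extras")

  # round trip: loading an expanded config is idempotent
  expect_identical(load_config(cy), cy)
})

test_that("configs expand into consistent model objects", {
  m <- build_model(load_config(list(preset = "fig1_left",
                                    grid = list(ds = 0.05))))
  expect_s3_class(m$grid, "sim_grid")
  expect_equal(m$grid$s_max, 4 * 4 + 10)     # 4 sigma_max + 10 / pM
  expect_equal(m$grid$ds, 0.05)
  expect_identical(m$rate$family, "step")
  expect_equal(state_mass(m$init), 1)
  expect_lt(max(abs(Matrix::colSums(m$kd$matrix) - 1)), 1e-12)
})

test_that("outputs are written deterministically and echo the config", {
  g <- sim_grid(6, 120)
  kd <- discretize_kernel(kern_half(), g)
  rate <- firing_rate("step", threshold_rule(1))
  tr <- run_simulation(initial_data("exp_decay", g), rate, kd, T_end = 2,
                       snapshot_times = c(0, 1, 2))
  d <- tempfile(); dir.create(d)
  f1 <- write_outputs(tr, file.path(d, "runA"), cfg = list(note = "x"))
  f2 <- write_outputs(tr, file.path(d, "runB"), cfg = list(note = "x"))
  expect_true(all(file.exists(f1)))
  # byte-identical outputs for identical inputs
  for (k in seq_along(f1))
    expect_identical(readLines(f1[k]), readLines(f2[k]))
  act <- read.csv(f1[1])
  expect_identical(names(act), c("t", "N"))
  expect_equal(nrow(act), length(tr$times))
  snaps <- read.csv(f1[2])
  expect_identical(names(snaps), c("t", "s", "n"))
  meta <- jsonlite::read_json(f1[3])
  expect_true(meta$conservation_ok)
  expect_identical(meta$config$note, "x")

  # steady and spectral writers
  res <- linear_stationary(p_const(1), discretize_kernel(kern_reset(), g),
                           1e-4)
  fs <- write_outputs(res, file.path(d, "steady"))
  expect_identical(basename(fs), c("steady_A.csv", "steady_steady.json"))
  sj <- jsonlite::read_json(fs[2])
  expect_equal(sj$lambda, res$lambda, tolerance = 1e-12)
  expect_true(sj$eigenvalue_bracket_ok)

  fl <- find_lambda(rate_const(1), kern_reset(), g)
  fp <- write_outputs(fl, file.path(d, "spec"))
  pj <- jsonlite::read_json(fp[2])
  expect_true(pj$admissible)
  expect_equal(pj$lambda, -0.25)
  unlink(d, recursive = TRUE)
})
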