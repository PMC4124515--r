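default_config <- function() {
  list(
    preset = NULL,
    grid = list(s_max = NULL, n_cells = NULL, ds = 0.01),
    rate = list(family = "step", alpha = 2, sigma = NULL, pM = 1, delta = 0),
    kernel = list(family = "point_map", psi_slope = 0.5),
    init = list(kind = "exp_decay", centers = c(1, 5), widths = 0.2),
    run = list(T = 100, snapshot_times = NULL),
    solver = list(root_rule = "continuation", fp_tol = 1e-12)
  )
}

# Root-selection rules per preset: the reset kernel's large-amplitude
# periodic family rides the hysteresis branch (continuation), while the
# proportional kernel's unique orbit is selected by the maximal
# self-consistent activity (largest).
preset_table <- function() {
  list(
    fig1_left  = list(rate = list(alpha = 2), kernel = list(psi_slope = 0),
                      solver = list(root_rule = "continuation")),
    fig1_right = list(rate = list(alpha = 2), kernel = list(psi_slope = 0.5),
                      solver = list(root_rule = "largest")),
    fig2       = list(rate = list(alpha = 4), kernel = list(psi_slope = 0),
                      solver = list(root_rule = "continuation")),
    fig3       = list(rate = list(alpha = 4), kernel = list(psi_slope = 0.5),
                      solver = list(root_rule = "largest")),
    fig4       = list(rate = list(alpha = 3), kernel = list(psi_slope = 0.5),
                      solver = list(root_rule = "largest"))
  )
}

#' List or describe the built-in experiment presets
#'
#' The presets reproduce the long-time regimes of the model's four
#' reference experiments: full-reset kernel versus proportional
#' (`psi(u) = u/2`) kernel at threshold scales `alpha = 2, 3, 4`, all with
#' the step rate, ceiling 1, and an `e^{-s}` initial profile (the
#' structured multi-bump profile is the companion initial condition for
#' the comparison runs).
#'
#' @param name optional preset name; when absent, all presets are listed.
#' @return a list describing the preset(s), invisibly when printing.
#' @export
describe_presets <- function(name = NULL) {
  pt <- preset_table()
  if (!is.null(name)) {
    if (!name %in% names(pt)) stop("unknown preset: ", name)
    return(pt[[name]])
  }
  pt
}

merge_config <- function(base, upd) {
  for (nm in names(upd)) {
    if (is.list(upd[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], upd[[nm]])
    else base[nm] <- list(upd[[nm]])    # keeps explicit NULLs in place
  }
  base
}

known_keys <- function() {
  list(grid = c("s_max", "n_cells", "ds"),
       rate = c("family", "alpha", "sigma", "pM", "delta"),
       kernel = c("family", "psi_slope"),
       init = c("kind", "centers", "widths", "weights"),
       run = c("T", "snapshot_times"),
       solver = c("root_rule", "fp_tol"))
}

validate_config <- function(cfg) {
  errs <- character(0)
  kk <- known_keys()
  for (blk in names(cfg)) {
    if (blk == "preset") next
    if (!blk %in% names(kk)) { errs <- c(errs, paste("unknown block:", blk)); next }
    bad <- setdiff(names(cfg[[blk]]), kk[[blk]])
    if (length(bad))
      errs <- c(errs, sprintf("unknown key(s) in [%s]: %s", blk,
                              paste(bad, collapse = ", ")))
  }
  r <- cfg$rate
  if (!r$family %in% c("step", "regularized"))
    errs <- c(errs, "rate family must be 'step' or 'regularized'")
  if (is.null(r$sigma) && (!is.numeric(r$alpha) || r$alpha <= 0))
    errs <- c(errs, "rate alpha must be positive")
  if (!is.numeric(r$pM) || r$pM <= 0)
    errs <- c(errs, "rate pM must be positive")
  if (r$family == "regularized" && (!is.numeric(r$delta) || r$delta <= 0))
    errs <- c(errs, "regularized rate needs delta > 0")
  k <- cfg$kernel
  if (!k$family %in% c("point_map", "density"))
    errs <- c(errs, "kernel family must be 'point_map' or 'density'")
  if (k$family == "point_map" &&
      (!is.numeric(k$psi_slope) || k$psi_slope < 0 || k$psi_slope >= 1))
    errs <- c(errs, "kernel psi_slope must lie in [0, 1)")
  if (!cfg$init$kind %in% c("exp_decay", "multi_bump"))
    errs <- c(errs, "init kind must be 'exp_decay' or 'multi_bump'")
  if (!is.numeric(cfg$run$T) || cfg$run$T < 0)
    errs <- c(errs, "run T must be nonnegative")
  if (!cfg$solver$root_rule %in% c("continuation", "largest"))
    errs <- c(errs, "solver root_rule must be 'continuation' or 'largest'")
  if (length(errs))
    stop("config validation failed:\n  - ", paste(errs, collapse = "\n  - "))
  cfg
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration file, expands an optional `preset`
#' (see [describe_presets()]) before applying the file's own overrides,
#' fills defaults, and validates every key (all violations are reported
#' together).  An empty file yields the all-defaults configuration.
#'
#' @param path configuration file (`.yaml`/`.yml`/`.json`), or `NULL` /
#'   a list for programmatic use.
#' @return validated configuration list.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) list()
          else if (is.list(path)) path
          else {
            if (!file.exists(path)) stop("config file not found: ", path)
            if (grepl("\\.json$", path, ignore.case = TRUE))
              jsonlite::read_json(path, simplifyVector = TRUE)
            else yaml::read_yaml(path) %||% list()
          }
  cfg <- default_config()
  pr <- user$preset %||% NULL
  if (!is.null(pr)) {
    pt <- preset_table()
    if (!pr %in% names(pt)) stop("unknown preset: ", pr)
    cfg <- merge_config(cfg, pt[[pr]])
    cfg$preset <- pr
  }
  cfg <- merge_config(cfg, user[setdiff(names(user), "preset")])
  validate_config(cfg)
}

#' Instantiate model objects from a configuration
#'
#' Expands a validated configuration into the grid, rate, kernel, kernel
#' discretization and initial state.  When `s_max` is absent it defaults
#' to `4 * sigma_max + 10 / pM` (beyond the threshold the rate equals the
#' ceiling, so the tail mass decays geometrically past that point).
#'
#' @param cfg configuration list from [load_config()].
#' @return list with `grid`, `rate`, `kern`, `kd`, `init`, `cfg`.
#' @export
build_model <- function(cfg) {
  cfg <- validate_config(cfg)
  r <- cfg$rate
  thr <- if (!is.null(r$sigma)) r$sigma else threshold_rule(r$alpha)
  rate <- firing_rate(r$family, thr, p_max = r$pM,
                      smoothing = r$delta %||% 0)
  sig_max <- if (is.numeric(thr)) thr else thr$sigma_plus
  s_max <- cfg$grid$s_max %||% (4 * sig_max + 10 / r$pM)
  n_cells <- cfg$grid$n_cells %||% round(s_max / cfg$grid$ds)
  grid <- sim_grid(s_max, n_cells)
  kern <- if (cfg$kernel$family == "point_map")
    fragmentation_kernel("point_map", psi = cfg$kernel$psi_slope)
  else stop("density kernels must be constructed programmatically")
  kd <- discretize_kernel(kern, grid)
  init <- initial_data(cfg$init$kind, grid,
                       params = list(centers = cfg$init$centers,
                                     widths = cfg$init$widths,
                                     weights = cfg$init$weights))
  list(grid = grid, rate = rate, kern = kern, kd = kd, init = init,
       cfg = cfg)
}

#' Write run results to CSV/JSON files
#'
#' Writes, per result class, the canonical tabular outputs with a
#' deterministic field order plus a JSON metadata file (package version,
#' configuration echo, conservation report):
#' * trajectory: `<prefix>_activity.csv` (t, N),
#'   `<prefix>_snapshots.csv` (long format t, s, n), `<prefix>_meta.json`;
#' * stationary result: `<prefix>_A.csv` (s, A), `<prefix>_steady.json`;
#' * dual eigenresult: `<prefix>_P.csv` (s, P), `<prefix>_spectral.json`.
#'
#' @param result a `trajectory`, `stationary_result` or
#'   `dual_eigenresult`.
#' @param prefix output path prefix.
#' @param cfg optional configuration to echo into the metadata.
#' @return character vector of the files written, invisibly.
#' @export
write_outputs <- function(result, prefix, cfg = NULL) {
  ver <- as.character(utils::packageVersion("neurofrag"))
  files <- character(0)
  wjson <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    path
  }
  if (inherits(result, "trajectory")) {
    f1 <- paste0(prefix, "_activity.csv")
    utils::write.csv(data.frame(t = result$times, N = result$N),
                     f1, row.names = FALSE)
    files <- c(files, f1)
    if (length(result$snapshots)) {
      f2 <- paste0(prefix, "_snapshots.csv")
      long <- do.call(rbind, lapply(seq_along(result$snapshots), function(i)
        data.frame(t = result$snapshot_times[i], s = result$grid$centers,
                   n = result$snapshots[[i]])))
      utils::write.csv(long, f2, row.names = FALSE)
      files <- c(files, f2)
    }
    files <- c(files, wjson(
      list(package_version = ver, config = cfg,
           mass_drift = result$mass_drift,
           conservation_ok = abs(result$mass_drift) < 1e-10,
           t_end = max(result$times), dt = result$grid$dt),
      paste0(prefix, "_meta.json")))
  } else if (inherits(result, "stationary_result")) {
    f1 <- paste0(prefix, "_A.csv")
    utils::write.csv(data.frame(s = result$grid$centers, A = result$A_values),
                     f1, row.names = FALSE)
    files <- c(files, f1, wjson(
      list(package_version = ver, config = cfg,
           lambda = result$lambda, epsilon = result$epsilon, R = result$R,
           A_star = result$A_star, residual = result$residual,
           eigenvalue_bracket_ok = result$bounds_ok,
           mass = result$grid$ds * sum(result$A_values)),
      paste0(prefix, "_steady.json")))
  } else if (inherits(result, "dual_eigenresult")) {
    if (!is.null(result$P_values)) {
      f1 <- paste0(prefix, "_P.csv")
      utils::write.csv(data.frame(s = result$s, P = result$P_values),
                       f1, row.names = FALSE)
      files <- c(files, f1)
    }
    files <- c(files, wjson(
      list(package_version = ver, config = cfg,
           lambda = result$lambda, B_star = result$B_star,
           B_ratio = result$B_ratio, admissible = result$admissible,
           status = result$status),
      paste0(prefix, "_spectral.json")))
  } else stop("unsupported result class: ", paste(class(result), collapse = "/"))
  invisible(files)
}
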