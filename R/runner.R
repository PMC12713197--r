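#' Configure a full simulation run
#'
#' Resolves a run profile into a complete, validated configuration. Profiles
#' fix the replicate count per grid cell: `"paper"` runs the published scale
#' (100,000 replicates per cell), `"reduced"` 10,000, `"smoke"` 200; profile
#' `"custom"` accepts any `n_reps`. Supplying `n_reps` with a fixed profile is
#' a configuration error.
#'
#' @param profile One of `"reduced"`, `"paper"`, `"smoke"`, `"custom"`.
#' @param n_reps Replicates per cell; only with `profile = "custom"`.
#' @param truth_fraction Fraction of true-effect replicates per cell.
#' @param q_threshold FDR level for the interaction test.
#' @param alpha_posthoc Two-sided level for the post-hoc paired tests.
#' @param posthoc_scope Conditioning scope used for the headline pooled
#'   rates and the power curve; see [pool_by_power()].
#' @param power_targets Sensitivities at which pooled control-FP rates are
#'   reported.
#' @param power_window Half-width of each power bin.
#' @param min_sensitivity Sensitivity floor for the pooled "well-powered"
#'   rate.
#' @param base_seed Integer base seed; every cell seed derives from it via
#'   [cell_seed()].
#' @param n_values,effect_values,weight_values Grid ranges (defaults are the
#'   published ranges).
#' @param cells Optional subset: integer indices or `cell_id` strings.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(profile = c("reduced", "paper", "smoke", "custom"),
                       n_reps = NULL, truth_fraction = 0.1,
                       q_threshold = 0.05, alpha_posthoc = 0.05,
                       posthoc_scope = c("true_significant", "all_significant"),
                       power_targets = c(0.05, 0.2, 0.8),
                       power_window = 0.025, min_sensitivity = 1 / 3,
                       base_seed = 1L,
                       n_values = seq(5L, 50L, 5L),
                       effect_values = seq(0.1, 1, 0.1),
                       weight_values = seq(0.1, 1, 0.1),
                       cells = NULL) {
  profile <- match.arg(profile)
  posthoc_scope <- match.arg(posthoc_scope)
  fixed <- c(paper = 100000L, reduced = 10000L, smoke = 200L)
  if (profile %in% names(fixed)) {
    if (!is.null(n_reps) && as.integer(n_reps) != fixed[[profile]])
      stop_posthocsim(sprintf("profile '%s' fixes n_reps = %d", profile,
                              fixed[[profile]]), "configuration_error")
    n_reps <- fixed[[profile]]
  } else if (is.null(n_reps)) {
    stop_posthocsim("profile 'custom' requires n_reps", "configuration_error")
  }
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1L)
    stop_posthocsim("n_reps must be a positive integer", "configuration_error")
  if (any(!is.finite(power_targets)) ||
      any(power_targets < 0 | power_targets > 1))
    stop_posthocsim("power_targets must lie in [0, 1]", "configuration_error")
  if (!is.finite(power_window) || power_window <= 0)
    stop_posthocsim("power_window must be positive", "configuration_error")
  structure(list(profile = profile, n_reps = n_reps,
                 truth_fraction = truth_fraction,
                 q_threshold = q_threshold, alpha_posthoc = alpha_posthoc,
                 posthoc_scope = posthoc_scope,
                 power_targets = power_targets, power_window = power_window,
                 min_sensitivity = min_sensitivity,
                 base_seed = as.integer(base_seed),
                 n_values = as.integer(n_values),
                 effect_values = effect_values,
                 weight_values = weight_values,
                 cells = cells),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Accepts the same keys as the arguments of [run_config()]; unknown keys are
#' a configuration error.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_posthocsim(sprintf("config file '%s' does not exist", path),
                    "configuration_error")
  vals <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(run_config)), "")
  bad <- setdiff(names(vals), allowed)
  if (length(bad) > 0L)
    stop_posthocsim(paste("unknown config keys:", paste(bad, collapse = ", ")),
                    "configuration_error")
  do.call(run_config, vals)
}

# Build the grid a config describes and apply its cell subset.
config_grid <- function(config) {
  grid <- build_grid(config$n_values, config$effect_values,
                     config$weight_values, n_reps = config$n_reps,
                     truth_fraction = config$truth_fraction,
                     base_seed = config$base_seed,
                     q_threshold = config$q_threshold,
                     alpha_posthoc = config$alpha_posthoc)
  if (is.null(config$cells)) return(grid)
  if (is.numeric(config$cells)) {
    idx <- as.integer(config$cells)
    if (any(is.na(idx) | idx < 1L | idx > length(grid)))
      stop_posthocsim("cell indices out of range", "configuration_error")
  } else {
    ids <- vapply(grid, `[[`, character(1), "cell_id")
    idx <- match(config$cells, ids)
    if (anyNA(idx))
      stop_posthocsim(paste("unknown cell ids:",
                            paste(config$cells[is.na(idx)], collapse = ", ")),
                      "configuration_error")
  }
  grid[idx]
}

# Power-bin table over both conditioning scopes; empty bins become NA rows.
power_bin_table <- function(summaries, config) {
  rows <- list()
  for (scope in c("true_significant", "all_significant")) {
    for (tgt in config$power_targets) {
      bin <- tryCatch(pool_by_power(summaries, tgt, config$power_window,
                                    scope = scope),
                      posthocsim_error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "bin", power_target = tgt, window = config$power_window,
        scope = scope,
        rate = if (is.null(bin)) NA_real_ else bin$rate,
        n_cells = if (is.null(bin)) 0L else bin$n_cells,
        n_pooled = if (is.null(bin)) 0L else bin$n_pooled)
    }
    above <- tryCatch(pool_above_power(summaries, config$min_sensitivity,
                                       scope = scope),
                      posthocsim_error = function(e) NULL)
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "floor", power_target = config$min_sensitivity, window = NA_real_,
      scope = scope,
      rate = if (is.null(above)) NA_real_ else above$rate,
      n_cells = if (is.null(above)) 0L else above$n_cells,
      n_pooled = if (is.null(above)) 0L else above$n_pooled)
  }
  do.call(rbind, rows)
}

# Meta-level fits over the per-cell summaries. Curve y-variables follow the
# configured conditioning scope; the winner's-curse curve is fitted on both
# the fraction and percent sensitivity scales.
meta_fits <- function(summaries, config) {
  reg <- tryCatch(fit_sensitivity_regression(summaries),
                  posthocsim_error = function(e) e)
  ycol <- if (config$posthoc_scope == "true_significant")
    "control_fp_rate_true" else "control_fp_rate"
  ok <- !is.na(summaries$sensitivity) & !is.na(summaries[[ycol]])
  fp_curve <- if (sum(ok) >= 4L)
    tryCatch(fit_curve(summaries$sensitivity[ok], summaries[[ycol]][ok],
                       "inv_sqrt"),
             posthocsim_error = function(e) e) else NULL
  det <- delta_effect_table(summaries)
  inflation_curve <- if (nrow(det) >= 4L)
    tryCatch(fit_curve(det$sensitivity, det$mean_delta_effect, "recip_quad"),
             posthocsim_error = function(e) e) else NULL
  inflation_curve_pct <- if (nrow(det) >= 4L)
    tryCatch(fit_curve(det$sensitivity * 100, det$mean_delta_effect,
                       "recip_quad"),
             posthocsim_error = function(e) e) else NULL
  list(regression = reg,
       control_fp_curve = fp_curve,
       inflation_curve = inflation_curve,
       inflation_curve_pct = inflation_curve_pct,
       dropped_cells = list(control_fp_curve = sum(!ok),
                            inflation_curve = nrow(summaries) - nrow(det)))
}

fit_to_json <- function(f) {
  if (is.null(f)) return(NULL)
  if (inherits(f, "error"))
    return(list(converged = FALSE, error = conditionMessage(f)))
  if (inherits(f, "curve_fit"))
    return(list(model_id = f$model_id, label = f$label,
                params = as.list(f$params), r2 = f$r2,
                adjusted_r2 = f$adjusted_r2, n_points = f$n_points,
                converged = f$converged,
                n_starts_converged = f$n_starts_converged,
                convergence_trace = f$diagnostics))
  if (inherits(f, "regression_fit"))
    return(list(coefficients = as.list(f$coefficients),
                std_errors = as.list(f$std_errors),
                t_values = as.list(f$t_values),
                p_values = as.list(f$p_values),
                residual_df = f$residual_df, adjusted_r2 = f$adjusted_r2,
                n_cells = f$n_cells))
  f
}

#' Run a full simulation experiment
#'
#' Orchestrates the whole pipeline deterministically from a [run_config()]:
#' builds the grid, simulates and tests every cell with [simulate_cell()],
#' summarises each cell with [summarize_setting()], pools the power-binned
#' control-arm false-positive rates, and fits the meta-level models
#' (sensitivity regression, control-FP power curve, winner's-curse curve).
#' Four artifacts are written to `output_dir`: `summary.csv` (one row per
#' cell), `power_bins.csv`, `fits.json` and `manifest.json` (the resolved
#' configuration, versions and wall-clock metadata).
#'
#' Given the same configuration (including `base_seed`) the run is
#' deterministic; any single cell re-run in isolation reproduces exactly its
#' rows, because every cell owns a seed derived from (`base_seed`, cell
#' index) alone.
#'
#' @param config A [run_config()].
#' @param output_dir Directory for the artifacts (created if missing).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list of class `experiment_run` with `summaries`,
#'   `power_bins`, `fits`, `manifest` and `paths`.
#' @export
run_experiment <- function(config, output_dir, quiet = FALSE) {
  if (!inherits(config, "run_config"))
    stop_posthocsim("config must be a run_config", "configuration_error")
  if (missing(output_dir) || !is.character(output_dir) || length(output_dir) != 1L)
    stop_posthocsim("output_dir must be a single path", "configuration_error")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(output_dir, 2L) != 0L)
    stop_posthocsim(sprintf("output directory '%s' is not writable", output_dir),
                    "configuration_error")
  grid <- config_grid(config)
  t0 <- Sys.time()
  n_degenerate <- 0L
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    res <- simulate_cell(grid[[i]])
    rows[[i]] <- withCallingHandlers(
      summarize_setting(res, grid[[i]]),
      warning = function(w) {
        n_degenerate <<- n_degenerate + 1L
        invokeRestart("muffleWarning")
      })
    if (!quiet && i %% 100L == 0L)
      message(sprintf("simulated %d/%d cells (%.1f s elapsed)", i, length(grid),
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  summaries <- do.call(rbind, rows)
  bins <- power_bin_table(summaries, config)
  fits <- meta_fits(summaries, config)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  if (n_degenerate > 0L)
    warning(sprintf("%d cell(s) contained degenerate replicates", n_degenerate))

  manifest <- list(
    config = unclass(config),
    n_cells = length(grid),
    package_version = as.character(packageVersion("posthocsim")),
    r_version = R.version.string,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    elapsed_seconds = elapsed,
    n_cells_with_degenerate_replicates = n_degenerate,
    dropped_cells = fits$dropped_cells)

  paths <- list(summary = file.path(output_dir, "summary.csv"),
                power_bins = file.path(output_dir, "power_bins.csv"),
                fits = file.path(output_dir, "fits.json"),
                manifest = file.path(output_dir, "manifest.json"))
  write.csv(summaries, paths$summary, row.names = FALSE)
  write.csv(bins, paths$power_bins, row.names = FALSE)
  jsonlite::write_json(
    list(regression = fit_to_json(fits$regression),
         control_fp_curve = fit_to_json(fits$control_fp_curve),
         inflation_curve = fit_to_json(fits$inflation_curve),
         inflation_curve_pct = fit_to_json(fits$inflation_curve_pct),
         dropped_cells = fits$dropped_cells),
    paths$fits, auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")

  invisible(structure(list(summaries = summaries, power_bins = bins,
                           fits = fits, manifest = manifest, paths = paths),
                      class = "experiment_run"))
}

#' @export
print.experiment_run <- function(x, ...) {
  cat(sprintf("<experiment_run> %d cells x %d reps (profile %s, seed %d)\n",
              x$manifest$n_cells, x$manifest$config$n_reps,
              x$manifest$config$profile, x$manifest$config$base_seed))
  cat(sprintf("  max interaction FPR: %.4f | cells with defined control-FP rate: %d\n",
              max(x$summaries$fpr_interaction, na.rm = TRUE),
              sum(!is.na(x$summaries$control_fp_rate_true))))
  invisible(x)
}
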