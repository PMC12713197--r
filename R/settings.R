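#' Specify one simulation setting (grid cell)
#'
#' A setting fixes the design of one batch of simulated trials: the per-group
#' sample size, the additive treatment effect `effect_size` (delta, in z-score
#' units, added to every post score of a true-effect active arm), the
#' test-retest noise scale `retest_weight` (w: the post score is the pre score
#' plus `w` times fresh standard-normal noise), the number of replicate trials
#' and the fraction of them carrying a true effect, the FDR threshold for the
#' interaction test and the two-sided level for the post-hoc paired tests,
#' and the seed of the setting's private random-number stream.
#'
#' Grid values of `effect_size` and `retest_weight` are carried internally as
#' integers scaled by 10 (`effect_size10`, `retest_weight10`) so that cell
#' identity is exact under joins despite the 0.1-step ranges.
#'
#' @param n_per_group Integer >= 2, participants per arm.
#' @param effect_size Additive post shift delta (z-units) in true-effect
#'   active arms. Non-negative.
#' @param retest_weight Noise scale w >= 0 multiplying the fresh post noise.
#'   `w = 0` is a degenerate case allowed only for testing; every paired and
#'   interaction statistic of such a trial has zero variance.
#' @param n_reps Number of replicate trials in this setting, >= 1.
#' @param truth_fraction Proportion of replicates with a true effect, in
#'   \[0, 1\]. Exactly `round(truth_fraction * n_reps)` replicates are true:
#'   the count is fixed, not re-randomized.
#' @param q_threshold FDR level declaring an interaction significant.
#' @param alpha_posthoc Two-sided level for the post-hoc paired tests.
#' @param seed Integer stream identifier for this setting.
#'
#' @return An object of class `setting_spec`.
#' @seealso [build_paper_grid()], [generate_trials()], [simulate_cell()]
#' @export
#' @examples
#' setting_spec(10, effect_size = 0.5, retest_weight = 0.5, n_reps = 100)
setting_spec <- function(n_per_group, effect_size, retest_weight, n_reps,
                         truth_fraction = 0.1, q_threshold = 0.05,
                         alpha_posthoc = 0.05, seed = 1L) {
  n_per_group <- as.integer(n_per_group)
  n_reps <- as.integer(n_reps)
  if (is.na(n_per_group) || n_per_group < 2L)
    stop_posthocsim("n_per_group must be an integer >= 2", "invalid_setting_error")
  if (is.na(n_reps) || n_reps < 1L)
    stop_posthocsim("n_reps must be an integer >= 1", "invalid_setting_error")
  if (!is.finite(effect_size) || effect_size < 0)
    stop_posthocsim("effect_size must be finite and >= 0", "invalid_setting_error")
  if (!is.finite(retest_weight) || retest_weight < 0)
    stop_posthocsim("retest_weight must be finite and >= 0", "invalid_setting_error")
  if (!is.finite(truth_fraction) || truth_fraction < 0 || truth_fraction > 1)
    stop_posthocsim("truth_fraction must lie in [0, 1]", "invalid_setting_error")
  for (nm in c("q_threshold", "alpha_posthoc")) {
    v <- get(nm)
    if (!is.finite(v) || v <= 0 || v >= 1)
      stop_posthocsim(sprintf("%s must lie in (0, 1)", nm), "invalid_setting_error")
  }
  e10 <- as.integer(round(effect_size * 10))
  w10 <- as.integer(round(retest_weight * 10))
  structure(list(
    n_per_group = n_per_group,
    effect_size = effect_size,
    retest_weight = retest_weight,
    effect_size10 = e10,
    retest_weight10 = w10,
    n_reps = n_reps,
    truth_fraction = truth_fraction,
    n_true = as.integer(round(truth_fraction * n_reps)),
    q_threshold = q_threshold,
    alpha_posthoc = alpha_posthoc,
    seed = as.integer(seed),
    cell_id = sprintf("n%02d_d%02d_w%02d", n_per_group, e10, w10)
  ), class = "setting_spec")
}

#' @export
print.setting_spec <- function(x, ...) {
  cat(sprintf(
    "<setting_spec %s> n=%d, delta=%.1f, w=%.1f, reps=%d (%d true), q<%g, alpha=%g, seed=%d\n",
    x$cell_id, x$n_per_group, x$effect_size, x$retest_weight,
    x$n_reps, x$n_true, x$q_threshold, x$alpha_posthoc, x$seed))
  invisible(x)
}

#' Deterministic per-cell seed stream
#'
#' Maps a base seed and a 1-based cell index to a positive integer seed so
#' that any grid cell can be regenerated in isolation and cells are mutually
#' independent streams. A fixed multiplicative hash keeps seeds distinct for
#' all indices within a grid.
#'
#' @param base_seed Integer base seed of the run.
#' @param index 1-based cell index.
#' @return A positive integer seed < 2^31.
#' @export
cell_seed <- function(base_seed, index) {
  b <- as.double(base_seed) %% 2147483647
  s <- (b * 48271 + as.double(index) * 16807) %% 2147483646
  as.integer(s) + 1L
}

# Generic grid constructor over explicit value lists (lexicographic in
# n, then effect, then weight). Internal; build_paper_grid() pins the
# published ranges on top of it.
build_grid <- function(n_values, effect_values, weight_values, n_reps,
                       truth_fraction = 0.1, base_seed = 1L,
                       q_threshold = 0.05, alpha_posthoc = 0.05) {
  n_values <- sort(unique(as.integer(n_values)))
  e10 <- sort(unique(as.integer(round(effect_values * 10))))
  w10 <- sort(unique(as.integer(round(weight_values * 10))))
  cells <- vector("list", length(n_values) * length(e10) * length(w10))
  i <- 0L
  for (n in n_values) for (d in e10) for (w in w10) {
    i <- i + 1L
    cells[[i]] <- setting_spec(
      n_per_group = n, effect_size = d / 10, retest_weight = w / 10,
      n_reps = n_reps, truth_fraction = truth_fraction,
      q_threshold = q_threshold, alpha_posthoc = alpha_posthoc,
      seed = cell_seed(base_seed, i))
  }
  cells
}

#' Build the published 1,000-cell simulation grid
#'
#' Constructs one [setting_spec()] per combination of per-group sample size
#' n in \{5, 10, ..., 50\}, treatment effect delta in \{0.1, ..., 1.0\} and
#' test-retest weight w in \{0.1, ..., 1.0\}, in lexicographic (n, delta, w)
#' order. Each cell receives its own deterministic seed from
#' [cell_seed()], so any cell can be regenerated alone and regeneration with
#' the same `base_seed` is bit-identical.
#'
#' @param n_reps Replicate trials per cell (the published experiment uses
#'   100,000; a reduced run of 10,000 preserves all summaries within
#'   Monte-Carlo tolerance).
#' @param truth_fraction Fraction of replicates per cell carrying a true
#'   effect (default 0.1, i.e. 10,000 of 100,000).
#' @param base_seed Integer base seed for the whole grid.
#' @param q_threshold,alpha_posthoc Significance settings stored in every cell.
#'
#' @return A list of 1,000 `setting_spec` objects.
#' @export
#' @examples
#' grid <- build_paper_grid(n_reps = 100, base_seed = 7)
#' length(grid)
#' grid[[1]]
build_paper_grid <- function(n_reps, truth_fraction = 0.1, base_seed = 1L,
                             q_threshold = 0.05, alpha_posthoc = 0.05) {
  grid <- build_grid(seq(5L, 50L, 5L), seq(0.1, 1, 0.1), seq(0.1, 1, 0.1),
                     n_reps = n_reps, truth_fraction = truth_fraction,
                     base_seed = base_seed, q_threshold = q_threshold,
                     alpha_posthoc = alpha_posthoc)
  stopifnot(length(grid) == 1000L)
  grid
}
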