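#' Summarise the replicate batch of one setting
#'
#' Collapses the per-replicate results of [simulate_cell()] into the rates
#' that characterise the selection artifact in one grid cell:
#'
#' * `sensitivity` — proportion of true-effect replicates with
#'   `q < q_threshold` (the statistical power of the interaction test);
#' * `fpr_interaction` — proportion of null replicates with
#'   `q < q_threshold`;
#' * `control_fp_rate_true` — among replicates that are *both* true-effect
#'   and significant, the proportion whose control-arm paired test has
#'   two-sided `p < alpha_posthoc` (the conditioning that creates the
#'   Berkson effect); the headline control-arm false-positive rate;
#' * `control_fp_rate` — the same proportion among *all* significant
#'   replicates, true or null;
#' * `control_fp_decline_rate` / `control_fp_decline_rate_true` — the
#'   decline-only variants (control test significant *and* mean change < 0);
#' * `mean_delta_effect` — among detected true effects, the mean of
#'   (`beta_hat` - delta): the winner's-curse inflation of the estimated
#'   effect size.
#'
#' Post-hoc quantities are computed only on replicates selected by the
#' interaction q-threshold. Rates with empty denominators are `NA`, never 0.
#' Degenerate replicates (zero change-score variance, possible only at
#' `retest_weight = 0`) are dropped from all denominators with a warning.
#'
#' @param results Data frame of per-replicate results as produced by
#'   [simulate_cell()] (columns `has_true_effect`, `q_value`, `beta_hat`,
#'   `control_p`, `control_mean_change`, `degenerate`).
#' @param spec The [setting_spec()] the results belong to.
#' @return A one-row data frame of class `setting_summary` with the cell
#'   identity (`n_per_group`, `effect_size`, `retest_weight`, `cell_id`),
#'   counts (`n_true`, `n_null`, `n_sig`, `n_true_positive`,
#'   `n_control_fp*`, `n_degenerate`), the rates above, and
#'   `mean_control_change_sig`, the mean control-arm change among significant
#'   replicates.
#' @export
summarize_setting <- function(results, spec) {
  if (!inherits(spec, "setting_spec"))
    stop_posthocsim("spec must be a setting_spec", "invalid_setting_error")
  need <- c("has_true_effect", "q_value", "beta_hat", "control_p",
            "control_mean_change", "degenerate")
  if (!is.data.frame(results) || !all(need %in% names(results)))
    stop_posthocsim(paste("results must contain columns:",
                          paste(need, collapse = ", ")),
                    "inconsistency_error")
  if (nrow(results) != spec$n_reps)
    stop_posthocsim(sprintf("results have %d rows but spec$n_reps is %d",
                            nrow(results), spec$n_reps),
                    "inconsistency_error")
  if (sum(results$has_true_effect) != spec$n_true)
    stop_posthocsim("truth-label count does not match the setting",
                    "inconsistency_error")

  n_deg <- sum(results$degenerate)
  if (n_deg > 0L)
    warning(sprintf("%s: dropped %d degenerate replicate(s) from denominators",
                    spec$cell_id, n_deg))
  res <- results[!results$degenerate, , drop = FALSE]

  truth <- res$has_true_effect
  sig <- res$q_value < spec$q_threshold
  posthoc_sig <- sig & res$control_p < spec$alpha_posthoc
  decline <- res$control_mean_change < 0

  rate <- function(num, den) if (den > 0L) num / den else NA_real_
  n_true <- sum(truth)
  n_null <- sum(!truth)
  n_sig <- sum(sig)
  n_tp <- sum(sig & truth)
  n_cfp <- sum(posthoc_sig)
  n_cfp_dec <- sum(posthoc_sig & decline)
  n_cfp_true <- sum(posthoc_sig & truth)
  n_cfp_true_dec <- sum(posthoc_sig & truth & decline)

  out <- data.frame(
    cell_id = spec$cell_id,
    n_per_group = spec$n_per_group,
    effect_size = spec$effect_size,
    retest_weight = spec$retest_weight,
    n_reps = spec$n_reps,
    n_true = n_true,
    n_null = n_null,
    n_degenerate = n_deg,
    sensitivity = rate(n_tp, n_true),
    fpr_interaction = rate(sum(sig & !truth), n_null),
    n_sig = n_sig,
    n_true_positive = n_tp,
    n_control_fp = n_cfp,
    n_control_fp_decline = n_cfp_dec,
    n_control_fp_true = n_cfp_true,
    n_control_fp_true_decline = n_cfp_true_dec,
    control_fp_rate = rate(n_cfp, n_sig),
    control_fp_decline_rate = rate(n_cfp_dec, n_sig),
    control_fp_rate_true = rate(n_cfp_true, n_tp),
    control_fp_decline_rate_true = rate(n_cfp_true_dec, n_tp),
    mean_delta_effect = if (n_tp > 0L)
      mean(res$beta_hat[sig & truth]) - spec$effect_size else NA_real_,
    mean_control_change_sig = if (n_sig > 0L)
      mean(res$control_mean_change[sig]) else NA_real_,
    stringsAsFactors = FALSE)
  class(out) <- c("setting_summary", class(out))
  out
}

# Resolve a pooling scope to its numerator/denominator count columns.
scope_columns <- function(scope) {
  switch(scope,
         true_significant = c(num = "n_control_fp_true", den = "n_true_positive"),
         all_significant  = c(num = "n_control_fp", den = "n_sig"),
         stop_posthocsim(sprintf("unknown scope '%s'", scope),
                         "invalid_setting_error"))
}

#' Pool the control-arm false-positive rate over a power bin
#'
#' Selects the grid cells whose estimated interaction-test sensitivity lies
#' within `power_target` plus/minus `window`, pools their selected replicates
#' (replicate-level pooling, not an average of cell rates) and returns the
#' fraction whose control-arm paired test was significant.
#'
#' `scope` decides which replicates are pooled: `"true_significant"` (the
#' default) conditions on replicates that simulated a true effect *and* were
#' detected, the conditioning under which the published per-power rates are
#' quoted; `"all_significant"` pools every significant replicate, null or
#' true.
#'
#' @param summaries Data frame of [summarize_setting()] rows (one per cell).
#' @param power_target Sensitivity at the centre of the bin, in \[0, 1\].
#' @param window Half-width of the bin (default 0.025).
#' @param scope `"true_significant"` or `"all_significant"`.
#' @return An object of class `power_bin`: a list with `rate`, `n_cells`,
#'   `n_pooled` (pooled denominator), `power_target`, `window`, `scope`.
#' @section Errors: an empty bin raises an `empty_bin_error` naming the bin.
#' @export
pool_by_power <- function(summaries, power_target, window = 0.025,
                          scope = c("true_significant", "all_significant")) {
  scope <- match.arg(scope)
  cols <- scope_columns(scope)
  keep <- !is.na(summaries$sensitivity) &
    summaries$sensitivity >= power_target - window &
    summaries$sensitivity <= power_target + window
  if (!any(keep))
    stop_posthocsim(sprintf("no cells with sensitivity in [%.3f, %.3f]",
                            power_target - window, power_target + window),
                    "empty_bin_error")
  num <- sum(summaries[[cols["num"]]][keep])
  den <- sum(summaries[[cols["den"]]][keep])
  structure(list(rate = if (den > 0L) num / den else NA_real_,
                 n_cells = sum(keep), n_pooled = den,
                 power_target = power_target, window = window, scope = scope),
            class = "power_bin")
}

#' @export
print.power_bin <- function(x, ...) {
  cat(sprintf(
    "<power_bin> power %.3f +/- %.3f (%s): control-FP rate %.3f (%d cells, %d pooled)\n",
    x$power_target, x$window, x$scope,
    x$rate, x$n_cells, x$n_pooled))
  invisible(x)
}

#' Pool the control-arm false-positive rate above a sensitivity floor
#'
#' Same replicate-level pooling as [pool_by_power()], over all cells with
#' sensitivity at or above `min_sensitivity` — e.g. the rate attained once a
#' design detects at least one third of true effects.
#'
#' @inheritParams pool_by_power
#' @param min_sensitivity Sensitivity floor in \[0, 1\].
#' @return A `power_bin` object (its `power_target` is the floor, `window`
#'   is `NA`).
#' @export
pool_above_power <- function(summaries, min_sensitivity,
                             scope = c("true_significant", "all_significant")) {
  scope <- match.arg(scope)
  cols <- scope_columns(scope)
  keep <- !is.na(summaries$sensitivity) &
    summaries$sensitivity >= min_sensitivity
  if (!any(keep))
    stop_posthocsim(sprintf("no cells with sensitivity >= %.3f", min_sensitivity),
                    "empty_bin_error")
  num <- sum(summaries[[cols["num"]]][keep])
  den <- sum(summaries[[cols["den"]]][keep])
  structure(list(rate = if (den > 0L) num / den else NA_real_,
                 n_cells = sum(keep), n_pooled = den,
                 power_target = min_sensitivity, window = NA_real_,
                 scope = scope),
            class = "power_bin")
}

#' Per-cell effect-size inflation against sensitivity
#'
#' Extracts, for every cell with at least one detected true effect, the pair
#' (sensitivity, mean effect-size inflation among detected true effects),
#' ordered by sensitivity — the raw material of the winner's-curse curve.
#'
#' @param summaries Data frame of [summarize_setting()] rows.
#' @return Data frame with columns `cell_id`, `sensitivity`,
#'   `mean_delta_effect`, `n_true_positive`, ordered by sensitivity.
#' @export
delta_effect_table <- function(summaries) {
  keep <- !is.na(summaries$mean_delta_effect) & summaries$n_true_positive > 0L
  out <- summaries[keep, c("cell_id", "sensitivity", "mean_delta_effect",
                           "n_true_positive")]
  out <- out[order(out$sensitivity), ]
  rownames(out) <- NULL
  out
}
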