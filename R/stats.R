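#' 2x2 group-by-time repeated-measures interaction test
#'
#' Tests the group-by-time interaction of a two-arm pre/post trial. For this
#' design the repeated-measures interaction F is algebraically the square of
#' the pooled two-sample t statistic on per-subject change scores
#' (post - pre), with 1 and 2n - 2 degrees of freedom, and that closed form is
#' what is computed here. The estimated interaction effect `beta_hat` is the
#' difference in mean change between arms (active minus control), i.e. the
#' interaction coefficient of the 2x2 model under standard coding.
#'
#' The q-value slot is returned as `NA`; it is filled in at the batch level by
#' [bh_fdr()] across the replicates that form one FDR family.
#'
#' @param trial A [trial_data()] object with n >= 2 per arm.
#' @return An object of class `interaction_result`: a list with `f_stat`,
#'   `p_value`, `q_value` (`NA` here), `beta_hat`, `df_num` (1) and `df_den`
#'   (2n - 2).
#' @section Errors: a zero pooled change-score variance (possible only with
#'   degenerate noise `w = 0`) raises a `degenerate_variance_error` carrying
#'   `sign_mean_diff`, the sign of the arm difference in mean change, for
#'   diagnostics.
#' @export
#' @examples
#' tr <- trial_data(pre_control = c(0, 0, 0), post_control = c(0, 0, 1),
#'                  pre_active = c(0, 0, 0), post_active = c(1, 1, 2))
#' interaction_test(tr)
interaction_test <- function(trial) {
  if (!inherits(trial, "trial_data"))
    stop_posthocsim("trial must be a trial_data object", "invalid_trial_error")
  n <- trial$n_per_group
  dc <- trial$post_control - trial$pre_control
  da <- trial$post_active - trial$pre_active
  mc <- sum(dc) / n
  ma <- sum(da) / n
  ss <- sum((dc - mc)^2) + sum((da - ma)^2)
  df_den <- 2L * n - 2L
  sp2 <- ss / df_den
  beta_hat <- ma - mc
  if (sp2 == 0)
    stop_posthocsim(
      "zero pooled change-score variance; interaction F undefined",
      "degenerate_variance_error", sign_mean_diff = sign(beta_hat))
  t_stat <- beta_hat / sqrt(sp2 * (2 / n))
  f_stat <- t_stat^2
  structure(list(f_stat = f_stat,
                 p_value = pf(f_stat, 1, df_den, lower.tail = FALSE),
                 q_value = NA_real_,
                 beta_hat = beta_hat,
                 df_num = 1L, df_den = df_den),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("<interaction_result> F(%d, %d) = %.4f, p = %.4g, beta = %.4f%s\n",
              x$df_num, x$df_den, x$f_stat, x$p_value, x$beta_hat,
              if (is.na(x$q_value)) "" else sprintf(", q = %.4g", x$q_value)))
  invisible(x)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR-adjusted p-values: `q_(i) = min over j >= i of m * p_(j) / j`,
#' capped at 1 and returned in the input order — the minimum FDR at which each
#' test would be declared significant. The adjustment is delegated to
#' [stats::p.adjust()] (`method = "BH"`) after validating the input; the FDR
#' family is whatever vector the caller passes, which in the grid pipeline is
#' the full replicate batch of one setting.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\], no `NA`.
#' @return Numeric vector of q-values, same length and order.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
bh_fdr <- function(p_values) {
  if (!is.numeric(p_values) || length(p_values) == 0)
    stop_posthocsim("p_values must be a non-empty numeric vector",
                    "invalid_probability_error")
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop_posthocsim("all p-values must lie in [0, 1]",
                    "invalid_probability_error")
  p.adjust(p_values, method = "BH")
}

#' Within-arm paired t-test on change scores
#'
#' Classical one-sample t-test of the per-subject differences (post - pre)
#' against zero, with a two-sided p-value from t(n - 1). In the simulation
#' pipeline this is the post-hoc test applied to the control arm of trials
#' whose interaction was significant; `is_decline` flags a negative mean
#' change, the "spurious decline" pattern.
#'
#' @param pre,post Numeric score vectors of equal length n >= 2.
#' @return An object of class `posthoc_result`: a list with `t_stat`,
#'   `p_value` (two-sided), `mean_change`, `df` (n - 1) and `is_decline`.
#' @section Errors: zero variance of the differences raises a
#'   `degenerate_variance_error`.
#' @export
#' @examples
#' paired_test(pre = c(1, 2, 3), post = c(0, 2, 1))
paired_test <- function(pre, post) {
  if (!is.numeric(pre) || !is.numeric(post) || length(pre) != length(post))
    stop_posthocsim("pre and post must be numeric vectors of equal length",
                    "invalid_trial_error")
  n <- length(pre)
  if (n < 2L || anyNA(pre) || anyNA(post))
    stop_posthocsim("paired test needs n >= 2 complete pairs",
                    "invalid_trial_error")
  d <- post - pre
  m <- sum(d) / n
  ssd <- sum((d - m)^2)
  if (ssd == 0)
    stop_posthocsim("zero variance of paired differences; t undefined",
                    "degenerate_variance_error", sign_mean_diff = sign(m))
  t_stat <- m / sqrt(ssd / (n - 1L) / n)
  structure(list(t_stat = t_stat,
                 p_value = 2 * pt(-abs(t_stat), n - 1L),
                 mean_change = m,
                 df = n - 1L,
                 is_decline = m < 0),
            class = "posthoc_result")
}

#' @export
print.posthoc_result <- function(x, ...) {
  cat(sprintf("<posthoc_result> t(%d) = %.4f, p = %.4g, mean change = %.4f%s\n",
              x$df, x$t_stat, x$p_value, x$mean_change,
              if (x$is_decline) " (decline)" else ""))
  invisible(x)
}
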