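#' One simulated two-arm pre/post trial
#'
#' Bundles the four score vectors of a single trial together with its truth
#' label. Scores are in z-units: pre scores are standard normal, and each post
#' score is its pre score plus `w` times fresh standard-normal noise, plus the
#' treatment effect delta in a true-effect active arm.
#'
#' @param pre_control,post_control,pre_active,post_active Numeric score
#'   vectors of identical length (the per-group sample size).
#' @param has_true_effect Logical truth label of the trial.
#' @return An object of class `trial_data`.
#' @seealso [generate_trials()], [interaction_test()], [paired_test()]
#' @export
trial_data <- function(pre_control, post_control, pre_active, post_active,
                       has_true_effect = FALSE) {
  n <- length(pre_control)
  vecs <- list(pre_control = pre_control, post_control = post_control,
               pre_active = pre_active, post_active = post_active)
  for (nm in names(vecs)) {
    v <- vecs[[nm]]
    if (!is.numeric(v) || length(v) != n || anyNA(v))
      stop_posthocsim(
        sprintf("%s must be a numeric vector of length %d without NA", nm, n),
        "invalid_trial_error")
  }
  if (n < 2L)
    stop_posthocsim("trials need at least 2 subjects per arm", "invalid_trial_error")
  structure(c(vecs, list(has_true_effect = isTRUE(has_true_effect),
                         n_per_group = n)),
            class = "trial_data")
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf("<trial_data> n=%d per arm, true effect: %s\n",
              x$n_per_group, x$has_true_effect))
  cat(sprintf("  control change: mean %.3f | active change: mean %.3f\n",
              mean(x$post_control - x$pre_control),
              mean(x$post_active - x$pre_active)))
  invisible(x)
}

# Draw all randomness for one setting in a fixed order, so that the
# trial-level view (generate_trials) and the vectorized batch view
# (simulate_cell) are bit-identical. Order within the seeded stream:
#   1. permutation assigning the round(truth_fraction * n_reps) true labels
#   2. pre_control, 3. noise_control, 4. pre_active, 5. noise_active
# each as an n x n_reps matrix drawn column-major.
draw_raw <- function(setting) {
  stopifnot(inherits(setting, "setting_spec"))
  n <- setting$n_per_group
  R <- setting$n_reps
  set.seed(setting$seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  truth <- logical(R)
  truth[sample.int(R)[seq_len(setting$n_true)]] <- TRUE
  list(truth = truth,
       pre_control = matrix(stats::rnorm(n * R), n, R),
       eps_control = matrix(stats::rnorm(n * R), n, R),
       pre_active = matrix(stats::rnorm(n * R), n, R),
       eps_active = matrix(stats::rnorm(n * R), n, R))
}

# Materialised pre/post view of one setting (reference semantics for the
# C++ batch kernel, which reproduces these scores bit for bit).
draw_cell <- function(setting) {
  r <- draw_raw(setting)
  w <- setting$retest_weight
  post_c <- r$pre_control + w * r$eps_control
  post_a <- r$pre_active + w * r$eps_active
  if (setting$n_true > 0L && setting$effect_size != 0) {
    shift <- setting$effect_size * r$truth  # recycles along columns
    post_a <- post_a + rep(shift, each = setting$n_per_group)
  }
  list(truth = r$truth, pre_control = r$pre_control, post_control = post_c,
       pre_active = r$pre_active, post_active = post_a)
}

#' Generate the replicate trials of one setting
#'
#' Materialises every replicate of a setting as a list of [trial_data()]
#' objects. Generation is fully determined by the setting's seed; the
#' vectorized [simulate_cell()] consumes the identical random stream, so the
#' two views agree trial by trial. Exactly
#' `round(truth_fraction * n_reps)` replicates carry a true effect; which
#' ones is decided by a seeded permutation of the replicate indices.
#'
#' Intended for inspection and for small settings; for full grid runs use
#' [simulate_cell()], which never materialises per-trial objects.
#'
#' @param setting A [setting_spec()].
#' @return A list of `n_reps` `trial_data` objects.
#' @export
#' @examples
#' s <- setting_spec(5, 0.7, 0.3, n_reps = 4, truth_fraction = 0.5, seed = 11)
#' trials <- generate_trials(s)
#' sum(vapply(trials, `[[`, logical(1), "has_true_effect"))
generate_trials <- function(setting) {
  if (!inherits(setting, "setting_spec"))
    stop_posthocsim("setting must be a setting_spec", "invalid_setting_error")
  d <- draw_cell(setting)
  lapply(seq_len(setting$n_reps), function(j) {
    trial_data(pre_control = d$pre_control[, j],
               post_control = d$post_control[, j],
               pre_active = d$pre_active[, j],
               post_active = d$post_active[, j],
               has_true_effect = d$truth[j])
  })
}

#' Simulate one setting and test every replicate (vectorized)
#'
#' Draws all replicates of a setting as one batch and applies the full
#' per-trial analysis in closed form: the 2x2 group-by-time repeated-measures
#' interaction test on change scores, Benjamini-Hochberg q-values across the
#' setting's replicates (the FDR family is the setting's batch, mirroring one
#' brain-wide map of regions per design), and the within-control paired
#' t-test. Results are bit-identical to running [interaction_test()] and
#' [paired_test()] on each trial from [generate_trials()].
#'
#' Replicates with zero pooled change-score variance (possible only at
#' `retest_weight = 0`) are flagged `degenerate` and carry `NA` statistics.
#'
#' @param setting A [setting_spec()].
#' @return A data frame with one row per replicate and columns
#'   `replicate_id`, `has_true_effect`, `f_stat`, `p_value`, `q_value`,
#'   `beta_hat`, `control_t`, `control_p`, `control_mean_change`,
#'   `degenerate`.
#' @seealso [summarize_setting()] for turning this into per-setting rates.
#' @export
#' @examples
#' s <- setting_spec(10, 0.5, 0.5, n_reps = 200, seed = 3)
#' res <- simulate_cell(s)
#' mean(res$q_value < 0.05)
simulate_cell <- function(setting) {
  if (!inherits(setting, "setting_spec"))
    stop_posthocsim("setting must be a setting_spec", "invalid_setting_error")
  n <- setting$n_per_group
  r <- draw_raw(setting)
  w <- setting$retest_weight
  shift <- if (setting$n_true > 0L && setting$effect_size != 0)
    setting$effect_size * r$truth else numeric(0)
  ctl <- .cell_moments(r$pre_control, r$eps_control, w, numeric(0))
  act <- .cell_moments(r$pre_active, r$eps_active, w, shift)
  mc <- ctl$mean_change
  ma <- act$mean_change
  ss_c <- ctl$ss_change
  ss_a <- act$ss_change
  d <- list(truth = r$truth)
  df_den <- 2L * n - 2L
  sp2 <- (ss_c + ss_a) / df_den
  degenerate <- sp2 == 0
  beta_hat <- ma - mc
  t2 <- beta_hat / sqrt(sp2 * (2 / n))
  f_stat <- t2^2
  p_value <- pf(f_stat, 1, df_den, lower.tail = FALSE)
  f_stat[degenerate] <- NA_real_
  p_value[degenerate] <- NA_real_
  var_c <- ss_c / (n - 1L)
  control_t <- mc / sqrt(var_c / n)
  control_p <- 2 * pt(-abs(control_t), n - 1L)
  deg_c <- var_c == 0
  control_t[deg_c] <- NA_real_
  control_p[deg_c] <- NA_real_
  q_value <- rep(NA_real_, setting$n_reps)
  ok <- !is.na(p_value)
  q_value[ok] <- p.adjust(p_value[ok], method = "BH")
  data.frame(replicate_id = seq_len(setting$n_reps),
             has_true_effect = d$truth,
             f_stat = f_stat, p_value = p_value, q_value = q_value,
             beta_hat = beta_hat,
             control_t = control_t, control_p = control_p,
             control_mean_change = mc,
             degenerate = degenerate | deg_c)
}

#' Dump the trials of one setting as tidy CSV
#'
#' Writes one row per subject, arm and replicate with columns `cell_id`,
#' `replicate_id`, `arm`, `subject_index`, `pre`, `post`, `has_true_effect`.
#' Mostly useful for auditing small settings; a full published-scale cell
#' would be 20 million rows.
#'
#' @param setting A [setting_spec()].
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_trials_csv <- function(setting, path) {
  d <- draw_cell(setting)
  n <- setting$n_per_group
  R <- setting$n_reps
  rep_id <- rep(seq_len(R), each = n)
  subj <- rep(seq_len(n), times = R)
  out <- rbind(
    data.frame(cell_id = setting$cell_id, replicate_id = rep_id,
               arm = "control", subject_index = subj,
               pre = as.vector(d$pre_control), post = as.vector(d$post_control),
               has_true_effect = d$truth[rep_id]),
    data.frame(cell_id = setting$cell_id, replicate_id = rep_id,
               arm = "active", subject_index = subj,
               pre = as.vector(d$pre_active), post = as.vector(d$post_active),
               has_true_effect = d$truth[rep_id]))
  out <- out[order(out$replicate_id, out$arm, out$subject_index), ]
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
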