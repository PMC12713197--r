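# Independent oracles the implementation is checked against.

# Brute-force 2 (group) x 2 (time) repeated-measures interaction F:
# full long-format model with a subject error stratum, solved by aov().
rm_interaction_oracle <- function(trial) {
  n <- trial$n_per_group
  long <- data.frame(
    score = c(trial$pre_control, trial$post_control,
              trial$pre_active, trial$post_active),
    group = factor(rep(c("control", "active"), each = 2 * n)),
    time = factor(rep(rep(c("pre", "post"), each = n), times = 2)),
    subject = factor(c(rep(seq_len(n), 2), rep(n + seq_len(n), 2))))
  fit <- stats::aov(score ~ group * time + Error(subject), data = long)
  tab <- summary(fit)[["Error: Within"]][[1]]
  i <- grep("group:time", rownames(tab))
  list(f = tab[i, "F value"], p = tab[i, "Pr(>F)"],
       df_den = tab["Residuals", "Df"])
}

# Literal step-up enumeration of Benjamini-Hochberg adjusted values:
# q_(i) = min over j >= i of m * p_(j) / j, capped at 1, input order kept.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m * ps[j] / j)
    q_sorted[i] <- min(best, 1)
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

random_trial <- function(n = sample(3:12, 1), w = runif(1, 0.1, 1),
                         delta = runif(1, 0, 1), true_effect = runif(1) < 0.5) {
  pre_c <- rnorm(n); pre_a <- rnorm(n)
  trial_data(pre_control = pre_c, post_control = pre_c + w * rnorm(n),
             pre_active = pre_a,
             post_active = pre_a + w * rnorm(n) + if (true_effect) delta else 0,
             has_true_effect = true_effect)
}

# Build a fake per-replicate results frame with prescribed significance and
# post-hoc outcomes, for testing the counting logic in isolation.
fake_results <- function(truth, sig, control_sig, control_decline = NULL,
                         beta = NULL, q_threshold = 0.05, alpha = 0.05) {
  R <- length(truth)
  if (is.null(control_decline)) control_decline <- control_sig
  if (is.null(beta)) beta <- rep(0, R)
  data.frame(replicate_id = seq_len(R),
             has_true_effect = truth,
             f_stat = rep(1, R), p_value = rep(0.5, R),
             q_value = ifelse(sig, q_threshold / 2, 2 * q_threshold),
             beta_hat = beta,
             control_t = rep(0, R),
             control_p = ifelse(control_sig, alpha / 2, 2 * alpha),
             control_mean_change = ifelse(control_decline, -0.5, 0.5),
             degenerate = rep(FALSE, R))
}
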