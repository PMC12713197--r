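test_that("interaction test matches the hand-derived 12-observation example", {
  tr <- trial_data(pre_control = c(0, 0, 0), post_control = c(0, 0, 1),
                   pre_active = c(0, 0, 0), post_active = c(1, 1, 2))
  res <- interaction_test(tr)
  expect_equal(res$beta_hat, 1.0)
  expect_equal(res$f_stat, 4.5)
  expect_equal(sqrt(res$f_stat), 2.1213, tolerance = 1e-4)
  expect_identical(res$df_num, 1L)
  expect_identical(res$df_den, 4L)
  oracle <- rm_interaction_oracle(tr)
  expect_equal(res$f_stat, oracle$f)
  expect_equal(res$p_value, oracle$p)
  expect_identical(res$df_den, as.integer(oracle$df_den))
})

test_that("interaction F equals the brute-force repeated-measures F", {
  set.seed(101)
  for (i in 1:1000) {
    tr <- random_trial()
    res <- interaction_test(tr)
    oracle <- rm_interaction_oracle(tr)
    expect_equal(res$f_stat, oracle$f, tolerance = 1e-8)
    expect_equal(res$p_value, oracle$p, tolerance = 1e-10)
  }
})

test_that("interaction test is label-symmetric and location-invariant", {
  set.seed(55)
  tr <- random_trial(n = 6)
  res <- interaction_test(tr)
  swapped <- trial_data(pre_control = tr$pre_active,
                        post_control = tr$post_active,
                        pre_active = tr$pre_control,
                        post_active = tr$post_control)
  res_sw <- interaction_test(swapped)
  expect_equal(res_sw$beta_hat, -res$beta_hat)
  expect_equal(res_sw$f_stat, res$f_stat)
  expect_equal(res_sw$p_value, res$p_value)
  shifted <- trial_data(pre_control = tr$pre_control + 5,
                        post_control = tr$post_control + 5,
                        pre_active = tr$pre_active + 5,
                        post_active = tr$post_active + 5)
  res_sh <- interaction_test(shifted)
  expect_equal(res_sh$f_stat, res$f_stat)
  expect_equal(res_sh$beta_hat, res$beta_hat)
})

test_that("zero pooled change variance raises a diagnosable error", {
  tr <- trial_data(pre_control = c(0, 0, 0), post_control = c(1, 1, 1),
                   pre_active = c(0, 0, 0), post_active = c(3, 3, 3))
  err <- tryCatch(interaction_test(tr), error = identity)
  expect_s3_class(err, "degenerate_variance_error")
  expect_identical(err$sign_mean_diff, 1)
})

test_that("BH q-values match literal step-up enumeration", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p_tied <- rep(0.2, 5)
  expect_equal(bh_fdr(p_tied), p_tied)
  set.seed(42)
  for (i in 1:25) {
    p <- runif(sample(1:30, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in p
  }
  expect_error(bh_fdr(c(0.1, 1.2)), class = "invalid_probability_error")
  expect_error(bh_fdr(c(0.1, NA)), class = "invalid_probability_error")
  expect_error(bh_fdr(numeric(0)), class = "invalid_probability_error")
})

test_that("paired test reproduces the closed-form t(2) example", {
  res <- paired_test(pre = c(1, 1, 2), post = c(0, 1, 0))  # diffs -1, 0, -2
  expect_equal(res$t_stat, -sqrt(3), tolerance = 1e-10)
  expect_identical(res$df, 2L)
  # two-sided p via the df = 2 closed form P(T <= t) = 1/2 + t/(2 sqrt(2+t^2))
  t <- -sqrt(3)
  expect_equal(res$p_value, 2 * (1 / 2 + t / (2 * sqrt(2 + t^2))))
  expect_equal(res$p_value, 0.2254, tolerance = 1e-4)
  expect_true(res$is_decline)
  ref <- t.test(c(0, 1, 0), c(1, 1, 2), paired = TRUE)
  expect_equal(res$t_stat, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
})

test_that("paired test handles degenerate and trivial inputs", {
  same <- paired_test(pre = c(1, 2, 3), post = c(3, 2, 4))
  expect_equal(sign(same$t_stat), sign(same$mean_change))
  expect_gt(same$t_stat, 0)
  res0 <- paired_test(pre = c(1, 2, 3), post = c(3, 1, 2))  # mean change 0
  expect_equal(res0$t_stat, 0)
  expect_equal(res0$p_value, 1)
  expect_error(paired_test(c(1, 2, 3), c(2, 3, 4)),
               class = "degenerate_variance_error")
  expect_error(paired_test(1, 2), class = "invalid_trial_error")
})

test_that("null interaction p-values are uniform", {
  s <- setting_spec(10, 0, 0.5, n_reps = 100000, truth_fraction = 0, seed = 77)
  res <- simulate_cell(s)
  ks <- suppressWarnings(ks.test(res$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.01)
})

test_that("rejection rate matches the analytic noncentral-t power", {
  # at uncorrected level alpha the interaction test is the two-sample t on
  # change scores: power follows from the noncentral t with effect delta/w
  cases <- list(c(n = 20, delta = 0.3, w = 0.6),
                c(n = 10, delta = 0.5, w = 0.5),
                c(n = 40, delta = 0.2, w = 0.8))
  for (cs in cases) {
    R <- 20000
    s <- setting_spec(cs["n"], cs["delta"], cs["w"], n_reps = R,
                      truth_fraction = 1, seed = 13)
    res <- simulate_cell(s)
    emp <- mean(res$p_value < 0.05)
    ana <- power.t.test(n = cs["n"], delta = cs["delta"], sd = cs["w"],
                        sig.level = 0.05)$power
    expect_lt(abs(emp - ana), 3 * sqrt(ana * (1 - ana) / R))
  }
})
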