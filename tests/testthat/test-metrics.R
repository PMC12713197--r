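test_that("setting summary counts a hand-built batch correctly", {
  # 10 replicates: 3 true (2 detected), 7 null (1 significant); of the 3
  # significant replicates exactly 1 is control-significant (a null one)
  truth <- c(TRUE, TRUE, TRUE, rep(FALSE, 7))
  sig <- c(TRUE, TRUE, FALSE, TRUE, rep(FALSE, 6))
  control_sig <- c(FALSE, FALSE, FALSE, TRUE, rep(FALSE, 6))
  res <- fake_results(truth, sig, control_sig, beta = rep(0.9, 10))
  spec <- setting_spec(5, 0.5, 0.5, n_reps = 10, truth_fraction = 0.3)
  sm <- summarize_setting(res, spec)
  expect_equal(sm$sensitivity, 2 / 3)
  expect_equal(sm$fpr_interaction, 1 / 7)
  expect_equal(sm$control_fp_rate, 1 / 3)
  expect_equal(sm$control_fp_rate_true, 0)      # neither detected true is
  expect_identical(sm$n_sig, 3L)
  expect_identical(sm$n_true_positive, 2L)
  expect_equal(sm$mean_delta_effect, 0.9 - 0.5)
  expect_identical(sm$n_true + sm$n_null, 10L)
})

test_that("empty denominators are missing, never zero", {
  truth <- c(TRUE, rep(FALSE, 9))
  res <- fake_results(truth, sig = rep(FALSE, 10), control_sig = rep(FALSE, 10))
  spec <- setting_spec(5, 0.5, 0.5, n_reps = 10, truth_fraction = 0.1)
  sm <- summarize_setting(res, spec)
  expect_equal(sm$sensitivity, 0)
  expect_equal(sm$fpr_interaction, 0)
  expect_true(is.na(sm$control_fp_rate))
  expect_true(is.na(sm$control_fp_rate_true))
  expect_true(is.na(sm$mean_delta_effect))
  expect_true(is.na(sm$mean_control_change_sig))
})

test_that("summary rejects inconsistent inputs", {
  spec <- setting_spec(5, 0.5, 0.5, n_reps = 10, truth_fraction = 0.3)
  res <- fake_results(c(TRUE, rep(FALSE, 8)), rep(FALSE, 9), rep(FALSE, 9))
  expect_error(summarize_setting(res, spec), class = "inconsistency_error")
  res10 <- fake_results(c(TRUE, rep(FALSE, 9)), rep(FALSE, 10), rep(FALSE, 10))
  expect_error(summarize_setting(res10, spec), class = "inconsistency_error")
})

test_that("degenerate replicates are dropped with a warning", {
  truth <- c(TRUE, TRUE, rep(FALSE, 8))
  res <- fake_results(truth, sig = c(TRUE, rep(FALSE, 9)),
                      control_sig = rep(FALSE, 10))
  res$degenerate[10] <- TRUE
  res$q_value[10] <- NA
  spec <- setting_spec(5, 0.5, 0, n_reps = 10, truth_fraction = 0.2)
  expect_warning(sm <- summarize_setting(res, spec), "degenerate")
  expect_identical(sm$n_degenerate, 1L)
  expect_identical(sm$n_null, 7L)
})

test_that("power-bin pooling is replicate-level and errors on empty bins", {
  specs <- list(setting_spec(5, 0.2, 0.5, 100, truth_fraction = 0.5, seed = 1),
                setting_spec(5, 0.3, 0.5, 100, truth_fraction = 0.5, seed = 2))
  # cell A: sensitivity 0.20 (10/50), 4 of 10 true positives control-sig
  resA <- fake_results(rep(c(TRUE, FALSE), each = 50),
                       sig = c(rep(TRUE, 10), rep(FALSE, 90)),
                       control_sig = c(rep(TRUE, 4), rep(FALSE, 96)))
  # cell B: sensitivity 0.20, 1 of 10 true positives control-sig
  resB <- fake_results(rep(c(TRUE, FALSE), each = 50),
                       sig = c(rep(TRUE, 10), rep(FALSE, 90)),
                       control_sig = c(rep(TRUE, 1), rep(FALSE, 99)))
  sm <- rbind(summarize_setting(resA, specs[[1]]),
              summarize_setting(resB, specs[[2]]))
  bin <- pool_by_power(sm, 0.2, window = 0.025, scope = "true_significant")
  expect_equal(bin$rate, 5 / 20)  # pooled counts, not averaged cell rates
  expect_identical(bin$n_cells, 2L)
  # a single-member bin equals that cell's own rate
  single <- pool_by_power(sm[1, ], 0.2, window = 0.025,
                          scope = "true_significant")
  expect_equal(single$rate, sm$control_fp_rate_true[1])
  expect_error(pool_by_power(sm, 0.9, window = 0.025),
               class = "empty_bin_error")
  above <- pool_above_power(sm, 0.1)
  expect_equal(above$rate, 5 / 20)
  expect_error(pool_above_power(sm, 0.99), class = "empty_bin_error")
})

test_that("delta-effect table keeps detected cells ordered by sensitivity", {
  specs <- list(setting_spec(5, 0.4, 0.5, 10, truth_fraction = 0.5, seed = 1),
                setting_spec(5, 0.6, 0.5, 10, truth_fraction = 0.5, seed = 2))
  # cell A: 5 true, a single detection with beta 1.3 against delta 0.4
  resA <- fake_results(c(rep(TRUE, 5), rep(FALSE, 5)),
                       sig = c(TRUE, rep(FALSE, 9)),
                       control_sig = rep(FALSE, 10),
                       beta = c(1.3, rep(0, 9)))
  # all five true replicates detected with beta exactly delta
  resB <- fake_results(rep(c(TRUE, FALSE), 5),
                       sig = rep(c(TRUE, FALSE), 5),
                       control_sig = rep(FALSE, 10),
                       beta = rep(c(0.6, 0), 5))
  sm <- rbind(summarize_setting(resA, specs[[1]]),
              summarize_setting(resB, specs[[2]]))
  tab <- delta_effect_table(sm)
  expect_identical(nrow(tab), 2L)
  expect_equal(tab$sensitivity, sort(tab$sensitivity))
  expect_equal(tab$mean_delta_effect[tab$sensitivity == 0.2], 0.9)
  expect_equal(tab$mean_delta_effect[tab$sensitivity == 1], 0)
})

test_that("selection on the interaction drags the control mean negative", {
  # a low-powered cell with a real effect: among replicates selected by the
  # interaction test, the control-arm mean change is biased negative, while
  # the unconditional control mean stays at zero (Berkson conditioning)
  s <- setting_spec(20, 0.5, 0.7, n_reps = 60000, truth_fraction = 0.1,
                    seed = 12)
  res <- simulate_cell(s)
  sm <- summarize_setting(res, s)
  expect_lt(sm$sensitivity, 0.2)
  sig <- res$q_value < s$q_threshold
  se_cond <- sd(res$control_mean_change[sig]) / sqrt(sum(sig))
  se_all <- sd(res$control_mean_change) / sqrt(nrow(res))
  expect_lt(sm$mean_control_change_sig + 3 * se_cond, 0)
  expect_lt(sm$mean_control_change_sig + 3 * (se_cond + se_all),
            mean(res$control_mean_change))
})
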