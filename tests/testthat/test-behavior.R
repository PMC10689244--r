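test_that("value updates follow the outcome-dependent learning and forgetting rules", {
  p <- list(alpha_rew = 0.4, alpha_unr = 0.2, omega = 0.25)
  up <- rl_update(0.5, 0.8, 1, p)
  expect_equal(up$Q_ch, 0.7)
  expect_equal(up$Q_unch, 0.6)
  up2 <- rl_update(0.5, 0.8, 0, p)
  expect_equal(up2$Q_ch, 0.4)
  expect_error(rl_update(0.5, 0.5, 1, list(alpha_rew = 1.2, alpha_unr = 0,
                                           omega = 0)), "rates")
  # fixed points: constant reward drives Q to 1 geometrically at 1-alpha
  q <- 0.2
  for (i in 1:5) q <- rl_update(q, 0, 1, p)$Q_ch
  expect_equal(1 - q, (1 - 0.2) * (1 - 0.4)^5)
  q <- 0.9
  for (i in 1:5) q <- rl_update(q, 0, 0, p)$Q_ch
  expect_equal(q, 0.9 * (1 - 0.2)^5)
})

test_that("the logistic policy reproduces hand values and alternation", {
  pm <- list(beta_dq = 2, beta0 = 0)
  expect_equal(choice_prob(0.5, 0.5, 0, pm, "mouse"), 0.5)
  expect_equal(choice_prob(0.75, 0.25, 0, pm, "mouse"),
               1 / (1 + exp(-1)))
  pd <- list(beta_dq = 2, beta0 = 0, beta_c = -0.5)
  expect_lt(choice_prob(0.5, 0.5, +1, pd, "deepRL"), 0.5)
  expect_gt(choice_prob(0.5, 0.5, -1, pd, "deepRL"), 0.5)
})

test_that("history regression recovers a generating kernel and nulls", {
  truth <- c(0.8, 0.4, 0.2, 0.1, 0.05)
  ses <- gen_kernel_behavior(truth, rep(0, 5), 0,
                             task_cfg = task_config(n_trials = 5000),
                             seed = 71)
  hf <- fit_history_logit(ses)
  expect_true(hf$converged)
  expect_true(all(abs(hf$beta_r - truth) < 0.2))
  expect_gt(cor(hf$beta_r, truth), 0.95)
  expect_true(all(abs(hf$beta_c) < 0.2))
  # reward-independent random chooser: all weights near zero
  set.seed(72)
  rnd <- mk_session(choice = sample(c("L", "R"), 3000, replace = TRUE),
                    reward = rbinom(3000, 1, 0.3), A_L = 0.6, A_R = 0.1)
  h0 <- fit_history_logit(rnd)
  expect_true(all(abs(c(h0$beta_r, h0$beta_c, h0$beta_bias)) < 0.15))
  # all-left behavior is degenerate
  expect_error(fit_history_logit(
    mk_session(rep("L", 200), rbinom(200, 1, 0.5), 0.6, 0.1)),
    "separation")
})

test_that("summed weights, dependence magnitude and policy axes are consistent", {
  fit <- structure(list(beta_r = c(0.5, -0.2, 0.1, 0, 0),
                        beta_c = c(-0.3, 0, 0, 0, 0.1), beta_bias = 0.2),
                   class = "history_fit")
  sw <- summed_history_weights(fit)
  expect_equal(unname(sw), c(0.4, -0.2))
  expect_equal(reward_history_dependence(fit), 0.8)
  expect_gte(reward_history_dependence(fit), abs(sw[["sum_r"]]))
  ax <- policy_axes(fit)
  expect_equal(axis_angle(ax$p_r, ax$p_r)$degrees, 0)
  expect_equal(axis_angle(ax$p_r, -ax$p_r)$degrees, 180)
  expect_equal(axis_angle(c(1, 0, 0, 0, 0), c(0, 1, 0, 0, 0))$degrees, 90)
  expect_equal(axis_angle(ax$p_r, 2 * ax$p_r)$cosine, 1)
  expect_error(axis_angle(rep(0, 5), ax$p_r), "zero vector")
})

test_that("the split regression needs both classes and covers every control row", {
  set.seed(80)
  tc <- task_config(n_trials = 300)
  ses <- gen_behavior_session(teacher_spec(), tc)$session
  expect_error(fit_history_logit_split(ses), "both control and inactivation")
  # 13% inactivation: covering rule gives ceiling(n_ctrl / n_opto) iterations
  d <- metabandit:::history_design(ses)
  flags <- rep(FALSE, 300)
  flags[d$trial_idx[seq(1, length(d$trial_idx), by = 8)]] <- TRUE
  ses$trials$inactivation <- flags
  n_opto <- sum(flags[d$trial_idx])
  n_ctrl <- length(d$trial_idx) - n_opto
  fit <- suppressWarnings(fit_history_logit_split(ses))
  expect_equal(fit$n_iter, ceiling(n_ctrl / n_opto))
  expect_length(fit$ctrl$beta_r, 5L)
  expect_length(fit$opto$beta_c, 5L)
  expect_gte(fit$abs_bias_ctrl, 0)
})

test_that("split weights agree between exchangeable trial classes", {
  set.seed(81)
  tc <- task_config(n_trials = 500)
  ses <- gen_behavior_session(teacher_spec(), tc)$session
  # flags assigned with the real scheduler but behavior is identical
  ses$trials$inactivation <- gen_inactivation_schedule(500)
  fit <- suppressWarnings(fit_history_logit_split(ses))
  expect_lt(abs(sum(fit$ctrl$beta_r) - sum(fit$opto$beta_r)), 0.6)
})

test_that("the value-model fit recovers teacher parameters on synthetic sessions", {
  set.seed(90)
  errs <- sapply(1:2, function(i) {
    g <- gen_behavior_session(teacher_spec(), task_config())
    f <- fit_rl_model(g$session, "mouse")
    abs(unlist(f$params[c("alpha_rew", "alpha_unr", "omega")]) -
          c(0.6, 0.2, 0.1))
  })
  # best-of-2 guards against the occasional local optimum on one session
  expect_true(all(apply(errs, 1, min) < 0.15))
})

test_that("value series stay in range and the penalty limit flattens the policy", {
  g <- gen_behavior_session(teacher_spec(), task_config(n_trials = 200),
                            seed = 91)
  expect_true(all(g$values$Q_L >= 0 & g$values$Q_L <= 1))
  expect_true(all(g$values$Q_R >= 0 & g$values$Q_R <= 1))
  expect_true(all(abs(g$values$dQ) <= 1))
  expect_true(all(g$values$sumQ >= 0 & g$values$sumQ <= 2))
  f <- fit_rl_model(g$session, "mouse", lambda_grid = 1e6, n_folds = 5,
                    n_starts = 3, min_trials = 100)
  expect_true(all(abs(f$values$P_L - 0.5) < 0.05))
  expect_true(all(f$values$Q_L >= 0 & f$values$Q_L <= 1))
})

test_that("the fitted value model beats a bias-only account on held-out data", {
  g <- gen_behavior_session(teacher_spec(), task_config(n_trials = 600),
                            seed = 92)
  cc <- metabandit:::session_choice_codes(g$session)
  half <- seq_len(300)
  test_mask <- as.integer(seq_along(cc$choices) > 300)
  f <- fit_rl_model(g$session, "mouse")
  par <- unlist(f$params)
  nll_model <- metabandit:::rl_negloglik_cpp(par, cc$choices, cc$rewards,
                                             FALSE, 0.5, 0, test_mask)
  p_left <- mean(cc$choices[half] == 1)
  n_test_l <- sum(cc$choices[-half] == 1)
  n_test <- sum(cc$choices[-half] != 0)
  nll_bias <- -(n_test_l * log(p_left) + (n_test - n_test_l) * log(1 - p_left))
  expect_lt(nll_model, nll_bias)
})

test_that("policy axes stay put for a fixed teacher kernel across sessions", {
  set.seed(95)
  kern <- c(1.2, 0.6, 0.3, 0.15, 0.08)
  axes <- lapply(1:3, function(i) {
    s <- gen_kernel_behavior(kern, rep(0, 5), 0,
                             task_cfg = task_config(n_trials = 2000))
    policy_axes(fit_history_logit(s))$p_r
  })
  cs <- c(axis_angle(axes[[1]], axes[[2]])$cosine,
          axis_angle(axes[[2]], axes[[3]])$cosine)
  expect_true(all(cs > 0.9))
})
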