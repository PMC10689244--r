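test_that("the recurrent step is a bounded tanh map", {
  Wx <- matrix(0, 2, 3); Wy <- matrix(0, 2, 2)
  expect_equal(recurrent_step(Wx, Wy, c(0, 0), runif(3), runif(2)),
               c(0, 0))
  expect_equal(recurrent_step(Wx, Wy, c(1, 1), rnorm(3), rnorm(2)),
               rep(tanh(1), 2))
  set.seed(1)
  y <- recurrent_step(matrix(rnorm(6), 2), matrix(rnorm(4), 2),
                      rnorm(2), rnorm(3) * 10, rnorm(2))
  expect_true(all(abs(y) < 1))
  expect_error(recurrent_step(Wx, Wy, c(0, 0), c(Inf, 1, 1), c(0, 0)),
               "non-finite")
})

test_that("a session presents inputs only at trial-first steps and reproduces under a seed", {
  set.seed(20)
  p <- agent_params_init()
  cfg <- train_config(trials_per_session = 40L)
  set.seed(21)
  r1 <- run_session(p, task_config(), cfg)
  set.seed(21)
  r2 <- run_session(p, task_config(), cfg)
  expect_identical(r1$session$trials, r2$session$trials)
  expect_identical(r1$rollout$ya, r2$rollout$ya)
  ro <- r1$rollout
  # first trial: all-zero input at every step (no previous choice)
  expect_true(all(ro$X[, seq_len(ro$steps_per_trial[1])] == 0))
  # inputs are nonzero only at the first step of later trials
  firsts <- cumsum(c(1, head(ro$steps_per_trial, -1)))
  nonzero_cols <- which(colSums(abs(ro$X)) > 0)
  expect_true(all(nonzero_cols %in% firsts))
  # the input at trial t reports trial t-1's choice and outcome
  t_prev <- 5L
  x <- ro$X[, firsts[t_prev + 1L]]
  expect_equal(x[1], ro$rewards_step[ro$action_steps[t_prev]])
  expect_equal(x[2], as.numeric(ro$actions[t_prev] == 1L))
  expect_equal(x[3], as.numeric(ro$actions[t_prev] == 2L))
})

test_that("an untrained agent is near chance on high-side choices", {
  set.seed(30)
  p <- agent_params_init()
  r <- run_session(p, task_config(), train_config())
  expect_lt(abs(p_choose_high(r$session) - 0.5), 0.1)
})

test_that("segment losses reproduce hand-computed A2C quantities", {
  n <- 2L
  zero <- agent_params_init(n_units = n)
  for (nm in names(zero)) zero[[nm]][] <- 0
  # single step, action taken, fixed A = 1, R = 1:
  # pi = 0.5 -> L_pi = -ln(0.5) * 1 - 0.5 * ln 2;  L_v = 0.01 * 0.5 * 1
  out <- metabandit:::a2c_segment_cpp(
    zero, matrix(0, 3, 1), numeric(n), numeric(n), 1L, 1L, 0, 0,
    gamma = 0.5, beta_e = 0.5, beta_v = 0.01, want_grads = FALSE,
    A_fixed = 1, R_fixed = 1)
  expect_equal(out$loss_pi, -log(0.5) - 0.5 * log(2), tolerance = 1e-12)
  expect_equal(out$loss_v, 0.005, tolerance = 1e-12)
  # n-step return: rewards (1, 0), V two steps ahead = 0.2, gamma = 0.5
  # -> R_1 = 1 + 0.5*0 + 0.25*0.2 = 1.05; with V(s_t) = 0, delta = 1.05
  out2 <- metabandit:::a2c_segment_cpp(
    zero, matrix(0, 3, 2), numeric(n), numeric(n), 2L, 1L, c(1, 0),
    vboot = 0.2, gamma = 0.5, beta_e = 0.5, beta_v = 0.01,
    want_grads = FALSE)
  expect_equal(as.numeric(out2$returns), c(1.05, 0.1), tolerance = 1e-12)
  expect_equal(as.numeric(out2$advantages), 0.1, tolerance = 1e-12)
})

test_that("BPTT gradients match central finite differences on a toy network", {
  expect_lt(grad_check_worst_relerr(n_units = 2L, T = 9L), 1e-5)
})

test_that("weight updates happen only at session boundaries and vanish at zero learning rate", {
  set.seed(40)
  p <- agent_params_init()
  cfg0 <- train_config(trials_per_session = 30L, learning_rate = 0)
  r <- run_session(p, task_config(), cfg0)
  upd <- session_update(p, r$rollout, cfg0)
  expect_identical(upd$params, p)
  cfg1 <- train_config(trials_per_session = 30L)
  upd1 <- session_update(p, r$rollout, cfg1)
  expect_false(identical(upd1$params$Wy_a, p$Wy_a))
  # averaged update mode also moves the weights
  cfg2 <- train_config(trials_per_session = 30L, update_mode = "averaged")
  upd2 <- session_update(p, r$rollout, cfg2)
  expect_false(identical(upd2$params$Wy_a, p$Wy_a))
  expect_equal(nrow(upd1$losses), ceiling(sum(r$rollout$steps_per_trial) / 50))
})

test_that("a short training run logs one record per session and keeps shapes", {
  run <- train_agent(task_config(), train_config(n_sessions = 3L,
                                                 trials_per_session = 80L),
                     seed = 9)
  expect_equal(nrow(run$log), 4L) # 3 training + 1 frozen evaluation
  expect_length(run$sessions, 4L)
  expect_equal(dim(run$params$Wy_a), c(50L, 50L))
})

test_that("inactivation with zero fraction reproduces the control run exactly", {
  set.seed(50)
  p <- agent_params_init()
  cfg <- train_config(trials_per_session = 60L)
  set.seed(51)
  flags <- gen_inactivation_schedule(60L)
  ctl <- run_session(p, task_config(), cfg, keep_rollout = FALSE)
  set.seed(51)
  flags2 <- gen_inactivation_schedule(60L)
  ina <- run_session(p, task_config(), cfg,
                     inactivation = list(units = integer(0), trials = flags2),
                     keep_rollout = FALSE)
  expect_identical(ctl$session$trials$choice, ina$session$trials$choice)
  expect_identical(ctl$session$trials$reward, ina$session$trials$reward)
})

test_that("inactivated units are silent at the action-selection step", {
  set.seed(60)
  p <- agent_params_init()
  cfg <- train_config(trials_per_session = 10L)
  units <- 1:30
  r <- run_session(p, task_config(), cfg,
                   inactivation = list(units = units,
                                       trials = rep(TRUE, 10L)))
  final_steps <- r$rollout$action_steps
  expect_true(all(r$rollout$ya[1:30, final_steps] == 0))
  # untouched steps are generically nonzero
  expect_gt(mean(r$rollout$ya[1:30, -final_steps] != 0), 0.9)
})

test_that("activity extraction averages the right steps with stable unit IDs", {
  # hand-built rollout: 2 units, two trials of 4 and 5 steps
  ro <- list(ya = matrix(rep(1:9, each = 2), 2, 9) * 1.0,
             yc = matrix(rep(9:1, each = 2), 2, 9) * 1.0,
             steps_per_trial = c(4L, 5L))
  act <- extract_unit_activity(ro, "prechoice_mean3")
  # trial 1 (4 steps): mean of steps 1..3; trial 2 (5 steps): steps 6..8
  expect_equal(unname(act$activity[1, 1]), 2)
  expect_equal(unname(act$activity[2, 1]), 7)
  expect_equal(unname(act$activity[1, 3]), 8) # critic unit, steps 9,8,7
  post <- extract_unit_activity(ro, "postchoice")
  expect_equal(unname(post$activity[, 1]), c(4, 9))
  expect_identical(act$neuron_ids, c("a1", "a2", "c1", "c2"))
  zero <- list(ya = matrix(0, 2, 9), yc = matrix(0, 2, 9),
               steps_per_trial = c(4L, 5L))
  expect_true(all(extract_unit_activity(zero, "prechoice_mean3")$activity == 0))
})
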