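test_that("baiting collects and clears rewards deterministically when loaded", {
  cfg <- task_config()
  state <- bandit_state_init(cfg)
  state$baited_L <- TRUE
  st <- bait_and_step(state, "L", cfg)
  expect_identical(st$reward, 1L)
  expect_false(st$state$baited_L)
  # a none choice never collects
  state2 <- bandit_state_init(cfg)
  state2$baited_L <- TRUE; state2$baited_R <- TRUE
  st2 <- bait_and_step(state2, "none", cfg)
  expect_identical(st2$reward, 0L)
  expect_true(st2$state$baited_L && st2$state$baited_R)
})

test_that("empirical reward rates match the bait-accumulation closed form", {
  cfg <- task_config(prob_pairs = list(c(0.6, 0.1), c(0.1, 0.6)),
                     block_len_range = c(60, 80))
  set.seed(101)
  n_mc <- 20000
  # single left choice from a fresh state: rate = A_L
  r0 <- vapply(seq_len(n_mc), function(i)
    mc_episode("L", cfg)[1], integer(1))
  se0 <- sqrt(0.6 * 0.4 / n_mc)
  expect_lt(abs(mean(r0) - 0.6), 3 * se0)
  # left, two rights, then left: final left rate = 1 - (1-0.6)^3
  rk <- vapply(seq_len(n_mc), function(i)
    mc_episode(c("L", "R", "R", "L"), cfg)[4], integer(1))
  p_expect <- 1 - (1 - 0.6)^3
  sek <- sqrt(p_expect * (1 - p_expect) / n_mc)
  expect_lt(abs(mean(rk) - p_expect), 3 * sek)
})

test_that("reward conservation: a session never pays more than it baited", {
  cfg <- task_config(n_trials = 300)
  set.seed(7)
  ses <- metabandit:::play_session(
    function(t, pc, pr) sample(c("L", "R"), 1), cfg)
  tr <- ses$trials
  expect_true(all(tr$reward %in% c(0L, 1L)))
  expect_true(all(tr$reward[tr$choice == "none"] == 0))
  # each side's rewards cannot exceed opportunities: cumulative rewards on
  # a side <= number of trials (each trial sets at most one new bait/side)
  expect_lte(sum(tr$reward), nrow(tr))
})

test_that("block transitions honor range, postponement and the pair cycle", {
  cfg <- task_config()
  set.seed(11)
  st <- bandit_state_init(cfg)
  expect_true(st$scheduled_block_len >= 60 && st$scheduled_block_len <= 80)
  # below-threshold recent performance postpones the transition
  st$trials_elapsed <- st$scheduled_block_len
  st_post <- maybe_transition(st, rep(c(TRUE, FALSE), c(20, 40)), cfg)
  expect_identical(st_post$pair_idx, 1L)
  # at/above threshold it advances and resets
  st_adv <- maybe_transition(st, rep(c(TRUE, FALSE), c(30, 30)), cfg)
  expect_identical(st_adv$pair_idx, 2L)
  expect_identical(st_adv$trials_elapsed, 0L)
  expect_identical(st_adv$block, 2L)
  # before the scheduled end nothing happens regardless of performance
  st$trials_elapsed <- st$scheduled_block_len - 1L
  expect_identical(maybe_transition(st, rep(TRUE, 60), cfg)$pair_idx, 1L)
})

test_that("an always-high policy realizes exactly the scheduled block lengths", {
  cfg <- task_config(n_trials = 500)
  set.seed(13)
  # play manually so the policy can see the current probabilities
  state <- bandit_state_init(cfg)
  lens <- integer(0); cur <- state$block; count <- 0L
  recent <- logical(0)
  sched <- state$scheduled_block_len
  for (t in seq_len(2000)) {
    p <- current_probs(state, cfg)
    ch <- if (p[1] >= p[2]) "L" else "R"
    st <- bait_and_step(state, ch, cfg); state <- st$state
    recent <- tail(c(recent, TRUE), cfg$postpone_window)
    count <- count + 1L
    state <- maybe_transition(state, recent, cfg)
    if (state$block != cur) {
      lens <- c(lens, count); count <- 0L
      expect_identical(lens[length(lens)], as.integer(sched))
      sched <- state$scheduled_block_len
      cur <- state$block
    }
  }
  expect_true(all(lens >= 60 & lens <= 80))
  expect_gt(length(lens), 20)
})

test_that("reward availability matches the product-formula oracle", {
  # constant A_L = 0.6, three successive rights before the query
  ses <- mk_session(choice = c("L", "R", "R", "R", "L"),
                    reward = c(0, 0, 0, 0, 0),
                    A_L = 0.6, A_R = 0.1)
  expect_equal(p_reward_available(ses, 5, "L"), 1 - 0.4^4)
  expect_equal(p_reward_available(ses, 5, "L"),
               oracle_p_avail(ses$trials$choice, ses$trials$A_L, 5, "L"))
  # no prior opposite-side run: first trial returns A
  expect_equal(p_reward_available(ses, 1, "L"), 0.6)
  # probability change mid-run spans both values in the product
  ses2 <- mk_session(choice = c("L", "R", "L"), reward = 0,
                     A_L = c(0.6, 0.6, 0.1), A_R = c(0.1, 0.1, 0.6))
  expect_equal(p_reward_available(ses2, 3, "L"), 1 - 0.4 * 0.9)
  expect_error(p_reward_available(ses, 99, "L"), "out of range")
})

test_that("optimality score equals its brute-force evaluation", {
  # always-left under constant probabilities: every term is A_L
  ses <- mk_session(choice = rep("L", 20), reward = 0, A_L = 0.6, A_R = 0.1)
  expect_equal(optimality_score(ses), 0.6)
  # alternating choices: check against the independent oracle
  ch <- rep(c("L", "R"), 10)
  ses2 <- mk_session(choice = ch, reward = 0, A_L = 0.6, A_R = 0.1)
  oracle <- mean(vapply(seq_along(ch), function(t)
    oracle_p_avail(ch, rep(if (ch[t] == "L") 0.6 else 0.1, 20), t, ch[t]),
    numeric(1)))
  expect_equal(optimality_score(ses2), oracle)
  # interior alternating terms are 1-0.4^2 (left) and 1-0.9^2 (right)
  expect_equal(p_reward_available(ses2, 3, "L"), 1 - 0.4^2)
  expect_equal(p_reward_available(ses2, 4, "R"), 1 - 0.9^2)
  # the score never exceeds the best available side at each trial
  best <- mean(vapply(seq_along(ch), function(t)
    max(p_reward_available(ses2, t, "L"), p_reward_available(ses2, t, "R")),
    numeric(1)))
  expect_lte(optimality_score(ses2), best)
  expect_error(optimality_score(
    mk_session("none", 0L, 0.6, 0.1)), "no included choice trials")
})

test_that("high-side choice fraction behaves at its extremes", {
  ses_hi <- mk_session(choice = rep("L", 30), reward = 0, A_L = 0.6,
                       A_R = 0.1)
  expect_equal(p_choose_high(ses_hi), 1)
  set.seed(3)
  ch <- sample(c("L", "R"), 2000, replace = TRUE)
  ses_rand <- mk_session(choice = ch, reward = 0, A_L = 0.6, A_R = 0.1)
  expect_lt(abs(p_choose_high(ses_rand) - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("sessions round-trip through CSV plus sidecar and reproduce under a seed", {
  g1 <- gen_behavior_session(teacher_spec(), task_config(n_trials = 120),
                             seed = 55)
  g2 <- gen_behavior_session(teacher_spec(), task_config(n_trials = 120),
                             seed = 55)
  expect_identical(g1$session$trials, g2$session$trials)
  path <- file.path(tempdir(), "ses.csv")
  write_session(g1$session, path)
  back <- read_session(path)
  expect_equal(back$trials$choice, g1$session$trials$choice)
  expect_equal(back$trials$reward, g1$session$trials$reward)
  expect_equal(back$trials$A_L, g1$session$trials$A_L)
  expect_equal(back$config$block_len_range, g1$session$config$block_len_range)
})
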