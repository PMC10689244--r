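#' Recurrent actor-critic parameters
#'
#' Two parallel tanh recurrent subnetworks of `n_units` each (actor and
#' critic) receive the same three inputs (previous reward, previous left
#' choice, previous right choice). The actor head maps its subnetwork to
#' two action logits; the critic head maps its subnetwork to a scalar
#' state value. Weight matrices are Glorot-uniform initialized, biases
#' zero.
#'
#' @param n_units recurrent units per subnetwork (the concatenated
#'   `2 * n_units` units are the population used for decoding).
#' @param n_inputs number of input neurons.
#' @return named list of class `agent_params` with elements `Wx_a`,
#'   `Wy_a`, `b_a`, `Wx_c`, `Wy_c`, `b_c`, `W_pi`, `b_pi`, `W_v`, `b_v`.
#' @export
agent_params_init <- function(n_units = 50L, n_inputs = 3L) {
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  structure(list(
    Wx_a = glorot(n_units, n_inputs), Wy_a = glorot(n_units, n_units),
    b_a = numeric(n_units),
    Wx_c = glorot(n_units, n_inputs), Wy_c = glorot(n_units, n_units),
    b_c = numeric(n_units),
    W_pi = glorot(2L, n_units), b_pi = numeric(2L),
    W_v = glorot(1L, n_units), b_v = numeric(1L)),
    class = "agent_params")
}

#' A2C training configuration
#'
#' Defaults are the training hyperparameters of the study conditions:
#' learning rate 5e-4, per-step discount `gamma = 0.5`, entropy weight
#' `beta_e = 0.5`, value-loss weight `beta_v = 0.01`, unroll length 50
#' time steps, 500 trials per session, 300 training sessions plus one
#' frozen evaluation session, and 4 or 5 recurrent steps per trial drawn
#' uniformly.
#'
#' @param learning_rate RMSProp learning rate.
#' @param gamma per-time-step discount factor.
#' @param beta_e entropy bonus weight.
#' @param beta_v value-loss weight.
#' @param unroll truncated-BPTT segment length in time steps.
#' @param trials_per_session trials per session (episode).
#' @param n_sessions number of training sessions (weight updates).
#' @param steps_per_trial candidate recurrent steps per trial.
#' @param rmsprop_decay,rmsprop_eps RMSProp moving-average decay and
#'   numerical floor.
#' @param update_mode `"sequential"` applies the stored per-segment
#'   gradients one by one at the session boundary; `"averaged"` applies
#'   their mean as a single step.
#' @return list of class `train_config`.
#' @export
train_config <- function(learning_rate = 5e-4, gamma = 0.5, beta_e = 0.5,
                         beta_v = 0.01, unroll = 50L,
                         trials_per_session = 500L, n_sessions = 300L,
                         steps_per_trial = c(4L, 5L),
                         rmsprop_decay = 0.99, rmsprop_eps = 1e-5,
                         update_mode = c("sequential", "averaged")) {
  stopifnot(gamma > 0, gamma <= 1, unroll >= 1)
  structure(list(learning_rate = learning_rate, gamma = gamma,
                 beta_e = beta_e, beta_v = beta_v, unroll = as.integer(unroll),
                 trials_per_session = as.integer(trials_per_session),
                 n_sessions = as.integer(n_sessions),
                 steps_per_trial = as.integer(steps_per_trial),
                 rmsprop_decay = rmsprop_decay, rmsprop_eps = rmsprop_eps,
                 update_mode = match.arg(update_mode)),
            class = "train_config")
}

#' Single recurrent step
#'
#' `y_t = tanh(W_x x_t + W_y y_(t-1) + b)` for one subnetwork.
#'
#' @param Wx input weights, `Wy` recurrent weights, `b` bias.
#' @param Wy recurrent weight matrix.
#' @param b bias vector.
#' @param x input vector.
#' @param y_prev previous activation vector.
#' @return activation vector with entries in `(-1, 1)`.
#' @export
recurrent_step <- function(Wx, Wy, b, x, y_prev) {
  if (!all(is.finite(x)) || !all(is.finite(y_prev)))
    stop("non-finite inputs to recurrent_step")
  as.numeric(tanh(Wx %*% x + Wy %*% y_prev + b))
}

#' Run one session with frozen weights
#'
#' Plays `cfg$trials_per_session` trials of the baited bandit. Each trial
#' runs 4 or 5 recurrent time steps; the (reward, left, right) input is
#' presented only at the first step after the previous choice (all-zero
#' on the session's first trial); the action is sampled from the softmax
#' of the two actor logits at the trial's final step. Parameters are
#' never modified.
#'
#' @param params an `agent_params`.
#' @param task_cfg a [task_config()].
#' @param cfg a [train_config()].
#' @param inactivation optional list with `units` (indices in
#'   `1:(2*n_units)` to silence at the final step of flagged trials) and
#'   `trials` (logical flags per trial).
#' @param keep_rollout retain full activation traces (needed for learning
#'   updates and activity extraction).
#' @return list with `session` (a `bandit_session`) and `rollout`.
#' @export
run_session <- function(params, task_cfg, cfg, inactivation = NULL,
                        keep_rollout = TRUE) {
  n_trials <- cfg$trials_per_session
  n <- nrow(params$Wy_a)
  steps <- sample(cfg$steps_per_trial, n_trials, replace = TRUE)
  Ttot <- sum(steps)
  X <- matrix(0, 3L, Ttot)
  ya <- matrix(0, n, Ttot); yc <- matrix(0, n, Ttot)
  V <- numeric(Ttot)
  action_steps <- integer(n_trials); actions <- integer(n_trials)
  rewards_step <- numeric(Ttot); pi_take <- numeric(n_trials)
  choice <- character(n_trials); reward <- integer(n_trials)
  A_L <- numeric(n_trials); A_R <- numeric(n_trials); block <- integer(n_trials)
  inact_flag <- logical(n_trials)

  state <- bandit_state_init(task_cfg)
  recent_high <- logical(0)
  y_a <- numeric(n); y_c <- numeric(n)
  x_next <- numeric(3)
  pos <- 0L
  no_mask <- integer(0)
  for (t in seq_len(n_trials)) {
    p <- current_probs(state, task_cfg)
    A_L[t] <- p[1]; A_R[t] <- p[2]; block[t] <- state$block
    mask <- no_mask
    if (!is.null(inactivation) && isTRUE(inactivation$trials[t])) {
      mask <- as.integer(inactivation$units - 1L)
      inact_flag[t] <- TRUE
    }
    fw <- agent_trial_forward_cpp(params, y_a, y_c, x_next, steps[t], mask)
    idx <- pos + seq_len(steps[t])
    X[, pos + 1L] <- x_next
    ya[, idx] <- fw$ya; yc[, idx] <- fw$yc
    y_a <- fw$ya[, steps[t]]; y_c <- fw$yc[, steps[t]]
    V[idx] <- as.numeric(params$W_v %*% fw$yc) + params$b_v
    logits <- as.numeric(params$W_pi %*% y_a) + params$b_pi
    pl <- 1 / (1 + exp(-(logits[1] - logits[2])))
    a <- if (stats::runif(1) < pl) 1L else 2L
    ch <- c("L", "R")[a]
    st <- bait_and_step(state, ch, task_cfg)
    state <- st$state
    pos_action <- pos + steps[t]
    action_steps[t] <- pos_action; actions[t] <- a
    rewards_step[pos_action] <- st$reward
    pi_take[t] <- if (a == 1L) pl else 1 - pl
    choice[t] <- ch; reward[t] <- st$reward
    hi <- if (p[1] >= p[2]) "L" else "R"
    recent_high <- c(recent_high, ch == hi)
    if (length(recent_high) > task_cfg$postpone_window)
      recent_high <- utils::tail(recent_high, task_cfg$postpone_window)
    state <- maybe_transition(state, recent_high, task_cfg)
    x_next <- c(st$reward, as.integer(a == 1L), as.integer(a == 2L))
    pos <- pos + steps[t]
  }
  trials <- data.frame(choice = choice, reward = reward, A_L = A_L, A_R = A_R,
                       block = block, included = TRUE,
                       inactivation = inact_flag)
  session <- bandit_session(trials, task_cfg,
                            list(generator = "meta_rl_agent"))
  rollout <- NULL
  if (keep_rollout) {
    rollout <- list(X = X, ya = ya, yc = yc, V = V,
                    steps_per_trial = steps, action_steps = action_steps,
                    actions = actions, rewards_step = rewards_step,
                    pi_taken = pi_take)
    class(rollout) <- "a2c_rollout"
  }
  list(session = session, rollout = rollout)
}

# Split a rollout into unroll segments and compute per-segment losses and
# (optionally) BPTT gradients. Bootstrap value at each internal segment
# boundary is the critic's value at the next segment's first step (a
# constant under differentiation); zero at session end.
segment_sweep <- function(params, rollout, cfg, want_grads = TRUE) {
  Ttot <- ncol(rollout$X)
  starts <- seq(1L, Ttot, by = cfg$unroll)
  n <- nrow(params$Wy_a)
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    s0 <- starts[k]
    s1 <- min(s0 + cfg$unroll - 1L, Ttot)
    idx <- s0:s1
    ya0 <- if (s0 == 1L) numeric(n) else rollout$ya[, s0 - 1L]
    yc0 <- if (s0 == 1L) numeric(n) else rollout$yc[, s0 - 1L]
    vboot <- if (s1 == Ttot) 0 else rollout$V[s1 + 1L]
    in_seg <- rollout$action_steps >= s0 & rollout$action_steps <= s1
    out[[k]] <- a2c_segment_cpp(params, rollout$X[, idx, drop = FALSE],
                                ya0, yc0,
                                as.integer(rollout$action_steps[in_seg] - s0 + 1L),
                                as.integer(rollout$actions[in_seg]),
                                rollout$rewards_step[idx], vboot,
                                cfg$gamma, cfg$beta_e, cfg$beta_v,
                                want_grads)
  }
  out
}

#' Losses of a completed rollout
#'
#' Policy, value and total loss per unroll segment: the policy loss is
#' `-ln pi(a|s) * A(s) - beta_e * H(pi)` at action steps with the TD
#' error `A = R_t - V(s_t)` as the advantage; the value loss is
#' `beta_v * 0.5 * (R_t - V(s_t))^2` at every step; `R_t` is the
#' discounted n-step return bootstrapped at the segment boundary.
#'
#' @param params an `agent_params` (the frozen session weights).
#' @param rollout rollout from [run_session()].
#' @param cfg a [train_config()].
#' @return data frame with one row per segment (`loss_pi`, `loss_v`,
#'   `loss_tot`).
#' @export
compute_losses <- function(params, rollout, cfg) {
  segs <- segment_sweep(params, rollout, cfg, want_grads = FALSE)
  data.frame(segment = seq_along(segs),
             loss_pi = vapply(segs, `[[`, numeric(1), "loss_pi"),
             loss_v = vapply(segs, `[[`, numeric(1), "loss_v"),
             loss_tot = vapply(segs, `[[`, numeric(1), "loss_tot"))
}

rmsprop_state_init <- function(params) lapply(params, function(p) p * 0)

# Apply one RMSProp step for a single gradient list. Gradients coming
# back from the compiled code may carry an n x 1 dim; strip it so vector
# parameters keep their shape.
rmsprop_step <- function(params, g, cache, cfg) {
  for (nm in names(params)) {
    gi <- if (is.matrix(params[[nm]])) g[[nm]] else as.numeric(g[[nm]])
    cache[[nm]] <- cfg$rmsprop_decay * cache[[nm]] +
      (1 - cfg$rmsprop_decay) * gi^2
    params[[nm]] <- params[[nm]] -
      cfg$learning_rate * gi / (sqrt(cache[[nm]]) + cfg$rmsprop_eps)
  }
  list(params = params, cache = cache)
}

#' Session-boundary weight update
#'
#' Computes truncated-BPTT gradients of the total loss for every unroll
#' segment of the session's rollout (all under the same frozen weights),
#' then applies them with RMSProp at the session boundary — either
#' sequentially in segment order or as a single averaged step. Weights
#' never change mid-session.
#'
#' @param params an `agent_params`.
#' @param rollout rollout from [run_session()].
#' @param cfg a [train_config()].
#' @param opt_state RMSProp cache from a previous call (or `NULL`).
#' @return list with updated `params`, `opt_state`, and the segment `losses`.
#' @export
session_update <- function(params, rollout, cfg, opt_state = NULL) {
  segs <- segment_sweep(params, rollout, cfg, want_grads = TRUE)
  for (s in segs) {
    bad <- vapply(s$grads, function(g) any(!is.finite(g)), logical(1))
    if (any(bad))
      stop("non-finite gradient in parameters: ",
           paste(names(bad)[bad], collapse = ", "))
  }
  if (is.null(opt_state)) opt_state <- rmsprop_state_init(params)
  if (cfg$update_mode == "sequential") {
    for (s in segs) {
      st <- rmsprop_step(params, s$grads, opt_state, cfg)
      params <- st$params; opt_state <- st$cache
    }
  } else {
    gbar <- segs[[1]]$grads
    for (k in seq_along(segs)[-1])
      for (nm in names(gbar)) gbar[[nm]] <- gbar[[nm]] + segs[[k]]$grads[[nm]]
    for (nm in names(gbar)) gbar[[nm]] <- gbar[[nm]] / length(segs)
    st <- rmsprop_step(params, gbar, opt_state, cfg)
    params <- st$params; opt_state <- st$cache
  }
  losses <- data.frame(segment = seq_along(segs),
                       loss_pi = vapply(segs, `[[`, numeric(1), "loss_pi"),
                       loss_v = vapply(segs, `[[`, numeric(1), "loss_v"),
                       loss_tot = vapply(segs, `[[`, numeric(1), "loss_tot"))
  list(params = params, opt_state = opt_state, losses = losses)
}

#' Train the agent across sessions
#'
#' Runs `cfg$n_sessions` training sessions (weights frozen within each,
#' one RMSProp update sweep at each boundary) followed by one additional
#' frozen evaluation session, mirroring a slow outer learning loop
#' shaping a fast within-session loop carried by recurrent activity.
#'
#' @param task_cfg a [task_config()].
#' @param cfg a [train_config()].
#' @param seed integer seed (all randomness, including the environment,
#'   runs off R's RNG).
#' @param keep_sessions retain every session's behavior (else only the
#'   evaluation session).
#' @param snapshot_every store a parameter snapshot every this many
#'   sessions (`Inf` for none).
#' @return object of class `meta_rl_run`: final `params`, list of
#'   `sessions`, per-session `log` (mean reward, losses), `snapshots`,
#'   the last session's `rollout`, and the configs.
#' @export
train_agent <- function(task_cfg = task_config(), cfg = train_config(),
                        seed = 1L, keep_sessions = TRUE,
                        snapshot_every = Inf) {
  set.seed(seed)
  params <- agent_params_init()
  opt_state <- NULL
  sessions <- list()
  snapshots <- list()
  log <- vector("list", cfg$n_sessions + 1L)
  for (s in seq_len(cfg$n_sessions)) {
    run <- run_session(params, task_cfg, cfg)
    upd <- session_update(params, run$rollout, cfg, opt_state)
    params <- upd$params; opt_state <- upd$opt_state
    if (keep_sessions) sessions[[s]] <- run$session
    log[[s]] <- data.frame(session = s,
                           mean_reward = mean(run$session$trials$reward),
                           loss_pi = mean(upd$losses$loss_pi),
                           loss_v = mean(upd$losses$loss_v))
    if (is.finite(snapshot_every) && s %% snapshot_every == 0)
      snapshots[[as.character(s)]] <- params
  }
  eval_run <- run_session(params, task_cfg, cfg)
  sessions[[cfg$n_sessions + 1L]] <- eval_run$session
  log[[cfg$n_sessions + 1L]] <- data.frame(
    session = cfg$n_sessions + 1L,
    mean_reward = mean(eval_run$session$trials$reward),
    loss_pi = NA_real_, loss_v = NA_real_)
  structure(list(params = params, sessions = sessions,
                 log = do.call(rbind, log), snapshots = snapshots,
                 rollout = eval_run$rollout,
                 task_cfg = task_cfg, train_cfg = cfg, seed = seed),
            class = "meta_rl_run")
}

#' @export
print.meta_rl_run <- function(x, ...) {
  cat(sprintf("<meta_rl_run> %d sessions + eval, final mean reward %.3f\n",
              x$train_cfg$n_sessions,
              utils::tail(x$log$mean_reward, 1)))
  invisible(x)
}

#' Unit inactivation experiment on a trained agent
#'
#' Silences a random subset of `floor(fraction * N)` of the `N`
#' concatenated recurrent units at the time step immediately before
#' action selection, on trials scheduled at ~`rate` with the constraint
#' that each inactivation trial is followed by at least `min_gap`
#' control trials. Repeated `n_repeats` times with fresh unit subsets
#' and schedules.
#'
#' @param params trained `agent_params`.
#' @param fraction fraction of recurrent units to silence.
#' @param task_cfg,cfg task and training configuration.
#' @param n_repeats number of repeat sessions.
#' @param rate,min_gap inactivation-trial scheduling parameters.
#' @return list of `bandit_session`s with inactivation flags set.
#' @export
inactivate_and_run <- function(params, fraction, task_cfg = task_config(),
                               cfg = train_config(), n_repeats = 50L,
                               rate = 0.13, min_gap = 4L) {
  stopifnot(fraction >= 0, fraction <= 1)
  n_units_total <- 2L * nrow(params$Wy_a)
  k <- floor(fraction * n_units_total)
  lapply(seq_len(n_repeats), function(r) {
    units <- if (k > 0) sample.int(n_units_total, k) else integer(0)
    flags <- gen_inactivation_schedule(cfg$trials_per_session,
                                       rate = rate, min_gap = min_gap)
    run <- run_session(params, task_cfg, cfg,
                       inactivation = list(units = units, trials = flags),
                       keep_rollout = FALSE)
    run$session
  })
}

#' Extract per-trial unit activity from a rollout
#'
#' `"prechoice_mean3"` averages each unit over the three time steps
#' immediately before the choice step of each trial; `"postchoice"` takes
#' the activity at the trial's final step (the step at which the choice
#' and outcome occur). Unit IDs (`a1..a50`, `c1..c50`) are stable across
#' sessions of one network.
#'
#' @param rollout rollout from [run_session()].
#' @param epoch `"prechoice_mean3"` or `"postchoice"`.
#' @param session_id label stored with the activity table.
#' @return a [population_activity()] with trials x (2*n_units) activity.
#' @export
extract_unit_activity <- function(rollout, epoch = c("prechoice_mean3",
                                                     "postchoice"),
                                  session_id = "agent") {
  epoch <- match.arg(epoch)
  steps <- rollout$steps_per_trial
  n_trials <- length(steps)
  n <- nrow(rollout$ya)
  act <- matrix(0, n_trials, 2L * n)
  pos <- 0L
  for (t in seq_len(n_trials)) {
    if (epoch == "prechoice_mean3") {
      idx <- pos + (steps[t] - 3L):(steps[t] - 1L)
      act[t, ] <- c(rowMeans(rollout$ya[, idx, drop = FALSE]),
                    rowMeans(rollout$yc[, idx, drop = FALSE]))
    } else {
      idx <- pos + steps[t]
      act[t, ] <- c(rollout$ya[, idx], rollout$yc[, idx])
    }
    pos <- pos + steps[t]
  }
  population_activity(act,
                      neuron_ids = c(paste0("a", seq_len(n)),
                                     paste0("c", seq_len(n))),
                      included = rep(TRUE, n_trials),
                      epoch = epoch, session_id = session_id)
}
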