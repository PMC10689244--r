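#' Teacher specification for synthetic behavior
#'
#' The teacher is the generative forgetting Q-learning agent: values
#' update per trial (learning rates `alpha_rew`/`alpha_unr`, forgetting
#' `omega`) and choices follow the logistic policy (inverse temperature
#' `beta_dq`, bias `beta0`, optional previous-choice weight `beta_c`).
#' Miss/alarm trials (no choice, never rewarded, excluded from analyses)
#' are inserted at `miss_rate`; the teacher's values are not updated on
#' those trials.
#'
#' @param alpha_rew,alpha_unr learning rates after rewarded/unrewarded
#'   trials.
#' @param omega per-trial forgetting rate of the unchosen value.
#' @param beta_dq inverse temperature on the value difference.
#' @param beta0 constant side bias.
#' @param beta_c previous-choice weight (`NULL` for the mouse variant).
#' @param miss_rate probability a trial is a miss/alarm.
#' @param q0 initial action values.
#' @return list of class `teacher_spec`.
#' @export
teacher_spec <- function(alpha_rew = 0.6, alpha_unr = 0.2, omega = 0.1,
                         beta_dq = 3, beta0 = 0, beta_c = NULL,
                         miss_rate = 0, q0 = 0.5) {
  stopifnot(alpha_rew >= 0, alpha_rew <= 1, alpha_unr >= 0, alpha_unr <= 1,
            omega >= 0, omega <= 1, beta_dq >= 0,
            miss_rate >= 0, miss_rate < 1)
  structure(list(alpha_rew = alpha_rew, alpha_unr = alpha_unr, omega = omega,
                 beta_dq = beta_dq, beta0 = beta0, beta_c = beta_c,
                 miss_rate = miss_rate, q0 = q0),
            class = "teacher_spec")
}

#' Generate one behavioral session from the value-model teacher
#'
#' The teacher plays the baited bandit; its true per-trial value series
#' is recorded as ground truth for decoder and model-recovery studies.
#'
#' @param teacher a [teacher_spec()].
#' @param task_cfg a [task_config()].
#' @param seed optional integer seed (`NULL` to use the current RNG
#'   state).
#' @param meta extra provenance fields.
#' @return list with `session` (a `bandit_session`) and `values`
#'   (data frame `Q_L`, `Q_R`, `dQ`, `sumQ`, `Q_ch`, `P_L` per trial).
#' @export
gen_behavior_session <- function(teacher = teacher_spec(),
                                 task_cfg = task_config(), seed = NULL,
                                 meta = list()) {
  if (!is.null(seed)) set.seed(seed)
  variant <- if (is.null(teacher$beta_c)) "mouse" else "deepRL"
  env <- new.env()
  env$qL <- teacher$q0; env$qR <- teacher$q0; env$prev <- 0
  n <- task_cfg$n_trials
  env$QL <- numeric(n); env$QR <- numeric(n); env$PL <- numeric(n)
  policy <- function(t, prev_ch, prev_rw) {
    env$QL[t] <- env$qL; env$QR[t] <- env$qR
    pL <- choice_prob(env$qL, env$qR, env$prev, teacher, variant)
    env$PL[t] <- pL
    if (teacher$miss_rate > 0 && stats::runif(1) < teacher$miss_rate)
      return("none")
    ch <- if (stats::runif(1) < pL) "L" else "R"
    ch
  }
  # env update must see the realized reward, so wrap play_session's
  # per-trial callback: update values from the previous trial's outcome.
  policy_with_update <- function(t, prev_ch, prev_rw) {
    if (!is.null(prev_ch) && prev_ch != "none") {
      if (prev_ch == "L") {
        up <- rl_update(env$qL, env$qR, prev_rw, teacher)
        env$qL <- up$Q_ch; env$qR <- up$Q_unch; env$prev <- 1
      } else {
        up <- rl_update(env$qR, env$qL, prev_rw, teacher)
        env$qR <- up$Q_ch; env$qL <- up$Q_unch; env$prev <- -1
      }
    }
    policy(t, prev_ch, prev_rw)
  }
  meta <- utils::modifyList(list(generator = "rl_teacher", seed = seed),
                            meta)
  session <- play_session(policy_with_update, task_cfg, meta)
  cc <- session_choice_codes(session)
  qs <- cbind(Q_L = env$QL, Q_R = env$QR, P_L = env$PL)
  values <- value_series_from_q(qs, cc$choices)
  list(session = session, values = values, teacher = teacher)
}

#' History-kernel teacher for longitudinal behavior
#'
#' Generates choices directly from the history logistic model: the log
#' odds of a left choice are the inner products of `beta_r` and `beta_c`
#' with the recent signed reward- and choice-history differences, plus
#' `bias`. Used where the ground-truth action policy axis must be
#' controlled exactly (e.g. rotate-then-freeze schedules).
#'
#' @param beta_r,beta_c 5-vectors of reward- and choice-history weights.
#' @param bias constant bias.
#' @param miss_rate miss/alarm probability.
#' @param task_cfg a [task_config()].
#' @param seed optional seed.
#' @param meta provenance fields.
#' @return a `bandit_session`.
#' @export
gen_kernel_behavior <- function(beta_r, beta_c = rep(0, 5), bias = 0,
                                miss_rate = 0, task_cfg = task_config(),
                                seed = NULL, meta = list()) {
  stopifnot(length(beta_r) == 5, length(beta_c) == 5)
  if (!is.null(seed)) set.seed(seed)
  env <- new.env()
  env$rdiff <- numeric(0); env$cdiff <- numeric(0)
  policy <- function(t, prev_ch, prev_rw) {
    if (!is.null(prev_ch) && prev_ch != "none") {
      sgn <- if (prev_ch == "L") 1 else -1
      env$rdiff <- utils::head(c(prev_rw * sgn, env$rdiff), 5)
      env$cdiff <- utils::head(c(sgn, env$cdiff), 5)
    }
    if (miss_rate > 0 && stats::runif(1) < miss_rate) return("none")
    k <- length(env$rdiff)
    z <- bias
    if (k > 0)
      z <- z + sum(beta_r[seq_len(k)] * env$rdiff) +
        sum(beta_c[seq_len(k)] * env$cdiff)
    pL <- 1 / (1 + exp(-z))
    if (stats::runif(1) < pL) "L" else "R"
  }
  meta <- utils::modifyList(list(generator = "kernel_teacher", seed = seed),
                            meta)
  play_session(policy, task_cfg, meta)
}

#' Neural population generator specification
#'
#' Activity is a linear readout of the value-related signals plus a slow
#' smoothed random-walk drift plus white noise:
#' `a_i(t) = sum_s w_is * signal_s(t) + drift_i(t) + eps_i(t)`.
#' Signals are centered and scaled to unit standard deviation before
#' mixing so that `coding_sd` sets the per-neuron coding scale directly.
#' Defaults put the noise at the coding scale and the drift at twice the
#' coding scale — strong enough that per-trial decoding of an unrelated
#' slow variable is visibly inflated while the trial-difference decoder
#' stays at its floor.
#'
#' @param n_neurons population size.
#' @param coding_sd standard deviation of the Gaussian coding weights.
#' @param noise_sd white noise standard deviation.
#' @param drift_sd target per-neuron standard deviation of the slow
#'   drift over the session.
#' @param drift_tau exponential smoothing timescale of the drift, in
#'   trials. Kept short so that drift is slow in levels but nearly
#'   unstructured in trial-to-trial increments, the regime the
#'   trial-difference decoder is built for.
#' @return list of class `neural_gen_spec`.
#' @export
neural_gen_spec <- function(n_neurons = 60L, coding_sd = 1, noise_sd = 1,
                            drift_sd = 2, drift_tau = 3) {
  stopifnot(n_neurons >= 1, coding_sd >= 0, noise_sd >= 0, drift_sd >= 0,
            drift_tau > 0)
  structure(list(n_neurons = as.integer(n_neurons), coding_sd = coding_sd,
                 noise_sd = noise_sd, drift_sd = drift_sd,
                 drift_tau = drift_tau),
            class = "neural_gen_spec")
}

# Smoothed random-walk drift, rescaled to the target SD (zero if the
# target is zero).
gen_drift <- function(n_trials, n_neurons, sd_target, tau) {
  if (sd_target == 0) return(matrix(0, n_trials, n_neurons))
  steps <- matrix(stats::rnorm(n_trials * n_neurons), n_trials, n_neurons)
  walk <- apply(steps, 2, cumsum)
  a <- exp(-1 / tau)
  sm <- apply(walk, 2, function(w)
    as.numeric(stats::filter(w * (1 - a), a, method = "recursive")))
  scl <- apply(sm, 2, stats::sd)
  scl[scl == 0] <- 1
  sweep(sm, 2, scl, "/") * sd_target
}

scale_signals <- function(S) {
  S <- as.matrix(S)
  S[is.na(S)] <- 0
  mu <- colMeans(S)
  sdv <- apply(S, 2, stats::sd)
  sdv[sdv == 0] <- 1
  sweep(sweep(S, 2, mu), 2, sdv, "/")
}

#' Generate population activity encoding value signals
#'
#' @param values data frame with columns `dQ`, `sumQ`, `Q_ch` (e.g. from
#'   [gen_behavior_session()] or [fit_rl_model()]).
#' @param spec a [neural_gen_spec()].
#' @param seed optional seed.
#' @param weights optional n_neurons x 3 coding weight matrix (drawn
#'   `N(0, coding_sd^2)` if omitted).
#' @param included per-trial inclusion flags (defaults to all).
#' @param neuron_ids persistent IDs.
#' @param epoch,session_id labels.
#' @return list with `activity` (a [population_activity()]) and
#'   `weights` (the ground-truth coding matrix, targets in columns).
#' @export
gen_population <- function(values, spec = neural_gen_spec(), seed = NULL,
                           weights = NULL, included = NULL,
                           neuron_ids = NULL, epoch = "prechoice",
                           session_id = "synthetic") {
  if (!is.null(seed)) set.seed(seed)
  S <- scale_signals(values[, c("dQ", "sumQ", "Q_ch")])
  n_trials <- nrow(S)
  if (is.null(weights))
    weights <- matrix(stats::rnorm(spec$n_neurons * 3, 0, spec$coding_sd),
                      spec$n_neurons, 3,
                      dimnames = list(NULL, c("dQ", "sumQ", "Q_ch")))
  stopifnot(nrow(weights) == spec$n_neurons, ncol(weights) == 3)
  act <- S %*% t(weights) +
    gen_drift(n_trials, spec$n_neurons, spec$drift_sd, spec$drift_tau) +
    matrix(stats::rnorm(n_trials * spec$n_neurons, 0, spec$noise_sd),
           n_trials, spec$n_neurons)
  if (is.null(included)) included <- rep(TRUE, n_trials)
  list(activity = population_activity(act, neuron_ids, included, epoch,
                                      session_id),
       weights = weights)
}

# Rotate vector v by `angle` degrees toward a random direction orthogonal
# to v (within the full ambient space).
rotate_vector <- function(v, angle) {
  if (angle == 0) return(v)
  nv <- sqrt(sum(v^2))
  r <- stats::rnorm(length(v))
  r <- r - v * sum(r * v) / nv^2
  r <- r / sqrt(sum(r^2))
  th <- angle * pi / 180
  (cos(th) * v / nv + sin(th) * r) * nv
}

#' Generate a longitudinal synthetic study
#'
#' Emulates a longitudinal imaging design: each subject has two
#' interleaved imaging "planes" (disjoint neuron populations) recorded on
#' alternating sessions, so comparable session pairs are two sessions
#' apart. Behavior comes from a history-kernel teacher whose reward
#' kernel rotates by a per-session angle that decays geometrically
#' ("rotate then freeze"); the neural coding axes rotate on the same
#' decaying schedule, which couples coding-axis stabilization to policy
#' stabilization. Value signals for the neural readout are produced by a
#' fixed forgetting-Q observer run forward on each session's
#' choices and rewards. A random `dropout` fraction of a plane's neurons
#' is absent from each session's registration.
#'
#' @param n_subjects,n_sessions study size.
#' @param kernel0 initial reward-history kernel (5-vector).
#' @param rot0 initial per-session rotation angle in degrees.
#' @param rot_decay geometric decay factor of the rotation angle per
#'   session step.
#' @param neural_rot_scale ratio of coding-axis rotation angle to kernel
#'   rotation angle.
#' @param spec a [neural_gen_spec()].
#' @param observer a [teacher_spec()] whose value dynamics define the
#'   encoded signals.
#' @param dropout per-session neuron dropout rate.
#' @param miss_rate miss/alarm rate of the behavior.
#' @param task_cfg a [task_config()].
#' @param seed integer seed.
#' @return list of class `longitudinal_study`: per subject, a list of
#'   sessions each holding `session`, `values`, `activity`, the
#'   ground-truth `kernel` and coding `weights`, and `plane`.
#' @export
gen_longitudinal_study <- function(n_subjects = 3L, n_sessions = 12L,
                                   kernel0 = c(2, 1, 0.5, 0.25, 0.12),
                                   rot0 = 45, rot_decay = 0.65,
                                   neural_rot_scale = 1,
                                   spec = neural_gen_spec(),
                                   observer = teacher_spec(),
                                   dropout = 0.1, miss_rate = 0.05,
                                   task_cfg = task_config(), seed = 1L) {
  set.seed(seed)
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    W_plane <- list(
      matrix(stats::rnorm(spec$n_neurons * 3, 0, spec$coding_sd),
             spec$n_neurons, 3, dimnames = list(NULL, c("dQ", "sumQ", "Q_ch"))),
      matrix(stats::rnorm(spec$n_neurons * 3, 0, spec$coding_sd),
             spec$n_neurons, 3, dimnames = list(NULL, c("dQ", "sumQ", "Q_ch"))))
    ids_plane <- list(paste0("s", s, "p1n", seq_len(spec$n_neurons)),
                      paste0("s", s, "p2n", seq_len(spec$n_neurons)))
    kernel <- kernel0
    sessions <- vector("list", n_sessions)
    for (k in seq_len(n_sessions)) {
      plane <- ((k - 1L) %% 2L) + 1L
      session <- gen_kernel_behavior(kernel, beta_c = rep(0, 5), bias = 0,
                                     miss_rate = miss_rate,
                                     task_cfg = task_cfg,
                                     meta = list(subject = s, session = k,
                                                 plane = plane))
      cc <- session_choice_codes(session)
      par <- c(observer$alpha_rew, observer$alpha_unr, observer$omega,
               observer$beta_dq, observer$beta0)
      qs <- rl_qseries_cpp(par, cc$choices, cc$rewards, FALSE, observer$q0)
      values <- value_series_from_q(qs, cc$choices)
      present <- stats::runif(spec$n_neurons) >= dropout
      gp <- gen_population(values, spec,
                           weights = W_plane[[plane]],
                           included = session$trials$included,
                           neuron_ids = ids_plane[[plane]],
                           session_id = sprintf("s%d_k%d", s, k))
      act <- gp$activity
      act$activity <- act$activity[, present, drop = FALSE]
      act$neuron_ids <- act$neuron_ids[present]
      sessions[[k]] <- list(session = session, values = values,
                            activity = act, kernel = kernel,
                            weights = W_plane[[plane]][present, , drop = FALSE],
                            plane = plane, present = which(present))
      angle <- rot0 * rot_decay^(k - 1L)
      kernel <- rotate_vector(kernel, angle)
      W_plane[[plane]] <- apply(W_plane[[plane]], 2, rotate_vector,
                                angle = angle * neural_rot_scale)
      colnames(W_plane[[plane]]) <- c("dQ", "sumQ", "Q_ch")
    }
    subjects[[s]] <- sessions
  }
  structure(list(subjects = subjects,
                 params = list(kernel0 = kernel0, rot0 = rot0,
                               rot_decay = rot_decay, dropout = dropout,
                               n_subjects = n_subjects,
                               n_sessions = n_sessions, seed = seed)),
            class = "longitudinal_study")
}

#' Registered session pairs of a longitudinal study
#'
#' Same-plane session pairs (two sessions apart) with the intersection of
#' the neurons present in both sessions.
#'
#' @param study a `longitudinal_study`.
#' @return data frame with `subject`, `k1`, `k2`, `plane` and a
#'   list-column `shared` of registered neuron IDs.
#' @export
study_pairs <- function(study) {
  out <- list()
  for (s in seq_along(study$subjects)) {
    ses <- study$subjects[[s]]
    for (k in seq_len(length(ses) - 2L)) {
      a <- ses[[k]]; b <- ses[[k + 2L]]
      if (a$plane != b$plane) next
      shared <- intersect(a$activity$neuron_ids, b$activity$neuron_ids)
      out[[length(out) + 1L]] <-
        data.frame(subject = s, k1 = k, k2 = k + 2L, plane = a$plane,
                   shared = I(list(shared)))
    }
  }
  do.call(rbind, out)
}

#' Schedule inactivation trials
#'
#' Flags trials for inactivation at a long-run rate of ~`rate` under the
#' constraint that every flagged trial is followed by at least `min_gap`
#' consecutive unflagged trials. After each flag the next `min_gap`
#' trials are forced controls; eligible trials are flagged independently
#' with the probability that yields the requested long-run rate.
#'
#' @param n_trials number of trials.
#' @param rate target flagged fraction; must be below
#'   `1 / (1 + min_gap)`.
#' @param min_gap required control trials after each flag.
#' @return logical vector of flags.
#' @export
gen_inactivation_schedule <- function(n_trials, rate = 0.13, min_gap = 4L) {
  if (rate <= 0) return(logical(n_trials))
  if (rate >= 1 / (1 + min_gap))
    stop(sprintf("rate %.3g infeasible with min_gap %d (max %.3g)",
                 rate, min_gap, 1 / (1 + min_gap)))
  q <- rate / (1 - rate * min_gap)
  flags <- logical(n_trials)
  cool <- 0L
  for (t in seq_len(n_trials)) {
    if (cool > 0L) {
      cool <- cool - 1L
    } else if (stats::runif(1) < q) {
      flags[t] <- TRUE
      cool <- min_gap
    }
  }
  flags
}
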