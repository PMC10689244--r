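#' Task configuration for the baited reversal bandit
#'
#' The environment is a two-port probabilistic reversal task with reward
#' baiting (a concurrent variable-interval schedule): on every trial each
#' port independently receives a reward assignment with its current
#' probability unless a reward is already loaded there, and a loaded reward
#' stays on the port until that port is next chosen. The assignment
#' probability pair reverses every 60-80 trials, uncued, cycling
#' (0.60, 0.10) -> (0.10, 0.60) -> (0.525, 0.175) -> (0.175, 0.525) -> ...
#' A scheduled transition is postponed until the subject's recent
#' high-side choice fraction reaches the postponement threshold.
#'
#' @param prob_pairs list of length-2 numeric vectors `c(A_L, A_R)` cycled
#'   in order across blocks.
#' @param block_len_range integer interval from which each block length is
#'   drawn uniformly.
#' @param postpone_window number of recent included choice trials over
#'   which the high-side fraction is evaluated.
#' @param postpone_threshold minimum high-side fraction required for a
#'   scheduled transition to go through.
#' @param n_trials default number of trials per session.
#' @return an object of class `task_config`.
#' @export
task_config <- function(prob_pairs = list(c(0.60, 0.10), c(0.10, 0.60),
                                          c(0.525, 0.175), c(0.175, 0.525)),
                        block_len_range = c(60L, 80L),
                        postpone_window = 60L,
                        postpone_threshold = 0.5,
                        n_trials = 500L) {
  stopifnot(length(prob_pairs) >= 1, is.list(prob_pairs))
  hi <- c(0.60, 0.525); lo <- c(0.10, 0.175)
  for (p in prob_pairs) {
    stopifnot(length(p) == 2, all(p > 0), all(p < 1))
    if (!(sum(p %in% hi) == 1 && sum(p %in% lo) == 1))
      stop("each probability pair must contain one high (0.60/0.525) and one low (0.10/0.175) side")
  }
  highs <- vapply(prob_pairs, function(p) which.max(p), integer(1))
  if (length(prob_pairs) > 1 && any(diff(highs) == 0))
    stop("high and low sides must alternate along the pair cycle")
  stopifnot(length(block_len_range) == 2,
            block_len_range[1] >= 1, block_len_range[1] <= block_len_range[2])
  structure(list(prob_pairs = prob_pairs,
                 block_len_range = as.integer(block_len_range),
                 postpone_window = as.integer(postpone_window),
                 postpone_threshold = postpone_threshold,
                 n_trials = as.integer(n_trials)),
            class = "task_config")
}

#' Initial bandit state
#'
#' Both baited flags start clear; the first block length is drawn
#' uniformly from `cfg$block_len_range` using the current RNG state.
#'
#' @param cfg a [task_config()].
#' @return an object of class `bandit_state`.
#' @export
bandit_state_init <- function(cfg) {
  structure(list(pair_idx = 1L,
                 trials_elapsed = 0L,
                 scheduled_block_len = draw_block_len(cfg),
                 baited_L = FALSE, baited_R = FALSE,
                 trial_index = 0L,
                 block = 1L),
            class = "bandit_state")
}

draw_block_len <- function(cfg) {
  r <- cfg$block_len_range
  r[1] + sample.int(r[2] - r[1] + 1L, 1L) - 1L
}

#' Current assignment probabilities of a bandit state
#' @param state a `bandit_state`.
#' @param cfg a [task_config()].
#' @return numeric `c(A_L, A_R)`.
#' @export
current_probs <- function(state, cfg) cfg$prob_pairs[[state$pair_idx]]

#' Advance the bandit by one trial
#'
#' At the start of the trial each unbaited side becomes baited with its
#' current assignment probability. The chosen side's bait (if any) is
#' collected as the reward and its flag cleared; a `"none"` choice
#' (miss/alarm) collects nothing. The within-block trial counter is
#' incremented.
#'
#' @param state a `bandit_state`.
#' @param choice `"L"`, `"R"` or `"none"`.
#' @param cfg a [task_config()].
#' @return `list(reward = 0/1, state = updated state)`.
#' @export
bait_and_step <- function(state, choice, cfg) {
  choice <- match.arg(choice, c("L", "R", "none"))
  p <- current_probs(state, cfg)
  if (!state$baited_L) state$baited_L <- stats::runif(1) < p[1]
  if (!state$baited_R) state$baited_R <- stats::runif(1) < p[2]
  reward <- 0L
  if (choice == "L") {
    reward <- as.integer(state$baited_L)
    state$baited_L <- FALSE
  } else if (choice == "R") {
    reward <- as.integer(state$baited_R)
    state$baited_R <- FALSE
  }
  state$trials_elapsed <- state$trials_elapsed + 1L
  state$trial_index <- state$trial_index + 1L
  list(reward = reward, state = state)
}

#' Possibly advance to the next probability block
#'
#' Called once per trial after the choice. The transition scheduled at
#' `scheduled_block_len` trials goes through only when the fraction of
#' high-side choices among the recent included choice trials has reached
#' the postponement threshold; otherwise it is re-checked on every
#' subsequent trial until the criterion is met.
#'
#' @param state a `bandit_state`.
#' @param recent_high logical vector: for each of the recent included
#'   choice trials (most recent last, at most `cfg$postpone_window` used),
#'   whether the high-probability side was chosen.
#' @param cfg a [task_config()].
#' @return updated `bandit_state`.
#' @export
maybe_transition <- function(state, recent_high, cfg) {
  if (state$trials_elapsed < state$scheduled_block_len) return(state)
  w <- utils::tail(recent_high, cfg$postpone_window)
  frac <- if (length(w) == 0) 0 else mean(w)
  if (frac >= cfg$postpone_threshold) {
    state$pair_idx <- (state$pair_idx %% length(cfg$prob_pairs)) + 1L
    state$trials_elapsed <- 0L
    state$scheduled_block_len <- draw_block_len(cfg)
    state$block <- state$block + 1L
  }
  state
}

#' Assemble a session record
#'
#' @param trials data frame with columns `choice` (`"L"/"R"/"none"`),
#'   `reward` (0/1), `A_L`, `A_R`, `block`, `included` (logical),
#'   `inactivation` (logical).
#' @param cfg the [task_config()] under which the session was run.
#' @param meta named list of provenance fields (generator, seed, subject,
#'   session number, ...).
#' @return object of class `bandit_session`.
#' @export
bandit_session <- function(trials, cfg, meta = list()) {
  need <- c("choice", "reward", "A_L", "A_R", "block", "included", "inactivation")
  stopifnot(is.data.frame(trials), all(need %in% names(trials)))
  stopifnot(all(trials$choice %in% c("L", "R", "none")))
  stopifnot(all(trials$reward[trials$choice == "none"] == 0))
  stopifnot(all(trials$reward[!trials$included] == 0))
  trials$trial <- seq_len(nrow(trials)) - 1L
  structure(list(trials = trials, config = cfg, meta = meta),
            class = "bandit_session")
}

#' @export
print.bandit_session <- function(x, ...) {
  tr <- x$trials
  cat(sprintf("<bandit_session> %d trials, %d blocks, %d rewards, %.0f%% choice trials\n",
              nrow(tr), max(tr$block), sum(tr$reward),
              100 * mean(tr$choice != "none")))
  invisible(x)
}

#' Probability that a reward is available on one side
#'
#' Under the baiting rule the probability that a reward is loaded on a
#' side grows with every trial since that side was last chosen:
#' `1 - prod(1 - A_side(x))` with the product running from the trial after
#' the side's last choice through the current trial (from the session
#' start if the side has never been chosen).
#'
#' @param session a `bandit_session`.
#' @param t trial index, 1-based.
#' @param side `"L"` or `"R"`.
#' @return probability in `[0, 1]`.
#' @export
p_reward_available <- function(session, t, side) {
  side <- match.arg(side, c("L", "R"))
  tr <- session$trials
  if (t < 1 || t > nrow(tr)) stop("trial index out of range")
  prior <- which(tr$choice[seq_len(t - 1)] == side)
  from <- if (length(prior)) max(prior) + 1L else 1L
  a <- if (side == "L") tr$A_L[from:t] else tr$A_R[from:t]
  1 - prod(1 - a)
}

#' Session optimality score
#'
#' Mean, over included choice trials, of the probability that a reward was
#' available on the chosen side. Unlike the raw reward rate this measure
#' is unaffected by the randomness of the per-trial assignment draws.
#'
#' @param session a `bandit_session`.
#' @return score in `[0, 1]`.
#' @export
optimality_score <- function(session) {
  tr <- session$trials
  idx <- which(tr$included & tr$choice != "none")
  if (length(idx) == 0) stop("no included choice trials in session")
  mean(vapply(idx, function(t) p_reward_available(session, t, tr$choice[t]),
              numeric(1)))
}

#' Fraction of choices on the higher-probability side
#'
#' @param session a `bandit_session`.
#' @return fraction in `[0, 1]` over included choice trials.
#' @export
p_choose_high <- function(session) {
  tr <- session$trials
  idx <- tr$included & tr$choice != "none"
  if (!any(idx)) stop("no included choice trials in session")
  hi <- ifelse(tr$A_L >= tr$A_R, "L", "R")
  mean(tr$choice[idx] == hi[idx])
}

#' Write / read a session as CSV plus JSON sidecar
#'
#' The CSV holds one row per trial (`trial`, `choice`, `reward`, `A_L`,
#' `A_R`, `block`, `included`, `inactivation`); the sidecar
#' (`<path>.json`) holds the task configuration and provenance metadata.
#'
#' @param session a `bandit_session`.
#' @param path CSV file path.
#' @return `path`, invisibly (for `write_session`); a `bandit_session`
#'   (for `read_session`).
#' @export
write_session <- function(session, path) {
  tr <- session$trials
  out <- data.frame(trial = tr$trial, choice = tr$choice, reward = tr$reward,
                    A_L = tr$A_L, A_R = tr$A_R, block = tr$block,
                    included = as.integer(tr$included),
                    inactivation = as.integer(tr$inactivation))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  side <- list(config = unclass(session$config), meta = session$meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- side$config
  cfg$prob_pairs <- lapply(seq_len(nrow(cfg$prob_pairs)),
                           function(i) as.numeric(cfg$prob_pairs[i, ]))
  cfg <- do.call(task_config, cfg[c("prob_pairs", "block_len_range",
                                    "postpone_window", "postpone_threshold",
                                    "n_trials")])
  tr$included <- as.logical(tr$included)
  tr$inactivation <- as.logical(tr$inactivation)
  bandit_session(tr, cfg, as.list(side$meta))
}

# Shared driver: play `n_trials` of the bandit with an arbitrary policy.
# `policy_fn(t, prev_choice, prev_reward)` must return "L", "R" or "none"
# (stateful policies keep their own state in a closure; prev_* are NULL on
# the first trial). Used by the synthetic teachers; the deep RL agent has
# its own driver that also retains activations.
play_session <- function(policy_fn, cfg, meta = list()) {
  n <- cfg$n_trials
  state <- bandit_state_init(cfg)
  choice <- character(n); reward <- integer(n)
  A_L <- numeric(n); A_R <- numeric(n); block <- integer(n)
  recent_high <- logical(0)
  prev_ch <- NULL; prev_rw <- NULL
  for (t in seq_len(n)) {
    p <- current_probs(state, cfg)
    A_L[t] <- p[1]; A_R[t] <- p[2]; block[t] <- state$block
    ch <- policy_fn(t, prev_ch, prev_rw)
    st <- bait_and_step(state, ch, cfg)
    state <- st$state
    choice[t] <- ch; reward[t] <- st$reward
    if (ch != "none") {
      hi <- if (p[1] >= p[2]) "L" else "R"
      recent_high <- c(recent_high, ch == hi)
      if (length(recent_high) > cfg$postpone_window)
        recent_high <- utils::tail(recent_high, cfg$postpone_window)
    }
    state <- maybe_transition(state, recent_high, cfg)
    prev_ch <- ch; prev_rw <- st$reward
  }
  trials <- data.frame(choice = choice, reward = reward, A_L = A_L, A_R = A_R,
                       block = block, included = choice != "none",
                       inactivation = FALSE)
  bandit_session(trials, cfg, meta)
}
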