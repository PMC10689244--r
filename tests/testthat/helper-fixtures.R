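# Shared fixtures and oracles for the test suite.

# Build a session by hand from explicit choice/reward/probability columns.
mk_session <- function(choice, reward, A_L, A_R, block = 1L,
                       included = NULL, inactivation = FALSE,
                       cfg = task_config()) {
  n <- length(choice)
  if (is.null(included)) included <- choice != "none"
  bandit_session(data.frame(
    choice = choice, reward = reward,
    A_L = rep_len(A_L, n), A_R = rep_len(A_R, n),
    block = rep_len(block, n), included = rep_len(included, n),
    inactivation = rep_len(inactivation, n)), cfg)
}

# Independent oracle for reward availability: direct product formula over
# the trials since the side's last choice.
oracle_p_avail <- function(choices, A, t, side) {
  prior <- which(choices[seq_len(t - 1)] == side)
  from <- if (length(prior)) max(prior) + 1L else 1L
  1 - prod(1 - A[from:t])
}

# Run one Monte-Carlo episode: a fixed choice sequence through the baited
# environment with constant probabilities; returns the reward sequence.
mc_episode <- function(choices, cfg) {
  state <- bandit_state_init(cfg)
  vapply(choices, function(ch) {
    st <- bait_and_step(state, ch, cfg)
    state <<- st$state
    st$reward
  }, integer(1))
}

# Central finite-difference check of the segment gradients on a toy
# network; returns the worst relative error across all parameters.
grad_check_worst_relerr <- function(n_units = 2L, T = 9L, h = 1e-6,
                                    seed = 42L) {
  set.seed(seed)
  p <- agent_params_init(n_units = n_units)
  X <- matrix(0, 3, T)
  X[, c(1, 5)] <- matrix(stats::runif(6), 3)
  ya0 <- stats::rnorm(n_units, sd = 0.3)
  yc0 <- stats::rnorm(n_units, sd = 0.3)
  apos <- c(4L, T); acts <- c(1L, 2L)
  rew <- numeric(T); rew[apos] <- c(1, 0)
  seg <- function(pp, ...)
    metabandit:::a2c_segment_cpp(pp, X, ya0, yc0, apos, acts, rew,
                                 vboot = 0.3, gamma = 0.5, beta_e = 0.5,
                                 beta_v = 0.01, ...)
  ref <- seg(p, want_grads = TRUE)
  lossfn <- function(pp)
    seg(pp, want_grads = FALSE, A_fixed = ref$advantages,
        R_fixed = ref$returns)$loss_tot
  worst <- 0
  for (nm in names(p)) {
    g <- as.numeric(ref$grads[[nm]])
    fd <- numeric(length(p[[nm]]))
    for (i in seq_along(p[[nm]])) {
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] + h; up <- lossfn(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * h; dn <- lossfn(pp)
      fd[i] <- (up - dn) / (2 * h)
    }
    worst <- max(worst, max(abs(g - fd)) / max(1e-8, max(abs(fd))))
  }
  worst
}

# Smoothed random walk used for drift-only null value series.
mk_slow_walk <- function(n, tau = 3) {
  w <- cumsum(stats::rnorm(n))
  s <- as.numeric(stats::filter(w * (1 - exp(-1 / tau)), exp(-1 / tau),
                                method = "recursive"))
  s / stats::sd(s)
}

# Cache expensive trained agents across test files (training is
# deterministic in the seed, so cached and fresh runs are identical).
.trained_cache <- new.env(parent = emptyenv())
trained_run <- function(seed) {
  key <- as.character(seed)
  if (is.null(.trained_cache[[key]]))
    .trained_cache[[key]] <- train_agent(seed = seed, keep_sessions = TRUE)
  .trained_cache[[key]]
}
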