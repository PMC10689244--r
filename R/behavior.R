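#' Build the history design matrix for the choice regression
#'
#' Over the sequence of included choice trials, the model predicts a left
#' choice from signed reward-history differences `r_L - r_R` (+1 rewarded
#' left, -1 rewarded right, 0 unrewarded) and signed choice-history
#' differences `c_L - c_R` (+1 left, -1 right) at lags 1-5, plus a
#' constant bias. The first five choice trials are dropped as response
#' rows (incomplete history).
#'
#' @param session a `bandit_session`.
#' @param n_lags number of history lags.
#' @return list with response `y` (1 = left), design `X`
#'   (`rew_lag1..5`, `cho_lag1..5`), and `trial_idx` (row indices into
#'   `session$trials`).
#' @keywords internal
history_design <- function(session, n_lags = 5L) {
  tr <- session$trials
  idx <- which(tr$included & tr$choice != "none")
  m <- length(idx)
  if (m <= n_lags) stop("too few included choice trials for history design")
  sgn <- ifelse(tr$choice[idx] == "L", 1, -1)
  rdiff <- tr$reward[idx] * sgn
  cdiff <- sgn
  rows <- (n_lags + 1L):m
  X <- matrix(0, length(rows), 2L * n_lags)
  for (i in seq_len(n_lags)) {
    X[, i] <- rdiff[rows - i]
    X[, n_lags + i] <- cdiff[rows - i]
  }
  colnames(X) <- c(paste0("rew_lag", seq_len(n_lags)),
                   paste0("cho_lag", seq_len(n_lags)))
  list(y = as.integer(tr$choice[idx[rows]] == "L"), X = X,
       trial_idx = idx[rows])
}

#' Fit the choice-history logistic regression
#'
#' Maximum-likelihood logistic fit (no regularization) of the probability
#' of a left choice on five lags of reward history and choice history
#' plus a bias. Perfect separation or non-convergence is flagged with a
#' warning; the weights are still reported.
#'
#' @param session a `bandit_session`.
#' @param min_trials minimum number of included choice trials.
#' @return object of class `history_fit` with `beta_r` (lags 1-5),
#'   `beta_c`, `beta_bias`, `converged`, `separated`, `loglik`, `n`.
#' @export
fit_history_logit <- function(session, min_trials = 50L) {
  d <- history_design(session)
  if (length(d$y) + 5L < min_trials)
    stop("fewer than ", min_trials, " included choice trials")
  if (length(unique(d$y)) < 2L)
    stop("degenerate session: all choices on one side (perfect separation)")
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, d$X), d$y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep) warning("possible separation in history regression; weights flagged")
  cf <- fit$coefficients
  structure(list(beta_bias = unname(cf[1]),
                 beta_r = unname(cf[2:6]),
                 beta_c = unname(cf[7:11]),
                 converged = fit$converged, separated = sep,
                 loglik = -fit$deviance / 2,
                 n = length(d$y)),
            class = "history_fit")
}

#' @export
print.history_fit <- function(x, ...) {
  cat("<history_fit>\n  beta_r:", sprintf("%.3f", x$beta_r),
      "\n  beta_c:", sprintf("%.3f", x$beta_c),
      "\n  bias:", sprintf("%.3f", x$beta_bias), "\n")
  invisible(x)
}

#' Summed history weights and reward-history dependence
#'
#' `summed_history_weights` returns the plain sums of the five reward- and
#' choice-history weights (the session summaries whose signs distinguish
#' reward-following from choice alternation); `reward_history_dependence`
#' returns the sum of absolute reward-history weights, the magnitude of
#' behavioral reward-history dependence.
#'
#' @param fit a `history_fit` (or the ctrl/opto halves of a split fit).
#' @return named numeric.
#' @export
summed_history_weights <- function(fit) {
  c(sum_r = sum(fit$beta_r), sum_c = sum(fit$beta_c))
}

#' @rdname summed_history_weights
#' @export
reward_history_dependence <- function(fit) sum(abs(fit$beta_r))

#' Policy axes and angles between them
#'
#' A session's action policy axes are its 5-vectors of reward-history and
#' choice-history regression weights; the angle between the same axis of
#' two sessions measures policy stability.
#'
#' @param fit a `history_fit`.
#' @return `policy_axes`: list with `p_r` and `p_c`.
#' @export
policy_axes <- function(fit) {
  structure(list(p_r = fit$beta_r, p_c = fit$beta_c), class = "policy_axes")
}

vec_angle <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("angle undefined for zero vector")
  cosv <- sum(a * b) / (na * nb)
  cosv <- max(-1, min(1, cosv))
  list(cosine = cosv, degrees = acos(cosv) * 180 / pi)
}

#' @rdname policy_axes
#' @param p_a,p_b two axes (numeric vectors of equal length).
#' @export
axis_angle <- function(p_a, p_b) vec_angle(as.numeric(p_a), as.numeric(p_b))

#' Split control/inactivation history regression
#'
#' Fits one logistic model with separate weight sets for control and
#' inactivation trials (each set: 5 reward lags, 5 choice lags, bias,
#' interacted with the trial-class indicator). The fit is L2-penalized,
#' with the penalty chosen by fivefold contiguous cross-validation over a
#' 100-point logarithmic grid of inverse penalty strength in
#' `[1e-4, 1e4]`. Because inactivation trials are rare, control response
#' rows are subsampled to the inactivation count; subsampling is repeated
#' with the minimum number of iterations covering every control row at
#' least once, weights are averaged across iterations, and `|bias|` is
#' taken per iteration before averaging.
#'
#' @param session a `bandit_session` with inactivation flags.
#' @param n_folds CV folds.
#' @param n_c_grid grid size for the inverse penalty strength.
#' @return object of class `history_fit_split`: `ctrl` and `opto`
#'   (each a `history_fit`-like list), `abs_bias_ctrl`, `abs_bias_opto`
#'   (means of per-iteration absolute biases), `n_iter`.
#' @export
fit_history_logit_split <- function(session, n_folds = 5L, n_c_grid = 100L) {
  d <- history_design(session)
  opto_row <- session$trials$inactivation[d$trial_idx]
  if (!any(opto_row) || all(opto_row))
    stop("both control and inactivation trials are required")
  idx_ctrl <- which(!opto_row); idx_opto <- which(opto_row)
  n_iter <- ceiling(length(idx_ctrl) / length(idx_opto))
  perm <- sample(idx_ctrl)
  chunks <- split(perm, ceiling(seq_along(perm) / length(idx_opto)))
  short <- length(idx_opto) - length(chunks[[n_iter]])
  if (short > 0)
    chunks[[n_iter]] <- c(chunks[[n_iter]],
                          sample(setdiff(idx_ctrl, chunks[[n_iter]]), short))
  Cgrid <- 10^seq(-4, 4, length.out = n_c_grid)
  coefs <- matrix(0, n_iter, 22L)
  for (it in seq_len(n_iter)) {
    rows <- sort(c(chunks[[it]], idx_opto))
    ctrl_ind <- as.numeric(!opto_row[rows])
    opto_ind <- 1 - ctrl_ind
    Xi <- cbind(d$X[rows, , drop = FALSE] * ctrl_ind, bias_ctrl = ctrl_ind,
                d$X[rows, , drop = FALSE] * opto_ind, bias_opto = opto_ind)
    yi <- d$y[rows]
    lam <- rev(sort(1 / (length(yi) * Cgrid)))
    foldid <- ceiling(seq_along(yi) / (length(yi) / n_folds))
    cvf <- glmnet::cv.glmnet(Xi, yi, family = "binomial", alpha = 0,
                             lambda = lam, foldid = foldid,
                             intercept = FALSE, standardize = FALSE)
    coefs[it, ] <- as.numeric(stats::coef(cvf, s = "lambda.min"))[-1]
  }
  mean_cf <- colMeans(coefs)
  mk <- function(b) list(beta_r = b[1:5], beta_c = b[6:10], beta_bias = b[11])
  structure(list(ctrl = mk(mean_cf[1:11]), opto = mk(mean_cf[12:22]),
                 abs_bias_ctrl = mean(abs(coefs[, 11])),
                 abs_bias_opto = mean(abs(coefs[, 22])),
                 n_iter = n_iter),
            class = "history_fit_split")
}

#' Forgetting Q-learning update for one trial
#'
#' The chosen action's value moves toward the outcome with an
#' outcome-dependent learning rate (`alpha_rew` after reward, `alpha_unr`
#' after no reward); the unchosen action's value decays by `(1 - omega)`.
#'
#' @param Q_ch,Q_unch chosen and unchosen values in `[0, 1]`.
#' @param reward 0 or 1.
#' @param params list with `alpha_rew`, `alpha_unr`, `omega`.
#' @return `list(Q_ch, Q_unch)` after the update.
#' @export
rl_update <- function(Q_ch, Q_unch, reward, params) {
  with(params, {
    if (any(c(alpha_rew, alpha_unr, omega) < 0) ||
        any(c(alpha_rew, alpha_unr, omega) > 1))
      stop("learning/forgetting rates must lie in [0, 1]")
    a <- if (reward > 0.5) alpha_rew else alpha_unr
    list(Q_ch = Q_ch + a * (reward - Q_ch),
         Q_unch = (1 - omega) * Q_unch)
  })
}

#' Choice probability of the value model
#'
#' Logistic policy `P_L = 1 / (1 + exp(-beta_dq * (beta0 [+ beta_c *
#' C(t-1)] + Q_L - Q_R)))`. The `"deepRL"` variant includes the
#' previous-choice term (`C` = +1 left, -1 right), capturing
#' reward-independent choice alternation.
#'
#' @param Q_L,Q_R action values.
#' @param prev_choice +1 (left), -1 (right) or 0 (no previous choice).
#' @param params list with `beta_dq`, `beta0` and, for `"deepRL"`,
#'   `beta_c`.
#' @param variant `"mouse"` or `"deepRL"`.
#' @return probability of a left choice.
#' @export
choice_prob <- function(Q_L, Q_R, prev_choice = 0, params,
                        variant = c("mouse", "deepRL")) {
  variant <- match.arg(variant)
  z <- params$beta0 + Q_L - Q_R
  if (variant == "deepRL") z <- z + params$beta_c * prev_choice
  1 / (1 + exp(-params$beta_dq * z))
}

session_choice_codes <- function(session) {
  tr <- session$trials
  ch <- integer(nrow(tr))
  ch[tr$choice == "L" & tr$included] <- 1L
  ch[tr$choice == "R" & tr$included] <- 2L
  list(choices = ch, rewards = as.integer(tr$reward))
}

rl_par_space <- function(variant) {
  if (variant == "deepRL")
    list(lower = c(0, 0, 0, 0, -5, -5), upper = c(1, 1, 1, 50, 5, 5),
         start = c(0.4, 0.2, 0.1, 3, 0, 0),
         names = c("alpha_rew", "alpha_unr", "omega", "beta_dq", "beta0",
                   "beta_c"))
  else
    list(lower = c(0, 0, 0, 0, -5), upper = c(1, 1, 1, 50, 5),
         start = c(0.4, 0.2, 0.1, 3, 0),
         names = c("alpha_rew", "alpha_unr", "omega", "beta_dq", "beta0"))
}

rl_optim <- function(par0, cc, variant, q0, lambda, use, space) {
  f <- function(p) rl_negloglik_cpp(p, cc$choices, cc$rewards,
                                    variant == "deepRL", q0, lambda,
                                    as.integer(use))
  stats::optim(par0, f, method = "L-BFGS-B",
               lower = space$lower, upper = space$upper,
               control = list(maxit = 500))
}

#' Fit the forgetting Q-learning model to a session
#'
#' Minimizes the L2-penalized negative log-likelihood
#' `J = -ln L + lambda/2 * sum(theta^2)` by bounded quasi-Newton
#' optimization with multiple random restarts. The penalty `lambda` is
#' chosen on a logarithmic grid by tenfold contiguous-block
#' cross-validation (minimum held-out negative log-likelihood). Returns
#' the fitted parameters together with the implied per-trial value
#' series.
#'
#' @param session a `bandit_session` (>= `min_trials` included choice
#'   trials).
#' @param variant `"mouse"` (no previous-choice term) or `"deepRL"`.
#' @param lambda_grid penalty grid; default 20 points log-spaced in
#'   `[1e-4, 1e2]`.
#' @param n_folds CV folds.
#' @param n_starts random restarts for the final refit.
#' @param q0 initial action values at session start.
#' @param min_trials minimum included choice trials.
#' @return list of class `rl_fit`: `params` (named), `lambda`, `nll`,
#'   `cv` (per-lambda CV error), `converged`, and `values` (data frame
#'   `Q_L`, `Q_R`, `dQ`, `sumQ`, `Q_ch`, `P_L` per trial).
#' @export
fit_rl_model <- function(session, variant = c("mouse", "deepRL"),
                         lambda_grid = 10^seq(-4, 2, length.out = 20),
                         n_folds = 10L, n_starts = 10L, q0 = 0.5,
                         min_trials = 100L) {
  variant <- match.arg(variant)
  cc <- session_choice_codes(session)
  resp <- which(cc$choices != 0L)
  if (length(resp) < min_trials)
    stop("fewer than ", min_trials, " included choice trials")
  space <- rl_par_space(variant)
  n <- length(cc$choices)

  fold_of <- integer(n)
  fold_of[resp] <- ceiling(seq_along(resp) / (length(resp) / n_folds))
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  cv_err <- numeric(length(lambda_grid))
  warm <- space$start
  for (li in seq_along(lambda_grid)) {
    lam <- lambda_grid[li]
    err <- 0
    for (f in seq_len(n_folds)) {
      train <- fold_of != f & cc$choices != 0L
      test <- fold_of == f
      opt <- rl_optim(warm, cc, variant, q0, lam, train, space)
      err <- err + rl_negloglik_cpp(opt$par, cc$choices, cc$rewards,
                                    variant == "deepRL", q0, 0,
                                    as.integer(test))
    }
    cv_err[li] <- err
    warm <- rl_optim(warm, cc, variant, q0, lam,
                     cc$choices != 0L, space)$par
  }
  lam_best <- lambda_grid[which.min(cv_err)]

  all_use <- cc$choices != 0L
  best <- NULL
  starts <- c(list(space$start),
              lapply(seq_len(n_starts - 1L), function(i)
                stats::runif(length(space$lower), space$lower,
                             pmin(space$upper, c(1, 1, 1, 10, 2, 2)[seq_along(space$lower)]))))
  n_conv <- 0L
  for (p0 in starts) {
    opt <- try(rl_optim(p0, cc, variant, q0, lam_best, all_use, space),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (opt$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best) || n_conv == 0L)
    stop("no optimization start converged for the value model")
  par <- stats::setNames(best$par, space$names)

  qs <- rl_qseries_cpp(best$par, cc$choices, cc$rewards,
                       variant == "deepRL", q0)
  values <- value_series_from_q(qs, cc$choices)
  structure(list(params = as.list(par), variant = variant,
                 lambda = lam_best, nll = best$value,
                 cv = data.frame(lambda = lambda_grid, cv_nll = cv_err),
                 converged = TRUE, values = values),
            class = "rl_fit")
}

# Derive the decoded value signals from the raw Q series: dQ = Q_L - Q_R,
# sumQ = Q_L + Q_R, Q_ch = value (at t) of the side chosen on the
# immediately preceding trial (NA when that trial had no choice).
value_series_from_q <- function(qs, choices) {
  n <- nrow(qs)
  q_ch <- rep(NA_real_, n)
  if (n > 1) {
    prev <- choices[seq_len(n - 1)]
    t2 <- 2:n
    q_ch[t2[prev == 1L]] <- qs[t2[prev == 1L], "Q_L"]
    q_ch[t2[prev == 2L]] <- qs[t2[prev == 2L], "Q_R"]
  }
  data.frame(Q_L = qs[, "Q_L"], Q_R = qs[, "Q_R"],
             dQ = qs[, "Q_L"] - qs[, "Q_R"],
             sumQ = qs[, "Q_L"] + qs[, "Q_R"],
             Q_ch = q_ch, P_L = qs[, "P_L"])
}

#' @export
print.rl_fit <- function(x, ...) {
  cat("<rl_fit>", x$variant, "variant\n ",
      paste(names(x$params), sprintf("%.3f", unlist(x$params)),
            sep = "=", collapse = ", "),
      sprintf("\n  lambda=%.2g nll=%.1f\n", x$lambda, x$nll))
  invisible(x)
}

#' Serialize a fit as JSON
#'
#' @param fit a `history_fit`, `rl_fit`, or similar list of parameters
#'   and diagnostics.
#' @param path output file.
#' @export
write_fit_json <- function(fit, path) {
  obj <- unclass(fit)
  obj$values <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
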