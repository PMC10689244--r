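#' Population activity container
#'
#' Trials x neurons activity with persistent neuron IDs, per-trial
#' inclusion flags and an epoch label. Only included trials enter
#' decoders.
#'
#' @param activity numeric matrix, trials x neurons.
#' @param neuron_ids unique character IDs, one per column.
#' @param included logical per trial.
#' @param epoch epoch label (e.g. `"ITI"`, `"ready"`, `"postchoice"`,
#'   `"prechoice_mean3"`).
#' @param session_id label of the source session.
#' @return object of class `population_activity`.
#' @export
population_activity <- function(activity, neuron_ids = NULL,
                                included = NULL, epoch = "unspecified",
                                session_id = "") {
  activity <- as.matrix(activity)
  if (is.null(neuron_ids)) neuron_ids <- paste0("n", seq_len(ncol(activity)))
  if (anyDuplicated(neuron_ids)) stop("neuron IDs must be unique")
  stopifnot(length(neuron_ids) == ncol(activity))
  if (is.null(included)) included <- rep(TRUE, nrow(activity))
  stopifnot(length(included) == nrow(activity))
  colnames(activity) <- neuron_ids
  structure(list(activity = activity, neuron_ids = neuron_ids,
                 included = included, epoch = epoch,
                 session_id = session_id),
            class = "population_activity")
}

#' @export
print.population_activity <- function(x, ...) {
  cat(sprintf("<population_activity> %d trials x %d neurons, epoch '%s'\n",
              nrow(x$activity), ncol(x$activity), x$epoch))
  invisible(x)
}

#' Trial-difference design for value decoding
#'
#' Value signals and population activity are both slowly autocorrelated
#' across trials, so a per-trial decoder can report spurious coupling
#' between independent slow variables. The trial-difference decoder
#' regresses the change in the value signal between adjacent retained
#' trials on the change in each neuron's activity between the same
#' trials, discarding the slow components. Adjacent means adjacent within
#' the sequence of retained (included, non-`NA`) trials.
#'
#' @param activity a [population_activity()].
#' @param values numeric value signal per trial (`NA` allowed; those
#'   trials are dropped).
#' @param subset optional logical/integer subset of trials to retain
#'   before differencing (e.g. one task condition).
#' @return list with difference responses `y` (length m-1), difference
#'   predictors `X` (m-1 x neurons), and the retained trial indices.
#' @export
trial_diff_design <- function(activity, values, subset = NULL) {
  stopifnot(length(values) == nrow(activity$activity))
  keep <- activity$included & !is.na(values)
  if (!is.null(subset)) {
    sel <- rep(FALSE, length(keep))
    sel[subset] <- TRUE
    keep <- keep & sel
  }
  idx <- which(keep)
  if (length(idx) < 3L) stop("too few retained trials for differencing")
  y <- diff(values[idx])
  X <- apply(activity$activity[idx, , drop = FALSE], 2, diff)
  list(y = y, X = X, trials = idx)
}

#' Per-trial (standard) decoder design
#'
#' Rows are the raw per-trial values and activities of the retained
#' trials, with no differencing. This is the conventional decoder whose
#' accuracy is inflated when the value signal and the activity share
#' slow autocorrelation; it exists as the comparison arm for the
#' trial-difference decoder.
#'
#' @inheritParams trial_diff_design
#' @return list with `y`, `X`, `trials` as in [trial_diff_design()].
#' @export
per_trial_design <- function(activity, values, subset = NULL) {
  stopifnot(length(values) == nrow(activity$activity))
  keep <- activity$included & !is.na(values)
  if (!is.null(subset)) {
    sel <- rep(FALSE, length(keep))
    sel[subset] <- TRUE
    keep <- keep & sel
  }
  idx <- which(keep)
  if (length(idx) < 3L) stop("too few retained trials")
  list(y = values[idx], X = activity$activity[idx, , drop = FALSE],
       trials = idx)
}

# Least-squares solve with least-norm fallback on rank deficiency.
ls_solve <- function(X, y) {
  qr_d <- qr(X)
  if (qr_d$rank < ncol(X)) {
    warning("rank-deficient decoder design; using least-norm solution")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    coef <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
    as.numeric(coef)
  } else {
    as.numeric(qr.coef(qr_d, y))
  }
}

#' Fit a trial-difference value decoder
#'
#' Ordinary least squares of the value differences on the activity
#' differences plus an intercept. Accuracy is the Pearson correlation
#' between held-out predictions and observed differences, pooled over
#' tenfold contiguous (unshuffled) cross-validation; the reported weights
#' come from the full-data fit.
#'
#' @param design output of [trial_diff_design()].
#' @param n_folds number of contiguous CV folds.
#' @param target optional label (`"dQ"`, `"sumQ"`, `"Q_ch"`, ...).
#' @return object of class `decoder_fit`: `weights` (named per neuron),
#'   `intercept`, `accuracy` (CV r), `accuracy_insample`, `n_rows`,
#'   `target`.
#' @export
fit_value_decoder <- function(design, n_folds = 10L, target = "") {
  y <- design$y; X <- design$X
  n <- length(y)
  if (n < n_folds) stop("fewer difference rows than CV folds")
  Xi <- cbind(`(Intercept)` = 1, X)
  fold <- ceiling(seq_len(n) / (n / n_folds))
  pred <- numeric(n)
  for (f in unique(fold)) {
    te <- fold == f
    cf <- suppressWarnings(ls_solve(Xi[!te, , drop = FALSE], y[!te]))
    pred[te] <- Xi[te, , drop = FALSE] %*% cf
  }
  cf_full <- ls_solve(Xi, y)
  acc <- if (stats::sd(pred) == 0) 0 else stats::cor(pred, y)
  structure(list(weights = stats::setNames(cf_full[-1], colnames(X)),
                 intercept = cf_full[1],
                 accuracy = acc,
                 accuracy_insample = stats::cor(as.numeric(Xi %*% cf_full), y),
                 n_rows = n, target = target),
            class = "decoder_fit")
}

#' @export
print.decoder_fit <- function(x, ...) {
  cat(sprintf("<decoder_fit>%s %d neurons, %d rows, CV r = %.3f\n",
              if (nzchar(x$target)) paste0(" ", x$target) else "",
              length(x$weights), x$n_rows, x$accuracy))
  invisible(x)
}

# Covering draws of `k` cells: without replacement across iterations until
# every cell has appeared; the last draw is topped up with re-sampled
# cells when fewer than k remain.
covering_draws <- function(n_cells, k) {
  if (n_cells <= k) return(list(seq_len(n_cells)))
  perm <- sample.int(n_cells)
  n_iter <- ceiling(n_cells / k)
  draws <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    lo <- (i - 1L) * k + 1L
    hi <- min(i * k, n_cells)
    d <- perm[lo:hi]
    if (length(d) < k)
      d <- c(d, sample(perm[seq_len(lo - 1L)], k - length(d)))
    draws[[i]] <- sort(d)
  }
  draws
}

#' Decode with fixed-size neuron subsampling
#'
#' Subsamples `cells_per_draw` neurons without replacement per iteration
#' until every neuron has been used at least once (the last iteration is
#' topped up with re-sampled neurons); the cross-validated accuracy is
#' averaged over iterations. Populations at or below the draw size are
#' decoded once with all cells.
#'
#' @param activity a [population_activity()].
#' @param values value signal per trial.
#' @param cells_per_draw neurons per draw.
#' @param n_folds CV folds per draw.
#' @param target label.
#' @return list of class `subsample_decode`: `accuracy` (mean over
#'   draws), `fits` (per-draw `decoder_fit`s), `draws` (neuron index
#'   sets).
#' @export
subsample_decode <- function(activity, values, cells_per_draw = 55L,
                             n_folds = 10L, target = "") {
  draws <- covering_draws(ncol(activity$activity), cells_per_draw)
  fits <- lapply(draws, function(d) {
    sub <- population_activity(activity$activity[, d, drop = FALSE],
                               activity$neuron_ids[d], activity$included,
                               activity$epoch, activity$session_id)
    fit_value_decoder(trial_diff_design(sub, values), n_folds, target)
  })
  structure(list(accuracy = mean(vapply(fits, `[[`, numeric(1), "accuracy")),
                 fits = fits, draws = draws, target = target),
            class = "subsample_decode")
}

#' Within-session chance accuracy
#'
#' The value differences are shuffled across rows `n_shuffles` times, the
#' decoder refit each time, and the cross-validated accuracies averaged.
#' With the trial-difference design this floor sits close to zero even
#' when activity and values share slow drift.
#'
#' @param design output of [trial_diff_design()].
#' @param n_shuffles number of shuffles.
#' @param n_folds CV folds.
#' @return list with `chance` (mean accuracy) and `accuracies`.
#' @export
chance_within <- function(design, n_shuffles = 100L, n_folds = 10L) {
  acc <- vapply(seq_len(n_shuffles), function(i) {
    d <- design
    d$y <- sample(d$y)
    fit_value_decoder(d, n_folds)$accuracy
  }, numeric(1))
  list(chance = mean(acc), accuracies = acc)
}

#' Cross-session chance accuracy
#'
#' Decodes foreign value-difference series (from other subjects'
#' sessions) using this session's activity. Each foreign series is
#' circularly rotated at a random offset to randomize block phase,
#' circularly re-indexed to the session's trial count, and decoded; the
#' accuracies are averaged.
#'
#' @param activity a [population_activity()].
#' @param foreign_values list of per-trial value vectors from other
#'   sessions.
#' @param n_pick number of foreign series to draw (with replacement if
#'   the pool is smaller).
#' @param n_folds CV folds.
#' @return list with `chance` and `accuracies`.
#' @export
chance_cross <- function(activity, foreign_values, n_pick = 100L,
                         n_folds = 10L) {
  if (length(foreign_values) == 0) stop("empty foreign value pool")
  n <- nrow(activity$activity)
  picks <- sample.int(length(foreign_values), n_pick, replace = TRUE)
  acc <- vapply(picks, function(k) {
    v <- foreign_values[[k]]
    v <- v[!is.na(v)]
    off <- sample.int(length(v), 1L) - 1L
    v <- v[((seq_len(n) + off - 1L) %% length(v)) + 1L]
    fit_value_decoder(trial_diff_design(activity, v), n_folds)$accuracy
  }, numeric(1))
  list(chance = mean(acc), accuracies = acc)
}

#' Coding axis of a decoder fit
#'
#' The decoder weight vector restricted to (and ordered by) the neurons
#' registered as shared between the sessions being compared.
#'
#' @param fit a `decoder_fit`.
#' @param shared_ids character IDs of the registered shared neurons, in
#'   the common order.
#' @return numeric vector of class `coding_axis` (named by neuron ID).
#' @export
coding_axis <- function(fit, shared_ids = names(fit$weights)) {
  if (!all(shared_ids %in% names(fit$weights)))
    stop("some registered neurons are absent from the decoder fit")
  structure(fit$weights[shared_ids], class = "coding_axis",
            target = fit$target)
}

#' @rdname coding_axis
#' @param c_a,c_b two coding axes over the same registered neurons, in
#'   the same order.
#' @export
coding_axis_angle <- function(c_a, c_b) {
  if (!is.null(names(c_a)) && !is.null(names(c_b)) &&
      !identical(names(c_a), names(c_b)))
    stop("coding axes are not over the same registered neuron order")
  vec_angle(as.numeric(c_a), as.numeric(c_b))
}

#' Relate coding-axis and policy-axis stability
#'
#' Pairs the coding-axis angle and policy-axis angle computed over the
#' same session pairs and reports their Spearman rank correlation with a
#' permutation p-value (a resampling substitute for a mixed-effects
#' test).
#'
#' @param theta_c coding-axis angles (degrees) per session pair.
#' @param theta_p policy-axis angles (degrees) per session pair.
#' @param n_perm permutations.
#' @return list with `pairs` (data frame), `rho`, `p_value`.
#' @export
axis_policy_relation <- function(theta_c, theta_p, n_perm = 1000L) {
  stopifnot(length(theta_c) == length(theta_p))
  if (length(theta_c) < 3L) stop("need at least 3 session pairs")
  rho <- stats::cor(theta_c, theta_p, method = "spearman")
  perm <- vapply(seq_len(n_perm), function(i)
    stats::cor(theta_c, sample(theta_p), method = "spearman"), numeric(1))
  p <- (1 + sum(abs(perm) >= abs(rho))) / (1 + n_perm)
  list(pairs = data.frame(theta_c = theta_c, theta_p = theta_p),
       rho = rho, p_value = p)
}

#' Condition-restricted decoding
#'
#' Restricts the design to adjacent pairs within one task condition
#' (left, right, rewarded or unrewarded choice trials) before
#' differencing, then fits the trial-difference decoder.
#'
#' @param activity a [population_activity()].
#' @param values value signal per trial.
#' @param session the `bandit_session` the activity came from.
#' @param condition `"left"`, `"right"`, `"rewarded"` or `"unrewarded"`.
#' @param min_trials minimum retained condition trials.
#' @param n_folds CV folds.
#' @return a `decoder_fit`.
#' @export
condition_restricted_decode <- function(activity, values, session,
                                        condition = c("left", "right",
                                                      "rewarded",
                                                      "unrewarded"),
                                        min_trials = 12L, n_folds = 10L) {
  condition <- match.arg(condition)
  tr <- session$trials
  sel <- switch(condition,
                left = tr$choice == "L",
                right = tr$choice == "R",
                rewarded = tr$choice != "none" & tr$reward == 1,
                unrewarded = tr$choice != "none" & tr$reward == 0)
  sel <- sel & tr$included
  if (sum(sel & activity$included & !is.na(values)) < min_trials)
    stop("condition '", condition, "' has fewer than ", min_trials,
         " retained trials")
  d <- trial_diff_design(activity, values, subset = which(sel))
  fit_value_decoder(d, n_folds, target = condition)
}
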