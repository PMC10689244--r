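#' Load and validate a run configuration
#'
#' Configurations are plain named lists (or YAML files that parse to
#' one): a `seed`, an `out_dir`, and command-specific blocks (`task`,
#' `teacher`, `neural`, `agent`, `decode`). Unknown fields are kept;
#' missing required blocks raise an error naming the field.
#'
#' @param config named list or path to a YAML file.
#' @param require character vector of blocks/fields that must be
#'   present.
#' @return the validated configuration list.
#' @export
wb_config <- function(config, require = character(0)) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a named list or YAML path")
  missing <- setdiff(require, names(config))
  if (length(missing))
    stop("config is missing required field(s): ",
         paste(missing, collapse = ", "))
  config
}

# Small stable content hash for manifests (djb2 over the canonical JSON).
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  h <- 5381
  for (v in utf8ToInt(as.character(s))) h <- (h * 33 + v) %% 2^31
  sprintf("%08x", h)
}

write_manifest <- function(out_dir, config, files) {
  man <- list(config = config, config_hash = config_hash(config),
              files = sort(files))
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(man)
}

cfg_call <- function(fn, block) do.call(fn, as.list(block %||% list()))
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a synthetic dataset to disk
#'
#' Generates `n_subjects` x `n_sessions` teacher-played sessions with
#' matched ground-truth values and (optionally) neural populations, and
#' writes per-session behavior CSVs, activity CSVs, ground-truth JSON
#' and a manifest listing every emitted file with the configuration and
#' its hash.
#'
#' @param config list or YAML path with fields `seed`, `out_dir`,
#'   `n_subjects`, `n_sessions`, and optional blocks `task`, `teacher`,
#'   `neural` (set `neural: null` to skip activity).
#' @return the manifest, invisibly.
#' @export
wb_simulate <- function(config) {
  config <- wb_config(config, require = c("seed", "out_dir"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  task_cfg <- cfg_call(task_config, config$task)
  teacher <- cfg_call(teacher_spec, config$teacher)
  nsub <- config$n_subjects %||% 1L
  nses <- config$n_sessions %||% 1L
  set.seed(config$seed)
  files <- character(0)
  for (s in seq_len(nsub)) {
    for (k in seq_len(nses)) {
      g <- gen_behavior_session(teacher, task_cfg,
                                meta = list(subject = s, session = k))
      base <- file.path(out, sprintf("sub%02d_ses%03d", s, k))
      write_session(g$session, paste0(base, "_behavior.csv"))
      files <- c(files, paste0(base, "_behavior.csv"),
                 paste0(base, "_behavior.csv.json"))
      truth <- list(teacher = unclass(teacher), subject = s, session = k)
      if (!is.null(config$neural)) {
        spec <- cfg_call(neural_gen_spec, config$neural)
        gp <- gen_population(g$values, spec,
                             included = g$session$trials$included,
                             session_id = basename(base))
        af <- paste0(base, "_activity.csv")
        utils::write.csv(
          data.frame(trial = seq_len(nrow(gp$activity$activity)) - 1L,
                     gp$activity$activity, check.names = FALSE),
          af, row.names = FALSE, quote = FALSE)
        truth$coding_weights <- gp$weights
        files <- c(files, af)
      }
      vf <- paste0(base, "_values.csv")
      utils::write.csv(g$values, vf, row.names = FALSE, quote = FALSE)
      tf <- paste0(base, "_truth.json")
      jsonlite::write_json(truth, tf, auto_unbox = TRUE, digits = NA)
      files <- c(files, vf, tf)
    }
  }
  invisible(write_manifest(out, config, files))
}

#' Train an agent and write checkpoints and logs
#'
#' Wraps [train_agent()]: writes every session's behavior CSV, a
#' line-delimited JSON training log (one record per session), a JSON
#' parameter checkpoint and a manifest.
#'
#' @param config list or YAML path with `seed`, `out_dir` and optional
#'   blocks `task`, `agent` (fields of [train_config()]).
#' @return the `meta_rl_run`, invisibly.
#' @export
wb_train_agent <- function(config) {
  config <- wb_config(config, require = c("seed", "out_dir"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  task_cfg <- cfg_call(task_config, config$task)
  cfg <- cfg_call(train_config, config$agent)
  run <- train_agent(task_cfg, cfg, seed = config$seed)
  files <- character(0)
  for (s in seq_along(run$sessions)) {
    f <- file.path(out, sprintf("session%03d_behavior.csv", s))
    write_session(run$sessions[[s]], f)
    files <- c(files, f, paste0(f, ".json"))
  }
  logf <- file.path(out, "training_log.jsonl")
  con <- file(logf, "w")
  for (i in seq_len(nrow(run$log)))
    writeLines(as.character(jsonlite::toJSON(as.list(run$log[i, ]),
                                             auto_unbox = TRUE,
                                             digits = NA, na = "null")),
               con)
  close(con)
  ckpt <- file.path(out, "checkpoint.json")
  jsonlite::write_json(lapply(run$params, unclass), ckpt, digits = NA)
  files <- c(files, logf, ckpt)
  write_manifest(out, config, files)
  invisible(run)
}

#' Analyze a directory of behavior sessions
#'
#' Runs the history regression and (optionally) the value-model fit on
#' every `*_behavior.csv` under `in_dir`, writing a per-session report
#' table. Corrupt or unfittable files are recorded in the report's
#' `error` column and the run continues.
#'
#' @param config list or YAML path with `seed`, `in_dir`, `out_dir`, and
#'   optional `fit_rl` (logical) and `rl_variant`.
#' @return the report data frame, invisibly.
#' @export
wb_analyze <- function(config) {
  config <- wb_config(config, require = c("seed", "in_dir", "out_dir"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  paths <- sort(list.files(config$in_dir, pattern = "_behavior\\.csv$",
                           full.names = TRUE))
  rows <- lapply(paths, function(p) {
    row <- data.frame(file = basename(p), n_trials = NA_integer_,
                      p_choose_high = NA_real_, optimality = NA_real_,
                      sum_beta_r = NA_real_, sum_beta_c = NA_real_,
                      beta_bias = NA_real_,
                      alpha_rew = NA_real_, alpha_unr = NA_real_,
                      omega = NA_real_, beta_dq = NA_real_,
                      error = "")
    tryCatch({
      ses <- read_session(p)
      row$n_trials <- nrow(ses$trials)
      row$p_choose_high <- p_choose_high(ses)
      row$optimality <- optimality_score(ses)
      hf <- fit_history_logit(ses)
      sw <- summed_history_weights(hf)
      row$sum_beta_r <- sw["sum_r"]; row$sum_beta_c <- sw["sum_c"]
      row$beta_bias <- hf$beta_bias
      if (isTRUE(config$fit_rl)) {
        rf <- fit_rl_model(ses, variant = config$rl_variant %||% "mouse")
        row$alpha_rew <- rf$params$alpha_rew
        row$alpha_unr <- rf$params$alpha_unr
        row$omega <- rf$params$omega
        row$beta_dq <- rf$params$beta_dq
      }
      row
    }, error = function(e) {
      row$error <- conditionMessage(e)
      row
    })
  })
  report <- do.call(rbind, rows)
  rf <- file.path(config$out_dir, "behavior_report.csv")
  utils::write.csv(report, rf, row.names = FALSE)
  write_manifest(config$out_dir, config, rf)
  invisible(report)
}
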