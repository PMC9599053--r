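## Run configuration and orchestration: the programmatic face of the
## command-line tool (inst/scripts/pigtouch.R is a thin wrapper over these
## functions).

#' Default run configuration for a task
#'
#' A run configuration is a nested list: run identity (`subject_id`,
#' `session_id`, `task`, `seed`, `out_dir`, `overwrite`), a `task` parameter
#' section mirroring [shaping_config()], [ddt_config()] or [disc_config()],
#' and an `agent` section mirroring [agent_policy()]. Every default is
#' overridable from a YAML config file or function arguments.
#'
#' @param task one of `"shaping"`, `"ddt"`, `"discrimination"`.
#' @return a `run_config` list.
#' @export
default_run_config <- function(task = c("shaping", "ddt",
                                        "discrimination")) {
  task <- match.arg(task)
  task_params <- switch(task,
    shaping = unclass(shaping_config()),
    ddt = unclass(ddt_config()),
    discrimination = unclass(disc_config()))
  structure(list(subject_id = "sim", session_id = 1L, task = task,
                 seed = 1L, out_dir = NULL, overwrite = "error",
                 start_stage = 0L, task_params = task_params,
                 agent = unclass(agent_policy("perfect"))),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected with an error naming the field; missing keys
#' take the defaults of [default_run_config()].
#'
#' @param path YAML file with the structure of [default_run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading config files requires the 'yaml' package")
  raw <- yaml::read_yaml(path)
  task <- if (!is.null(raw$task)) raw$task else "shaping"
  cfg <- default_run_config(task)
  merge_into <- function(base, new, where) {
    for (key in names(new)) {
      if (!key %in% names(base))
        stop(sprintf("unknown config field '%s' in %s", key, where))
      base[[key]] <- if (is.list(new[[key]]) && is.list(base[[key]]))
        merge_into(base[[key]], new[[key]], paste0(where, "$", key))
        else new[[key]]
    }
    base
  }
  structure(merge_into(unclass(cfg), raw, "config"), class = "run_config")
}

build_task_config <- function(config) {
  ctor <- switch(config$task, shaping = shaping_config, ddt = ddt_config,
                 discrimination = disc_config)
  known <- names(formals(ctor))
  params <- config$task_params[intersect(names(config$task_params), known)]
  do.call(ctor, params)
}

build_agent <- function(config) {
  known <- names(formals(agent_policy))
  do.call(agent_policy, config$agent[intersect(names(config$agent), known)])
}

#' Run one configured session
#'
#' Executes the configured task to completion with the configured simulated
#' subject, writes the per-subject CSV when `out_dir` is set (existing files
#' handled per the `overwrite` policy of [write_subject_csvs()]), and prints
#' the end-of-session summary table.
#'
#' @param config a `run_config` from [default_run_config()] or
#'   [read_run_config()].
#' @param quiet suppress the printed summary.
#' @return the session summary (one-row data frame), invisibly, with the
#'   session log attached as attribute `"log"`.
#' @export
run_session <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  task_cfg <- build_task_config(config)
  agent <- build_agent(config)
  log <- switch(config$task,
    shaping = run_shaping_session(agent, task_cfg,
                                  subject_id = config$subject_id,
                                  session_id = config$session_id,
                                  seed = config$seed,
                                  start_stage = config$start_stage),
    ddt = run_ddt_session(agent, task_cfg, subject_id = config$subject_id,
                          session_id = config$session_id,
                          seed = config$seed),
    discrimination = run_discrimination_session(
      agent, task_cfg, subject_id = config$subject_id,
      session_id = config$session_id, seed = config$seed))
  if (!is.null(config$out_dir))
    write_subject_csvs(log, config$out_dir, overwrite = config$overwrite)
  summary <- summarize_session(log)
  if (!quiet) print(summary, row.names = FALSE)
  attr(summary, "log") <- log
  invisible(summary)
}

#' Simulate a session in one call
#'
#' Convenience wrapper assembling a run configuration from arguments.
#'
#' @param task task name.
#' @param agent an `agent_policy` (or arguments via `...` are ignored).
#' @param subject_id,session_id,seed run identity.
#' @param task_config a task configuration object (defaults per task).
#' @param out_dir optional output directory for the CSV.
#' @param quiet suppress the printed summary.
#' @return as [run_session()].
#' @export
simulate_session <- function(task = c("shaping", "ddt", "discrimination"),
                             agent = agent_policy("perfect"),
                             subject_id = "sim", session_id = 1L, seed = 1L,
                             task_config = NULL, out_dir = NULL,
                             quiet = TRUE) {
  task <- match.arg(task)
  config <- default_run_config(task)
  config$subject_id <- subject_id
  config$session_id <- as.integer(session_id)
  config$seed <- as.integer(seed)
  config$out_dir <- out_dir
  if (!is.null(task_config)) config$task_params <- unclass(task_config)
  config$agent <- unclass(agent)
  run_session(config, quiet = quiet)
}

#' Summarise session CSV files
#'
#' Reads one or more session logs written by this package and emits one
#' summary row per file.
#'
#' @param paths CSV file paths.
#' @param auc_mode AUC definition passed to [discounting_auc()].
#' @return data frame of per-session metrics.
#' @export
summarize_files <- function(paths, auc_mode = "proportion") {
  do.call(rbind, lapply(paths, function(p)
    summarize_session(read_session_csv(p), auc_mode = auc_mode)))
}
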