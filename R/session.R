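## Session engine: ties a clock, an event log, a peripheral controller and a
## seeded RNG together for one subject's session. Internal glue used by the
## task runners.

#' Open a task session
#'
#' Creates the mutable session container the task runners write into: a
#' simulated (or wall) clock, an empty event log, a peripheral controller and
#' a seeded RNG stream. The seed is recorded in the log's header event so any
#' session is reproducible from its CSV alone.
#'
#' @param subject_id subject identifier.
#' @param session_id session number (integer >= 1).
#' @param task one of `"shaping"`, `"ddt"`, `"discrimination"`.
#' @param seed integer seed driving every stochastic draw in the session
#'   (stimulus positions, trial shuffles, agent behavior).
#' @param clock a `task_clock`; defaults to a fresh simulated clock.
#' @param peripheral a `peripheral_state`.
#' @return a `task_session` environment.
#' @export
task_session <- function(subject_id, session_id, task, seed,
                         clock = sim_clock(),
                         peripheral = peripheral_state()) {
  task <- match.arg(task, TASK_NAMES)
  seed <- as.integer(seed)
  stopifnot(!is.na(seed))
  sess <- new.env(parent = emptyenv())
  sess$subject_id <- subject_id
  sess$session_id <- as.integer(session_id)
  sess$task <- task
  sess$seed <- seed
  sess$clock <- clock
  sess$log <- event_log()
  sess$periph <- peripheral
  sess$phase <- ""
  class(sess) <- "task_session"
  set.seed(seed)
  s_emit(sess, "manual_note",
         payload = payload_string(session_header = 1, seed = seed,
                                  task = task))
  sess
}

#' @export
print.task_session <- function(x, ...) {
  cat(sprintf("<task_session: %s session %d (%s), %d events, t = %.3f s>\n",
              x$subject_id, x$session_id, x$task, log_length(x$log),
              clock_now(x$clock)))
  invisible(x)
}

## append one event at the current clock time
s_emit <- function(sess, event_type, trial_index = NA_integer_,
                   x = NA_real_, y = NA_real_, payload = "",
                   phase = sess$phase) {
  log_event(sess$log, event_record(
    subject_id = sess$subject_id, session_id = sess$session_id,
    task = sess$task, event_type = event_type,
    timestamp = clock_now(sess$clock), phase = phase,
    trial_index = trial_index, x = x, y = y, payload = payload))
}

## dispatch a peripheral cue and log the resulting device events
s_cue <- function(sess, cue, trial_index = NA_integer_) {
  out <- dispatch_cue(sess$periph, cue, clock_now(sess$clock))
  sess$periph <- out$state
  for (ev in out$events)
    s_emit(sess, ev$event_type, trial_index = trial_index,
           payload = ev$payload)
  invisible(sess)
}

## deliver n pellets as n dispenser-cycle cues, spaced cycle_time apart
s_pellets <- function(sess, n, trial_index, cycle_time = 0) {
  for (i in seq_len(n)) {
    if (i > 1L && cycle_time > 0) clock_advance(sess$clock, cycle_time)
    s_cue(sess, "1", trial_index = trial_index)
  }
  invisible(sess)
}

## sound an audio cue and log it
s_audio <- function(sess, purpose, trial_index = NA_integer_) {
  cue <- play_cue(purpose)
  s_emit(sess, "tone", trial_index = trial_index,
         payload = payload_string(purpose = purpose,
                                  frequency_hz = cue$frequency,
                                  duration_s = cue$duration))
  invisible(cue)
}

## hit-test a touch; non-registering touches (press misses, all releases)
## are logged as raw touch events. Returns the registered box id or NA.
s_touch <- function(sess, geometry, touch, trial_index) {
  hit <- hit_test(geometry, touch)
  if (!is.na(hit)) return(hit)
  s_emit(sess, "touch", trial_index = trial_index, x = touch$x,
         y = touch$y, payload = payload_string(kind = touch$kind))
  NA_character_
}

## finish a session: return the log data frame
session_log <- function(sess) as.data.frame(sess$log)
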