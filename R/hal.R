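## Peripheral cue protocol and audio cues.
##
## The deployed rig drove a pellet dispenser and a tone generator from a
## second node over a radio link: single-character cues, "1" cycling the
## dispenser once and "2" turning the tone on for 1 s. The link is modelled
## here as an ordered lossless channel; stray tokens (radio pickup) are
## logged, never fatal. An optional watchdog forces outputs off when no
## refreshing cue arrives within a timeout, so a corrupted "on" cannot latch
## a device on.

#' Default cue table
#'
#' Maps received cue tokens to peripheral actions; configurable so deployments
#' can remap tokens.
#'
#' @return named character vector, token -> action (`"pellet"` or `"tone"`).
#' @export
default_cue_table <- function() c("1" = "pellet", "2" = "tone")

#' Create a peripheral controller state
#'
#' @param cue_table token -> action map, see [default_cue_table()].
#' @param tone_duration seconds the tone stays on per `"tone"` cue (default
#'   1 s). A second tone cue while on extends the off time (non-retriggering
#'   extension).
#' @param watchdog_timeout seconds after the last received cue at which all
#'   outputs are forced off, or `NA` to disable the watchdog (default).
#' @return a `peripheral_state` list: `pellet_cycles` counts dispenser
#'   cycles, `tone_on_until` is the scheduled tone-off time (`NA` = off),
#'   `last_cue_at` the time of the last received cue.
#' @export
peripheral_state <- function(cue_table = default_cue_table(),
                             tone_duration = 1, watchdog_timeout = NA) {
  stopifnot(is.character(cue_table), !is.null(names(cue_table)),
            tone_duration > 0,
            is.na(watchdog_timeout) || watchdog_timeout > 0)
  structure(list(pellet_cycles = 0L, tone_on_until = NA_real_,
                 last_cue_at = NA_real_, cue_table = cue_table,
                 tone_duration = tone_duration,
                 watchdog_timeout = watchdog_timeout),
            class = "peripheral_state")
}

#' Is the peripheral tone currently on?
#' @param state a `peripheral_state`.
#' @param now current time, seconds.
#' @return logical.
#' @export
tone_is_on <- function(state, now) {
  !is.na(state$tone_on_until) && now < state$tone_on_until
}

#' Dispatch one received cue to the peripherals
#'
#' A `"pellet"` cue increments the dispenser cycle count; a `"tone"` cue
#' turns the tone on until `now + tone_duration` (extending it if already
#' on). An unknown token changes no output and is logged as a stray-signal
#' note, so radio pickup cannot trigger hardware.
#'
#' @param state a `peripheral_state`.
#' @param cue received token (character scalar).
#' @param now receipt time, seconds.
#' @return list with `state` (updated) and `events` (list of partial event
#'   descriptions: `event_type` + `payload`) for the session logger.
#' @export
dispatch_cue <- function(state, cue, now) {
  stopifnot(inherits(state, "peripheral_state"), is.character(cue),
            length(cue) == 1L)
  action <- if (cue %in% names(state$cue_table))
    state$cue_table[[cue]] else "unknown"
  state$last_cue_at <- now
  events <- list()
  if (action == "pellet") {
    state$pellet_cycles <- state$pellet_cycles + 1L
    events[[1]] <- list(event_type = "pellet_command",
                        payload = payload_string(cue = cue,
                                                 cycle = state$pellet_cycles))
  } else if (action == "tone") {
    state$tone_on_until <- now + state$tone_duration
    events[[1]] <- list(event_type = "tone",
                        payload = payload_string(
                          cue = cue, on_until = state$tone_on_until))
  } else {
    events[[1]] <- list(event_type = "manual_note",
                        payload = payload_string(stray_cue = cue))
  }
  list(state = state, events = events)
}

#' Run the peripheral watchdog
#'
#' With the watchdog enabled (timeout `T`), any output still on more than
#' `T` seconds after the last received cue is forced off and the shutdown is
#' logged. A refreshing cue before the timeout restarts the countdown. With
#' the watchdog disabled the state is returned unchanged.
#'
#' @param state a `peripheral_state`.
#' @param now current time, seconds.
#' @return list with `state` and `events` as in [dispatch_cue()].
#' @export
watchdog_tick <- function(state, now) {
  stopifnot(inherits(state, "peripheral_state"))
  events <- list()
  if (!is.na(state$watchdog_timeout) && !is.na(state$last_cue_at)) {
    deadline <- state$last_cue_at + state$watchdog_timeout
    if (now > deadline && tone_is_on(state, now)) {
      state$tone_on_until <- deadline
      events[[1]] <- list(event_type = "manual_note",
                          payload = payload_string(watchdog = "tone_off",
                                                   at = deadline))
    }
  }
  list(state = state, events = events)
}

## ---- audio cues --------------------------------------------------------

## purpose -> (frequency Hz, duration s); the press-feedback tone matches the
## Sonalert on the rig, the trial-start tone is distinct so subjects orient
## to the screen when a trial becomes available.
AUDIO_CUES <- list(
  response_feedback = list(frequency = 2900, duration = 0.5),
  trial_start = list(frequency = 7500, duration = 0.5),
  reinforcement = list(frequency = 2900, duration = 1)
)

#' Build the audio cue for a purpose
#'
#' `response_feedback` is a 2900 Hz tone emitted on every registered
#' response; `trial_start` is a 7500 Hz tone marking button availability;
#' `reinforcement` reuses the 2900 Hz feedback frequency for a longer burst.
#'
#' @param purpose one of `"response_feedback"`, `"trial_start"`,
#'   `"reinforcement"`.
#' @return an `audio_cue` list with `frequency` (Hz), `duration` (s),
#'   `purpose`.
#' @export
play_cue <- function(purpose = c("response_feedback", "trial_start",
                                 "reinforcement")) {
  purpose <- match.arg(purpose)
  cue <- AUDIO_CUES[[purpose]]
  structure(list(frequency = cue$frequency, duration = cue$duration,
                 purpose = purpose), class = "audio_cue")
}
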