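## Response shaping: Pavlovian autoshaping (stage 0) followed by staged
## reduction of the reinforced screen region (stages 1-3), with an optional
## stage 4 that gradually shrinks the box to shape precision. Subjects move
## up automatically once they accumulate each stage's press threshold.

#' Configure the response-shaping task
#'
#' Stage progression thresholds default to 20 reinforced presses to leave
#' stage 0, then 15, 15 and 40; after the stage-3 threshold the subject is
#' flagged ready for testing (unless stage 4 is enabled).
#'
#' @param thresholds reinforced-press counts required to leave stages 0-3.
#' @param fr_stage3 fixed-ratio requirement applied at stages 3 and 4
#'   (stages 0-2 are always FR-1); raise to 3 or 5 when later tasks need a
#'   higher response requirement.
#' @param autoshape_delay seconds from illumination to the noncontingent
#'   pellet in stage 0 (default 10).
#' @param stage4 enable the optional shrinking-box stage after stage 3.
#' @param stage4_threshold reinforced presses to complete stage 4.
#' @param stage4_decrement box side shrink (screen fraction) per reinforced
#'   trial in stage 4.
#' @param stage4_min smallest stage-4 box side (screen fraction).
#' @param corner_offset stage-3/4 offset of corner positions from the screen
#'   edge (screen fraction).
#' @param hit_extension_above invisible upward hit extension applied to
#'   shaping boxes (screen fraction, default 0 = off).
#' @param response_window seconds without a registered response before a
#'   trial is scored as an omission (stages 1+).
#' @param iti intertrial interval, seconds (kept under 20 s so subjects do
#'   not disengage).
#' @return a `shaping_config` list.
#' @export
shaping_config <- function(thresholds = c(20L, 15L, 15L, 40L),
                           fr_stage3 = 1L, autoshape_delay = 10,
                           stage4 = FALSE, stage4_threshold = 40L,
                           stage4_decrement = 0.02, stage4_min = 0.1,
                           corner_offset = 0.05, hit_extension_above = 0,
                           response_window = 60, iti = 15) {
  stopifnot(length(thresholds) == 4L, all(thresholds >= 1L),
            fr_stage3 >= 1L, autoshape_delay > 0, stage4_threshold >= 1L,
            stage4_decrement >= 0, stage4_min > 0, corner_offset >= 0,
            hit_extension_above >= 0, response_window > 0, iti >= 0,
            iti < 20)
  structure(list(thresholds = as.integer(thresholds),
                 fr_stage3 = as.integer(fr_stage3),
                 autoshape_delay = autoshape_delay, stage4 = stage4,
                 stage4_threshold = as.integer(stage4_threshold),
                 stage4_decrement = stage4_decrement,
                 stage4_min = stage4_min, corner_offset = corner_offset,
                 hit_extension_above = hit_extension_above,
                 response_window = response_window, iti = iti),
            class = "shaping_config")
}

#' Current state of a shaping session
#'
#' @param stage current stage, 0-4.
#' @param presses_in_stage reinforced presses accumulated in the current
#'   stage (always below the stage threshold).
#' @param config a `shaping_config`.
#' @return a `shaping_state` list; `complete` flags readiness for testing,
#'   `stage4_size` the current stage-4 box side.
#' @export
shaping_state <- function(stage = 0L, presses_in_stage = 0L,
                          config = shaping_config()) {
  stage <- as.integer(stage)
  stopifnot(stage %in% 0:4, presses_in_stage >= 0L)
  structure(list(stage = stage,
                 presses_in_stage = as.integer(presses_in_stage),
                 complete = FALSE, stage4_size = 0.4),
            class = "shaping_state")
}

stage_threshold <- function(state, config) {
  if (state$stage <= 3L) config$thresholds[[state$stage + 1L]]
  else config$stage4_threshold
}

#' Draw the screen layout for a shaping stage
#'
#' Stages 0 and 1 illuminate the whole screen as one yellow box; stage 2
#' presents a full-width yellow rectangle one third of the screen high at one
#' of three heights drawn uniformly; stage 3 a yellow square with side 40% of
#' the screen width at one of five positions (just offset from each corner,
#' and centre) drawn uniformly; stage 4 the same five positions with the
#' current (shrinking) box side. Position draws consume the session RNG
#' stream.
#'
#' @param stage stage number, 0-4.
#' @param config a `shaping_config`.
#' @param stage4_size current stage-4 box side (screen fraction).
#' @return a `screen_geometry` with one active box, id `"target"`.
#' @export
shaping_geometry <- function(stage, config = shaping_config(),
                             stage4_size = 0.4) {
  stage <- as.integer(stage)
  if (!stage %in% 0:4) stop("invalid shaping stage: ", stage)
  fr <- if (stage >= 3L) config$fr_stage3 else 1L
  ext <- config$hit_extension_above
  if (stage <= 1L) {
    box <- response_box("target", 0, 0, 1, 1, "yellow",
                        fr_requirement = 1L)
  } else if (stage == 2L) {
    y <- c(0, 1, 2)[[sample.int(3L, 1L)]] / 3
    box <- response_box("target", 0, y, 1, 1 / 3, "yellow",
                        hit_extension_above = ext, fr_requirement = 1L)
  } else {
    side <- if (stage == 3L) 0.40 else stage4_size
    off <- config$corner_offset
    lo <- off
    hi <- 1 - off - side
    mid <- (1 - side) / 2
    pos <- list(c(lo, lo), c(hi, lo), c(lo, hi), c(hi, hi), c(mid, mid))
    p <- pos[[sample.int(5L, 1L)]]
    box <- response_box("target", p[[1]], p[[2]], side, side, "yellow",
                        hit_extension_above = ext, fr_requirement = fr)
  }
  screen_geometry(box)
}

#' Advance the shaping state after a reinforced press
#'
#' Increments the in-stage press count; on reaching the stage threshold the
#' stage increments (never decreases) and the count resets. After the
#' stage-3 threshold the state is flagged complete ("ready for testing")
#' unless stage 4 is enabled, which completes after its own threshold.
#'
#' @param state a `shaping_state`.
#' @param config a `shaping_config`.
#' @return list with `state` (updated) and `advanced` (logical: a stage
#'   boundary was crossed).
#' @export
shaping_advance <- function(state, config = shaping_config()) {
  stopifnot(inherits(state, "shaping_state"))
  state$presses_in_stage <- state$presses_in_stage + 1L
  advanced <- FALSE
  if (state$presses_in_stage >= stage_threshold(state, config)) {
    advanced <- TRUE
    state$presses_in_stage <- 0L
    if (state$stage == 3L && !config$stage4) {
      state$complete <- TRUE
    } else if (state$stage >= 4L) {
      state$complete <- TRUE
    } else {
      state$stage <- state$stage + 1L
    }
  }
  list(state = state, advanced = advanced)
}

#' Run one autoshaping (stage 0) illumination
#'
#' The whole screen illuminates; a pellet is delivered noncontingently 10 s
#' after illumination, but an FR-1 schedule is in effect throughout, so a
#' press anywhere on the screen is reinforced immediately and cancels the
#' pending noncontingent delivery — exactly one pellet per illumination.
#' Contingent presses count toward the stage threshold; noncontingent
#' deliveries do not.
#'
#' @param sess a `task_session`.
#' @param agent an `agent_policy`.
#' @param config a `shaping_config`.
#' @param trial_index index of this illumination.
#' @return list with `counted` (logical: a press was reinforced) and
#'   `press_time` (seconds from illumination, or `NA`).
#' @export
autoshape_step <- function(sess, agent, config = shaping_config(),
                           trial_index = 0L) {
  geom <- shaping_geometry(0L, config)
  s_audio(sess, "trial_start", trial_index)
  s_emit(sess, "trial_start", trial_index,
         payload = payload_string(trial_type = "autoshape"))
  t0 <- clock_now(sess$clock)
  omitted <- agent$omission_prob > 0 && stats::runif(1) < agent$omission_prob
  lat <- if (agent$kind == "nonresponder" || omitted) Inf
         else agent_latency(agent)
  if (lat >= config$autoshape_delay) {
    clock_advance(sess$clock, config$autoshape_delay)
    s_pellets(sess, 1L, trial_index)
    return(list(counted = FALSE, press_time = NA_real_))
  }
  clock_advance(sess$clock, lat)
  touches <- emit_touch(agent, geom[["target"]],
                        timestamp = clock_now(sess$clock))
  hit <- s_touch(sess, geom, touches[[1]], trial_index)
  if (is.na(hit)) {
    # scatter pushed the press off-screen edge case: falls back to the
    # noncontingent delivery at the scheduled time
    clock_advance(sess$clock, config$autoshape_delay - lat)
    s_pellets(sess, 1L, trial_index)
    return(list(counted = FALSE, press_time = NA_real_))
  }
  s_emit(sess, "response_registered", trial_index,
         x = touches[[1]]$x, y = touches[[1]]$y,
         payload = payload_string(box = hit, fr_press = 1, fr_of = 1))
  s_audio(sess, "response_feedback", trial_index)
  s_emit(sess, "reinforcement", trial_index,
         payload = payload_string(magnitude = 1, contingent = 1))
  s_pellets(sess, 1L, trial_index)
  list(counted = TRUE, press_time = clock_now(sess$clock) - t0)
}

## one stage-1..4 shaping trial; returns TRUE if the trial was reinforced
shaping_trial <- function(sess, agent, state, config, trial_index) {
  geom <- shaping_geometry(state$stage, config, state$stage4_size)
  box <- geom[["target"]]
  s_audio(sess, "trial_start", trial_index)
  s_emit(sess, "trial_start", trial_index,
         payload = payload_string(trial_type = "shaping_press",
                                  stage = state$stage,
                                  box_x = box$x, box_y = box$y,
                                  box_w = box$w))
  if (agent$omission_prob > 0 && stats::runif(1) < agent$omission_prob) {
    clock_advance(sess$clock, config$response_window)
    s_emit(sess, "omission", trial_index)
    return(FALSE)
  }
  elapsed <- 0
  registered <- 0L
  repeat {
    lat <- max(agent_latency(agent), 0.05)
    if (agent$kind == "nonresponder" ||
        elapsed + lat > config$response_window) {
      clock_advance(sess$clock, config$response_window - elapsed)
      if (registered == 0L) s_emit(sess, "omission", trial_index)
      return(FALSE)
    }
    elapsed <- elapsed + lat
    clock_advance(sess$clock, lat)
    touches <- emit_touch(agent, box, timestamp = clock_now(sess$clock))
    hit <- s_touch(sess, geom, touches[[1]], trial_index)
    if (is.na(hit)) next
    reg <- fr_register(box)
    box <- reg$box
    registered <- registered + 1L
    s_emit(sess, "response_registered", trial_index,
           x = touches[[1]]$x, y = touches[[1]]$y,
           payload = payload_string(box = hit, fr_press = registered,
                                    fr_of = box$fr_requirement))
    s_audio(sess, "response_feedback", trial_index)
    if (reg$fulfilled) {
      s_emit(sess, "reinforcement", trial_index,
             payload = payload_string(magnitude = 1, contingent = 1))
      s_pellets(sess, 1L, trial_index)
      return(TRUE)
    }
  }
}

#' Run a complete shaping session with a simulated subject
#'
#' Steps the shaping state machine trial by trial from `start_stage` until
#' the subject is flagged ready for testing or `max_trials` illuminations
#' have run. Subjects that completed a stage in a previous session can be
#' started at the next stage.
#'
#' @param agent an `agent_policy`.
#' @param config a `shaping_config`.
#' @param subject_id,session_id log identity.
#' @param seed session seed; drives every stochastic draw.
#' @param start_stage stage to begin at (0-4).
#' @param max_trials safety cap on trials.
#' @return the session log as a data frame (see [session_trials()] and
#'   [summarize_session()]), with the final `shaping_state` attached as
#'   attribute `"final_state"`.
#' @export
run_shaping_session <- function(agent, config = shaping_config(),
                                subject_id = "sim", session_id = 1L,
                                seed = 1L, start_stage = 0L,
                                max_trials = 1000L) {
  sess <- task_session(subject_id, session_id, "shaping", seed)
  state <- shaping_state(stage = start_stage, config = config)
  trial <- 0L
  while (!state$complete && trial < max_trials) {
    sess$phase <- paste0("stage", state$stage)
    reinforced <- if (state$stage == 0L) {
      autoshape_step(sess, agent, config, trial)$counted
    } else {
      shaping_trial(sess, agent, state, config, trial)
    }
    if (reinforced) {
      if (state$stage == 4L)
        state$stage4_size <- max(config$stage4_min,
                                 state$stage4_size - config$stage4_decrement)
      adv <- shaping_advance(state, config)
      if (adv$advanced)
        s_emit(sess, "stage_advance", trial,
               payload = payload_string(
                 stage = if (adv$state$complete) "complete"
                         else adv$state$stage))
      state <- adv$state
    }
    clock_advance(sess$clock, config$iti)
    trial <- trial + 1L
  }
  structure(session_log(sess), final_state = state)
}
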