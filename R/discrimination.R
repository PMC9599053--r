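## Color discrimination task.
##
## A trial starts with a centre (sample) box; responding to it brings up two
## choice boxes, left and right, with sides assigned pseudorandomly. In the
## simple and correction phases yellow is the reinforced color and blue the
## comparison. The correction phase re-presents any incorrectly answered
## trial with the same layout but the incorrect box inactive, forcing the
## correct choice. The conditional (match-to-sample) phase shows a green or
## blue sample in the centre and reinforces only choices of that color; a
## fixed-ratio requirement (e.g. FR-3) can be put on the sample and choice
## buttons to increase salience.

DISC_PHASES <- c("simple", "correction_enabled", "conditional")

#' Configure the color discrimination task
#'
#' @param phase one of `"simple"`, `"correction_enabled"`, `"conditional"`.
#' @param n_trials scored (non-correction) trials per session.
#' @param fr_sample fixed-ratio requirement on the centre sample box (1 or
#'   3 in practice).
#' @param fr_choice fixed-ratio requirement on the choice boxes.
#' @param target_color reinforced color in the simple/correction phases.
#' @param comparison_color the unreinforced comparison color.
#' @param sample_colors colors the conditional sample is drawn from.
#' @param reward_magnitude pellets per correct choice.
#' @param side_block block length for pseudorandom side balancing.
#' @param max_side_run longest allowed run of same-side correct positions.
#' @param iti intertrial interval, seconds (< 20 s).
#' @param response_window omission window, seconds.
#' @param hit_extension_above invisible upward hit extension (screen
#'   fraction, default 0).
#' @return a `disc_config` list.
#' @export
disc_config <- function(phase = DISC_PHASES, n_trials = 36L,
                        fr_sample = 1L, fr_choice = 1L,
                        target_color = "yellow", comparison_color = "blue",
                        sample_colors = c("green", "blue"),
                        reward_magnitude = 1L, side_block = 6L,
                        max_side_run = 3L, iti = 15, response_window = 60,
                        hit_extension_above = 0) {
  phase <- match.arg(phase)
  stopifnot(n_trials >= 1L, fr_sample >= 1L, fr_choice >= 1L,
            target_color %in% BOX_COLORS, comparison_color %in% BOX_COLORS,
            target_color != comparison_color,
            all(sample_colors %in% BOX_COLORS), length(sample_colors) == 2L,
            reward_magnitude >= 1L, side_block >= 2L,
            side_block %% 2L == 0L, max_side_run >= 1L, iti >= 0, iti < 20,
            response_window > 0, hit_extension_above >= 0)
  structure(list(phase = phase, n_trials = as.integer(n_trials),
                 fr_sample = as.integer(fr_sample),
                 fr_choice = as.integer(fr_choice),
                 target_color = target_color,
                 comparison_color = comparison_color,
                 sample_colors = sample_colors,
                 reward_magnitude = as.integer(reward_magnitude),
                 side_block = as.integer(side_block),
                 max_side_run = as.integer(max_side_run),
                 iti = iti, response_window = response_window,
                 hit_extension_above = hit_extension_above),
            class = "disc_config")
}

#' Pseudorandom side sequence
#'
#' Balanced within consecutive blocks (equal left/right counts per block)
#' with runs of the same correct side capped at `max_run`, drawn by
#' rejection sampling from the session RNG.
#'
#' @param n sequence length.
#' @param block block length for balancing (even).
#' @param max_run longest allowed same-side run.
#' @return character vector of `"left"`/`"right"`.
#' @export
pseudorandom_sides <- function(n, block = 6L, max_run = 3L) {
  stopifnot(n >= 1L, block %% 2L == 0L, max_run >= 1L)
  longest_run <- function(x) max(rle(x)$lengths)
  sides <- character(0)
  while (length(sides) < n) {
    repeat {
      cand <- sample(rep(c("left", "right"), each = block %/% 2L))
      tail_part <- sides[seq_len(min(length(sides), max_run))
                         + max(0L, length(sides) - max_run)]
      if (longest_run(c(tail_part, cand)) <= max_run) break
    }
    sides <- c(sides, cand)
  }
  sides[seq_len(n)]
}

disc_layout <- function(config, correct_color, correct_side) {
  other_side <- if (correct_side == "left") "right" else "left"
  comparison <- if (config$phase == "conditional")
    setdiff(config$sample_colors, correct_color) else config$comparison_color
  sample_color <- if (config$phase == "conditional") correct_color
                  else config$target_color
  xs <- c(left = 0.08, right = 0.62)
  list(correct_color = correct_color, comparison_color = comparison,
       correct_side = correct_side, other_side = other_side,
       sample_color = sample_color, xs = xs)
}

## geometry for the sample stage: centre box only
disc_sample_geometry <- function(config, layout) {
  screen_geometry(response_box("sample", 0.35, 0.35, 0.30, 0.30,
                               color = layout$sample_color,
                               hit_extension_above =
                                 config$hit_extension_above,
                               fr_requirement = config$fr_sample))
}

## geometry for the choice stage; on a correction trial the incorrect box is
## rendered but inactive
disc_choice_geometry <- function(config, layout, correction = FALSE) {
  make <- function(side, color, active) {
    response_box(side, layout$xs[[side]], 0.35, 0.30, 0.30, color = color,
                 active = active,
                 hit_extension_above = config$hit_extension_above,
                 fr_requirement = config$fr_choice)
  }
  screen_geometry(
    make(layout$correct_side, layout$correct_color, TRUE),
    make(layout$other_side, layout$comparison_color, !correction))
}

disc_options <- function(layout, correction = FALSE) {
  data.frame(id = c(layout$correct_side, layout$other_side),
             magnitude = c(1, 0), delay = 0,
             side = c(layout$correct_side, layout$other_side),
             color = c(layout$correct_color, layout$comparison_color),
             active = c(TRUE, !correction),
             stringsAsFactors = FALSE)
}

## press a box until its FR requirement is fulfilled or the window closes.
## `choice_info(hit)` (optional) supplies extra payload keys for the
## fulfilling press (realized choice, side, color). Returns the id of the
## box whose FR was fulfilled, or NA.
press_until_fulfilled <- function(sess, agent, geom, target_id, ti,
                                  window, choice_info = NULL) {
  elapsed <- 0
  registered <- 0L
  presses <- integer(0)
  repeat {
    lat <- max(agent_latency(agent), 0.05)
    if (agent$kind == "nonresponder" || elapsed + lat > window)
      return(list(fulfilled = NA_character_, elapsed = elapsed,
                  registered = registered))
    elapsed <- elapsed + lat
    clock_advance(sess$clock, lat)
    touches <- emit_touch(agent, geom[[target_id]],
                          timestamp = clock_now(sess$clock))
    hit <- s_touch(sess, geom, touches[[1]], ti)
    if (is.na(hit)) next
    reg <- fr_register(geom[[hit]])
    req <- geom[[hit]]$fr_requirement
    geom[[hit]] <- reg$box
    registered <- registered + 1L
    presses[hit] <- (if (hit %in% names(presses)) presses[[hit]] else 0L) + 1L
    extra <- if (reg$fulfilled && !is.null(choice_info)) choice_info(hit)
             else list()
    payload <- do.call(payload_string,
                       c(list(box = hit, fr_press = presses[[hit]],
                              fr_of = req), extra))
    s_emit(sess, "response_registered", ti,
           x = touches[[1]]$x, y = touches[[1]]$y, payload = payload)
    s_audio(sess, "response_feedback", ti)
    if (reg$fulfilled)
      return(list(fulfilled = hit, elapsed = elapsed,
                  registered = registered))
  }
}

#' Run one discrimination trial
#'
#' Presents the sample, then the choice boxes, scores the choice and — in
#' the correction and conditional phases — schedules a correction trial
#' after an incorrect choice. See the package task description for the full
#' contingencies.
#'
#' @param sess a `task_session`.
#' @param state a `disc_state` as returned by [disc_state()] /
#'   previous calls.
#' @param agent an `agent_policy`.
#' @param config a `disc_config`.
#' @param trial_index trial number.
#' @param correct_side precomputed pseudorandom side for a fresh trial
#'   (ignored when a correction is pending).
#' @return list with the updated `state`, `choice`
#'   (`"correct"`/`"incorrect"`/`"none"`), `omitted`, and `correction`
#'   (was this a correction trial).
#' @export
run_discrimination_trial <- function(sess, state, agent,
                                     config = disc_config(),
                                     trial_index = 0L,
                                     correct_side = "left") {
  stopifnot(inherits(state, "disc_state"))
  ti <- trial_index
  correction <- !is.null(state$pending_correction)
  layout <- if (correction) state$pending_correction
            else disc_layout(config,
                             correct_color = if (config$phase == "conditional")
                               config$sample_colors[[sample.int(2L, 1L)]]
                             else config$target_color,
                             correct_side = correct_side)
  s_audio(sess, "trial_start", ti)
  s_emit(sess, "trial_start", ti,
         payload = payload_string(
           trial_type = if (correction) "correction" else "choice",
           phase = config$phase,
           sample_color = if (config$phase == "conditional")
             layout$sample_color else NA,
           correct_side = layout$correct_side,
           correct_color = layout$correct_color))
  if (correction)
    s_emit(sess, "correction_start", ti,
           payload = payload_string(inactive_side = layout$other_side))
  end_trial <- function(choice, state) {
    clock_advance(sess$clock, config$iti)
    list(state = state, choice = choice, omitted = choice == "none",
         correction = correction)
  }
  omit <- agent$omission_prob > 0 && stats::runif(1) < agent$omission_prob
  if (omit || agent$kind == "nonresponder") {
    clock_advance(sess$clock, config$response_window)
    s_emit(sess, "omission", ti)
    state$pending_correction <- NULL
    return(end_trial("none", state))
  }
  # sample stage: centre box, FR fr_sample
  sample_geom <- disc_sample_geometry(config, layout)
  samp <- press_until_fulfilled(sess, agent, sample_geom, "sample", ti,
                                config$response_window)
  if (is.na(samp$fulfilled)) {
    clock_advance(sess$clock, config$response_window - samp$elapsed)
    if (samp$registered == 0L) s_emit(sess, "omission", ti)
    state$pending_correction <- NULL
    return(end_trial("none", state))
  }
  # choice stage
  geom <- disc_choice_geometry(config, layout, correction)
  target <- agent_choose(agent, disc_options(layout, correction))
  if (is.na(target)) {
    clock_advance(sess$clock, config$response_window)
    s_emit(sess, "omission", ti)
    state$pending_correction <- NULL
    return(end_trial("none", state))
  }
  choice_info <- function(hit) {
    ok <- hit == layout$correct_side
    list(choice = if (ok) "correct" else "incorrect", side = hit,
         color = if (ok) layout$correct_color else layout$comparison_color)
  }
  res <- press_until_fulfilled(sess, agent, geom, target, ti,
                               config$response_window,
                               choice_info = choice_info)
  if (is.na(res$fulfilled)) {
    clock_advance(sess$clock, config$response_window - res$elapsed)
    if (res$registered == 0L) s_emit(sess, "omission", ti)
    state$pending_correction <- NULL
    return(end_trial("none", state))
  }
  chosen_side <- res$fulfilled
  correct <- chosen_side == layout$correct_side
  if (correct) {
    s_emit(sess, "reinforcement", ti,
           payload = payload_string(choice = "correct",
                                    magnitude = config$reward_magnitude))
    s_pellets(sess, config$reward_magnitude, ti)
    state$pending_correction <- NULL
  } else {
    state$pending_correction <-
      if (config$phase != "simple") layout else NULL
  }
  end_trial(if (correct) "correct" else "incorrect", state)
}

#' Initial discrimination state
#'
#' @param config a `disc_config`.
#' @return a `disc_state` list with no pending correction.
#' @export
disc_state <- function(config = disc_config()) {
  structure(list(phase = config$phase, pending_correction = NULL),
            class = "disc_state")
}

#' Run a complete discrimination session with a simulated subject
#'
#' Runs `n_trials` scored trials; correction trials (inserted after
#' incorrect choices in the correction and conditional phases) do not count
#' toward `n_trials` and are excluded from the accuracy denominator by the
#' analysis functions.
#'
#' @param agent an `agent_policy`.
#' @param config a `disc_config`.
#' @param subject_id,session_id log identity.
#' @param seed session seed.
#' @param max_trials safety cap on total trials including corrections.
#' @return the session log as a data frame.
#' @export
run_discrimination_session <- function(agent, config = disc_config(),
                                       subject_id = "sim", session_id = 1L,
                                       seed = 1L, max_trials = 10L *
                                         config$n_trials) {
  sess <- task_session(subject_id, session_id, "discrimination", seed)
  sess$phase <- config$phase
  state <- disc_state(config)
  sides <- pseudorandom_sides(config$n_trials, config$side_block,
                              config$max_side_run)
  scored <- 0L
  ti <- 0L
  # a trailing correction is still run after the last scored trial
  while ((scored < config$n_trials ||
            !is.null(state$pending_correction)) && ti < max_trials) {
    out <- run_discrimination_trial(
      sess, state, agent, config, trial_index = ti,
      correct_side = sides[[min(scored + 1L, config$n_trials)]])
    state <- out$state
    if (!out$correction) scored <- scored + 1L
    ti <- ti + 1L
  }
  session_log(sess)
}
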