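## Delay discounting task (DDT).
##
## Two buttons: Large delivers 4 pellets, Small 1. A session opens as a
## magnitude discrimination (both immediate) and, once preference for Large
## is established, delays to the Large reward are introduced in ascending
## blocks within the session (default 0, 5, 10, 20 s, incrementing every 12
## trials). Each block gives 6 forced-choice trials (only one button active;
## half Large, half Small, shuffled) followed by 6 free-choice trials.

#' Configure the delay discounting task
#'
#' @param large_magnitude pellets delivered by the Large button (default 4).
#' @param small_magnitude pellets delivered by the Small button (default 1).
#' @param delays ascending delays (seconds) applied to the Large reward,
#'   one block per delay. `c(0)` gives a pure magnitude discrimination.
#' @param trials_per_block trials per delay block (default 12).
#' @param forced_per_block forced-choice trials opening each block (must be
#'   even: half Large-only, half Small-only).
#' @param free_per_block free-choice trials closing each block;
#'   `forced_per_block + free_per_block` must equal `trials_per_block`.
#' @param large_side which side the Large button occupies (`"left"` or
#'   `"right"`), fixed for the session.
#' @param iti intertrial interval, seconds (< 20 s).
#' @param response_window seconds before an unanswered trial is scored as an
#'   omission.
#' @param pellet_cycle_time spacing between consecutive dispenser-cycle
#'   commands, seconds (0 = command the full magnitude at once).
#' @param hit_extension_above invisible upward hit extension on both
#'   buttons (screen fraction, default 0).
#' @return a `ddt_config` list.
#' @export
ddt_config <- function(large_magnitude = 4L, small_magnitude = 1L,
                       delays = c(0, 5, 10, 20), trials_per_block = 12L,
                       forced_per_block = 6L, free_per_block = 6L,
                       large_side = c("left", "right"), iti = 15,
                       response_window = 60, pellet_cycle_time = 0,
                       hit_extension_above = 0) {
  large_side <- match.arg(large_side)
  stopifnot(large_magnitude >= 1L, small_magnitude >= 1L,
            length(delays) >= 1L, all(delays >= 0),
            all(diff(delays) > 0) || length(delays) == 1L,
            forced_per_block >= 0L, free_per_block >= 0L,
            iti >= 0, iti < 20, response_window > 0,
            pellet_cycle_time >= 0, hit_extension_above >= 0)
  if (forced_per_block + free_per_block != trials_per_block)
    stop("forced_per_block + free_per_block must equal trials_per_block")
  if (forced_per_block %% 2L != 0L)
    stop("forced_per_block must be even (half Large-only, half Small-only)")
  structure(list(large_magnitude = as.integer(large_magnitude),
                 small_magnitude = as.integer(small_magnitude),
                 delays = as.numeric(delays),
                 trials_per_block = as.integer(trials_per_block),
                 forced_per_block = as.integer(forced_per_block),
                 free_per_block = as.integer(free_per_block),
                 large_side = large_side, iti = iti,
                 response_window = response_window,
                 pellet_cycle_time = pellet_cycle_time,
                 hit_extension_above = hit_extension_above),
            class = "ddt_config")
}

#' Swap the Large and Small button sides
#'
#' A pure configuration transform used for within-subject reversals;
#' applying it twice restores the original configuration. Magnitudes and
#' delays are untouched.
#'
#' @param config a `ddt_config`.
#' @return the configuration with `large_side` flipped.
#' @export
reverse_buttons <- function(config) {
  stopifnot(inherits(config, "ddt_config"))
  config$large_side <- if (config$large_side == "left") "right" else "left"
  config
}

#' Build the ordered trial plan for a DDT session
#'
#' One block per delay in ascending order; within each block the forced
#' trials (half Large-only, half Small-only, order shuffled from the session
#' RNG) precede the free-choice trials. The block delay applies to the Large
#' reward only.
#'
#' @param config a `ddt_config`.
#' @return data frame of trial specs: `trial_index`, `block_index`, `delay`,
#'   `trial_type` (`"forced_choice"`/`"free_choice"`), `forced_option`
#'   (`"large"`, `"small"`, or `NA` on free trials), `large_side`.
#' @export
build_ddt_session <- function(config = ddt_config()) {
  stopifnot(inherits(config, "ddt_config"))
  blocks <- lapply(seq_along(config$delays), function(b) {
    nf <- config$forced_per_block
    forced <- if (nf > 0L)
      sample(rep(c("large", "small"), each = nf %/% 2L)) else character(0)
    data.frame(block_index = b - 1L, delay = config$delays[[b]],
               trial_type = c(rep("forced_choice", nf),
                              rep("free_choice", config$free_per_block)),
               forced_option = c(forced,
                                 rep(NA_character_, config$free_per_block)),
               stringsAsFactors = FALSE)
  })
  plan <- do.call(rbind, blocks)
  plan$trial_index <- seq_len(nrow(plan)) - 1L
  plan$large_side <- config$large_side
  plan[, c("trial_index", "block_index", "delay", "trial_type",
           "forced_option", "large_side")]
}

## the two-button layout; the unavailable option of a forced trial is shown
## but inactive (gray)
ddt_geometry <- function(config, forced_option = NA_character_) {
  sides <- c(large = config$large_side,
             small = if (config$large_side == "left") "right" else "left")
  make <- function(opt) {
    x <- if (sides[[opt]] == "left") 0.10 else 0.60
    active <- is.na(forced_option) || forced_option == opt
    response_box(opt, x, 0.35, 0.30, 0.30,
                 color = if (active) "yellow" else "inactive_gray",
                 active = active,
                 hit_extension_above = config$hit_extension_above)
  }
  screen_geometry(make("large"), make("small"))
}

ddt_options <- function(config, spec) {
  sides <- c(large = config$large_side,
             small = if (config$large_side == "left") "right" else "left")
  data.frame(id = c("large", "small"),
             magnitude = c(config$large_magnitude, config$small_magnitude),
             delay = c(spec$delay, 0),
             side = unname(sides[c("large", "small")]),
             color = "yellow",
             active = is.na(spec$forced_option) |
               spec$forced_option == c("large", "small"),
             stringsAsFactors = FALSE)
}

#' Run one DDT trial
#'
#' Sounds the trial-start tone, presents the two buttons (the unavailable
#' one inactive on forced trials), and lets the agent respond. A registered
#' Large choice schedules `large_magnitude` pellet commands after the
#' block's delay; a Small choice delivers `small_magnitude` immediately. No
#' registered response within the response window scores an omission. The
#' intertrial interval follows.
#'
#' @param sess a `task_session`.
#' @param spec one row of [build_ddt_session()].
#' @param agent an `agent_policy`.
#' @param config a `ddt_config`.
#' @return list: `choice` (`"large"`, `"small"`, or `"none"`), `omitted`,
#'   `pellets` delivered.
#' @export
run_ddt_trial <- function(sess, spec, agent, config = ddt_config()) {
  stopifnot(inherits(sess, "task_session"), inherits(agent, "agent_policy"),
            inherits(config, "ddt_config"))
  ti <- spec$trial_index
  geom <- ddt_geometry(config, spec$forced_option)
  s_audio(sess, "trial_start", ti)
  s_emit(sess, "trial_start", ti,
         payload = payload_string(trial_type = spec$trial_type,
                                  block = spec$block_index,
                                  delay = spec$delay,
                                  forced_option = spec$forced_option,
                                  large_side = spec$large_side))
  end_trial <- function(choice, pellets) {
    clock_advance(sess$clock, config$iti)
    list(choice = choice, omitted = choice == "none", pellets = pellets)
  }
  choice <- agent_choose(agent, ddt_options(config, spec))
  if (is.na(choice)) {
    clock_advance(sess$clock, config$response_window)
    s_emit(sess, "omission", ti)
    return(end_trial("none", 0L))
  }
  elapsed <- 0
  repeat {
    lat <- max(agent_latency(agent), 0.05)
    if (elapsed + lat > config$response_window) {
      clock_advance(sess$clock, config$response_window - elapsed)
      s_emit(sess, "omission", ti)
      return(end_trial("none", 0L))
    }
    elapsed <- elapsed + lat
    clock_advance(sess$clock, lat)
    touches <- emit_touch(agent, geom[[choice]],
                          timestamp = clock_now(sess$clock))
    hit <- s_touch(sess, geom, touches[[1]], ti)
    if (!is.na(hit)) break
  }
  side <- if ((hit == "large") == (config$large_side == "left"))
    "left" else "right"
  s_emit(sess, "response_registered", ti,
         x = touches[[1]]$x, y = touches[[1]]$y,
         payload = payload_string(box = hit, choice = hit, side = side,
                                  color = "yellow"))
  s_audio(sess, "response_feedback", ti)
  magnitude <- if (hit == "large") config$large_magnitude
               else config$small_magnitude
  delay <- if (hit == "large") spec$delay else 0
  if (delay > 0) clock_advance(sess$clock, delay)
  s_emit(sess, "reinforcement", ti,
         payload = payload_string(choice = hit, magnitude = magnitude,
                                  delay = delay))
  s_pellets(sess, magnitude, ti, cycle_time = config$pellet_cycle_time)
  end_trial(hit, magnitude)
}

#' Run a complete DDT session with a simulated subject
#'
#' Builds the trial plan with [build_ddt_session()] and runs every trial in
#' order.
#'
#' @param agent an `agent_policy`.
#' @param config a `ddt_config`.
#' @param subject_id,session_id log identity.
#' @param seed session seed.
#' @return the session log as a data frame, with the trial plan attached as
#'   attribute `"plan"`.
#' @export
run_ddt_session <- function(agent, config = ddt_config(),
                            subject_id = "sim", session_id = 1L, seed = 1L) {
  sess <- task_session(subject_id, session_id, "ddt", seed)
  plan <- build_ddt_session(config)
  for (i in seq_len(nrow(plan))) {
    spec <- plan[i, ]
    sess$phase <- paste0("block", spec$block_index)
    run_ddt_trial(sess, spec, agent, config)
  }
  structure(session_log(sess), plan = plan)
}
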