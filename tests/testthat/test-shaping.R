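# Response shaping: stage geometries, autoshaping, and stage advancement.

test_that("stages 0 and 1 illuminate the whole screen", {
  for (stage in 0:1) {
    geom <- shaping_geometry(stage)
    box <- geom[["target"]]
    expect_equal(c(box$x, box$y, box$w, box$h), c(0, 0, 1, 1))
    expect_equal(box$color, "yellow")
  }
})

test_that("stage 2 presents a third-of-screen rectangle at three heights", {
  set.seed(1)
  ys <- replicate(200, {
    geom <- shaping_geometry(2)
    expect_equal(geom[["target"]]$h, 1 / 3)
    expect_equal(geom[["target"]]$w, 1)
    geom[["target"]]$y
  })
  expect_setequal(round(unique(ys), 6), round(c(0, 1, 2) / 3, 6))
})

test_that("stage 2 heights are drawn uniformly (chi-square, 3000 draws)", {
  set.seed(202)
  ys <- replicate(3000, shaping_geometry(2)[["target"]]$y)
  counts <- table(factor(round(ys, 6), levels = round(c(0, 1, 2) / 3, 6)))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("stage 3 presents a square of 40% screen width at five positions", {
  set.seed(3)
  pos <- t(replicate(400, {
    box <- shaping_geometry(3)[["target"]]
    expect_equal(box$w, 0.40)
    expect_equal(box$h, 0.40)
    c(box$x, box$y)
  }))
  expect_equal(nrow(unique(pos)), 5L)
  expect_true(any(pos[, 1] == 0.3 & pos[, 2] == 0.3))   # centre position
})

test_that("invalid stages are rejected", {
  expect_error(shaping_geometry(5), "stage")
})

test_that("stage-4 geometry uses the current shrinking box side", {
  set.seed(4)
  box <- shaping_geometry(4, stage4_size = 0.22)[["target"]]
  expect_equal(box$w, 0.22)
})

test_that("advancement follows the 20/15/15/40 press thresholds", {
  config <- shaping_config()
  state <- shaping_state(config = config)
  for (i in 1:19) {
    state <- shaping_advance(state, config)$state
    expect_equal(state$stage, 0L)
  }
  expect_equal(state$presses_in_stage, 19L)
  out <- shaping_advance(state, config)          # 20th press
  expect_true(out$advanced)
  expect_equal(out$state$stage, 1L)
  expect_equal(out$state$presses_in_stage, 0L)
})

test_that("a perfect responder completes after the sum of thresholds", {
  config <- shaping_config()
  state <- shaping_state(config = config)
  presses <- 0L
  while (!state$complete) {
    state <- shaping_advance(state, config)$state
    presses <- presses + 1L
  }
  expect_equal(presses, sum(config$thresholds))   # 20+15+15+40
  expect_equal(state$stage, 3L)
})

test_that("with stage 4 enabled completion needs the extra threshold", {
  config <- shaping_config(stage4 = TRUE, stage4_threshold = 10L)
  state <- shaping_state(config = config)
  presses <- 0L
  while (!state$complete) {
    state <- shaping_advance(state, config)$state
    presses <- presses + 1L
  }
  expect_equal(presses, sum(config$thresholds) + 10L)
  expect_equal(state$stage, 4L)
})

test_that("a non-responding subject gets the pellet exactly 10 s after each illumination", {
  sess <- task_session("pig0", 1L, "shaping", seed = 5)
  agent <- agent_policy("nonresponder")
  for (ti in 0:4) {
    out <- autoshape_step(sess, agent, trial_index = ti)
    expect_false(out$counted)
    clock_advance(sess$clock, 15)
  }
  df <- as.data.frame(sess$log)
  for (ti in 0:4) {
    ev <- trial_events(df, ti)
    t0 <- ev$timestamp_s[ev$event_type == "trial_start"]
    tp <- ev$timestamp_s[ev$event_type == "pellet_command"]
    expect_length(tp, 1L)
    expect_equal(tp - t0, 10)
  }
})

test_that("an early press is reinforced at once and cancels the scheduled pellet", {
  sess <- task_session("pig0", 1L, "shaping", seed = 6)
  agent <- agent_policy("perfect", response_latency_mean = 0)  # presses at +0 s
  out <- autoshape_step(sess, agent, trial_index = 0L)
  expect_true(out$counted)
  expect_lt(out$press_time, 10)
  df <- as.data.frame(sess$log)
  ev <- trial_events(df, 0L)
  expect_equal(sum(ev$event_type == "pellet_command"), 1L)  # one max
  t0 <- ev$timestamp_s[ev$event_type == "trial_start"]
  tp <- ev$timestamp_s[ev$event_type == "pellet_command"]
  expect_lt(tp - t0, 10)
})

test_that("exactly one pellet per illumination for any mix of responders", {
  set.seed(8)
  sess <- task_session("pig0", 1L, "shaping", seed = 8)
  agent <- agent_policy("hyperbolic", response_latency_mean = 8,
                        omission_prob = 0.3)
  for (ti in 0:29) {
    autoshape_step(sess, agent, trial_index = ti)
    clock_advance(sess$clock, 15)
  }
  df <- as.data.frame(sess$log)
  per_trial <- vapply(0:29, function(ti)
    sum(trial_events(df, ti)$event_type == "pellet_command"), integer(1))
  expect_true(all(per_trial == 1L))
})

test_that("a perfect agent runs the full shaping curriculum without omissions", {
  elapsed <- system.time(
    log <- run_shaping_session(agent_policy("perfect"), seed = 1)
  )[["elapsed"]]
  state <- attr(log, "final_state")
  expect_true(state$complete)
  trials <- session_trials(log)
  expect_equal(nrow(trials), sum(shaping_config()$thresholds))
  expect_equal(sum(trials$omitted), 0L)
  expect_equal(sum(log$event_type == "pellet_command"), 90L)
  # stage sequence never decreases
  stages <- as.integer(sub("stage", "", trials$phase))
  expect_true(all(diff(stages) >= 0))
  expect_lt(elapsed, 1)
})

test_that("subjects can start at a later stage", {
  log <- run_shaping_session(agent_policy("perfect"), seed = 2,
                             start_stage = 3L)
  expect_equal(nrow(session_trials(log)), 40L)
  expect_true(attr(log, "final_state")$complete)
})

test_that("an FR-3 requirement at stage 3 needs three presses per pellet", {
  config <- shaping_config(fr_stage3 = 3L)
  log <- run_shaping_session(agent_policy("perfect"), config, seed = 9,
                             start_stage = 3L)
  trials <- session_trials(log)
  expect_equal(nrow(trials), 40L)
  expect_equal(sum(log$event_type == "pellet_command"), 40L)
  expect_equal(sum(log$event_type == "response_registered"), 120L)
})
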