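# Delay discounting task: session structure, trial contingencies, reversals.

test_that("the default session is four ascending blocks of 12 trials", {
  set.seed(1)
  plan <- build_ddt_session()
  expect_equal(nrow(plan), 48L)
  expect_equal(unname(table(plan$block_index)), rep(12L, 4), ignore_attr = TRUE)
  expect_equal(unique(plan$delay), c(0, 5, 10, 20))
  # delay never decreases over the session plan
  expect_true(all(diff(plan$delay) >= 0))
})

test_that("each block opens with 6 forced trials (3 Large, 3 Small) then 6 free", {
  set.seed(2)
  plan <- build_ddt_session()
  for (b in 0:3) {
    blk <- plan[plan$block_index == b, ]
    expect_equal(blk$trial_type,
                 c(rep("forced_choice", 6), rep("free_choice", 6)))
    expect_equal(sum(blk$forced_option == "large", na.rm = TRUE), 3L)
    expect_equal(sum(blk$forced_option == "small", na.rm = TRUE), 3L)
    expect_true(all(is.na(blk$forced_option[blk$trial_type == "free_choice"])))
  }
})

test_that("alternative delay sets build matching blocks", {
  set.seed(3)
  plan <- build_ddt_session(ddt_config(delays = c(0, 1, 2, 4)))
  expect_equal(unique(plan$delay), c(0, 1, 2, 4))
  # a single zero-delay block is a magnitude discrimination
  plan0 <- build_ddt_session(ddt_config(delays = 0))
  expect_equal(nrow(plan0), 12L)
  expect_true(all(plan0$delay == 0))
})

test_that("configuration contracts are enforced", {
  expect_error(ddt_config(forced_per_block = 5L, free_per_block = 7L),
               "even")
  expect_error(ddt_config(forced_per_block = 6L, free_per_block = 5L),
               "equal")
  expect_error(ddt_config(delays = c(0, 10, 5)))
  expect_error(ddt_config(iti = 25))   # ITI must stay under 20 s
})

test_that("button reversal is an involution that only flips sides", {
  config <- ddt_config()
  rev1 <- reverse_buttons(config)
  expect_equal(rev1$large_side, "right")
  expect_equal(rev1$large_magnitude, config$large_magnitude)
  expect_equal(rev1$delays, config$delays)
  expect_equal(reverse_buttons(rev1), config)
})

test_that("a Large choice delivers 4 pellets after the block delay", {
  sess <- task_session("pig0", 1L, "ddt", seed = 4)
  config <- ddt_config()
  spec <- list(trial_index = 0L, block_index = 2L, delay = 10,
               trial_type = "free_choice", forced_option = NA_character_,
               large_side = "left")
  agent <- agent_policy("hyperbolic", k = 0, response_latency_mean = 0)
  out <- run_ddt_trial(sess, spec, agent, config)
  expect_equal(out$choice, "large")
  expect_equal(out$pellets, 4L)
  df <- as.data.frame(sess$log)
  resp_t <- df$timestamp_s[df$event_type == "response_registered"]
  pellet_t <- df$timestamp_s[df$event_type == "pellet_command"]
  expect_length(pellet_t, 4L)
  expect_equal(pellet_t - resp_t, rep(10, 4))   # delayed by the block delay
})

test_that("a Small choice delivers 1 pellet immediately", {
  sess <- task_session("pig0", 1L, "ddt", seed = 5)
  spec <- list(trial_index = 0L, block_index = 3L, delay = 20,
               trial_type = "forced_choice", forced_option = "small",
               large_side = "left")
  agent <- agent_policy("perfect", response_latency_mean = 0)
  out <- run_ddt_trial(sess, spec, agent, ddt_config())
  expect_equal(out$choice, "small")
  expect_equal(out$pellets, 1L)
  df <- as.data.frame(sess$log)
  resp_t <- df$timestamp_s[df$event_type == "response_registered"]
  pellet_t <- df$timestamp_s[df$event_type == "pellet_command"]
  expect_equal(pellet_t, resp_t)              # no delay on Small
})

test_that("forced trials leave the unavailable button inactive", {
  # a greedy Large-preferring agent still earns Small on Small-only trials
  log <- run_ddt_session(agent_policy("hyperbolic", k = 0), seed = 6)
  trials <- session_trials(log)
  forced_small <- trials[trials$trial_type == "forced_choice" &
                           trials$choice == "small", ]
  expect_equal(nrow(forced_small), 12L)       # 3 per block, 4 blocks
})

test_that("an unanswered trial is an omission with no pellets", {
  sess <- task_session("pig0", 1L, "ddt", seed = 7)
  spec <- list(trial_index = 0L, block_index = 0L, delay = 0,
               trial_type = "free_choice", forced_option = NA_character_,
               large_side = "left")
  out <- run_ddt_trial(sess, spec, agent_policy("nonresponder"), ddt_config())
  expect_true(out$omitted)
  expect_equal(out$pellets, 0L)
  df <- as.data.frame(sess$log)
  expect_equal(sum(df$event_type == "omission"), 1L)
  expect_equal(sum(df$event_type == "pellet_command"), 0L)
})

test_that("pellet commands are conserved across a full session", {
  log <- run_ddt_session(agent_policy("hyperbolic", k = 0.5,
                                      omission_prob = 0.1), seed = 8)
  trials <- session_trials(log)
  expect_equal(sum(log$event_type == "pellet_command"),
               sum(trials$reinforcers_delivered))
  expect_equal(sum(trials$reinforcers_delivered),
               4L * sum(trials$choice == "large") +
                 1L * sum(trials$choice == "small"))
  # omitted trials earned nothing
  expect_true(all(trials$reinforcers_delivered[trials$omitted] == 0L))
})

test_that("every trial opens with the 7500 Hz availability tone", {
  log <- run_ddt_session(agent_policy("perfect"),
                         ddt_config(delays = 0), seed = 9)
  starts <- which(log$event_type == "trial_start")
  expect_true(all(log$event_type[starts - 1L] == "tone"))
  expect_true(all(grepl("frequency_hz=7500", log$payload[starts - 1L])))
})
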