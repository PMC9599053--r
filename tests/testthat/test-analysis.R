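# Outcome metrics: AUC, preference indices, accuracy, latency.

test_that("AUC endpoints are 1 for all-Large and 0 for all-Small in both modes", {
  all_large <- make_trials(rep("large", 48),
                           delay = rep(c(0, 5, 10, 20), each = 12))
  all_small <- make_trials(rep("small", 48),
                           delay = rep(c(0, 5, 10, 20), each = 12))
  for (mode in c("proportion", "trapezoid")) {
    expect_equal(discounting_auc(all_large, mode), 1)
    expect_equal(discounting_auc(all_small, mode), 0)
  }
})

test_that("proportion-mode AUC is the pooled fraction of Large choices", {
  half <- make_trials(rep(c("large", "small"), 24),
                      delay = rep(c(0, 5, 10, 20), each = 12))
  expect_equal(discounting_auc(half), 0.5)   # 24 Large of 48
  # omitted trials leave the denominator
  with_omissions <- make_trials(c(rep("large", 6), rep("none", 6)),
                                omitted = rep(c(FALSE, TRUE), each = 6))
  expect_equal(discounting_auc(with_omissions), 1)
})

test_that("proportion AUC equals the mean per-block proportion under equal block sizes", {
  # enumeration oracle: blocks of equal completed size
  set.seed(10)
  for (case in 1:20) {
    props <- runif(4)
    choices <- unlist(lapply(props, function(p)
      ifelse(seq_len(12) <= round(p * 12), "large", "small")))
    trials <- make_trials(choices, delay = rep(c(0, 5, 10, 20), each = 12))
    per_block <- vapply(c(0, 5, 10, 20), function(d)
      mean(trials$choice[trials$delay == d] == "large"), numeric(1))
    expect_equal(discounting_auc(trials), mean(per_block))
  }
})

test_that("trapezoid-mode AUC matches a hand trapezoidal quadrature", {
  trials <- make_trials(
    c(rep("large", 12),                                   # p = 1 at 0 s
      rep(c("large", "small"), 6),                        # p = .5 at 5 s
      rep(c("large", "small", "small", "small"), 3),      # p = .25 at 10 s
      rep("small", 12)),                                  # p = 0 at 20 s
    delay = rep(c(0, 5, 10, 20), each = 12))
  d <- c(0, 5, 10, 20) / 20
  p <- c(1, 0.5, 0.25, 0)
  oracle <- sum(diff(d) * (head(p, -1) + tail(p, -1)) / 2)
  expect_equal(discounting_auc(trials, "trapezoid"), oracle)
})

test_that("AUC is absent without completed free choices", {
  expect_true(is.na(discounting_auc(make_trials(character(0)))))
  omitted <- make_trials(rep("none", 5), omitted = TRUE)
  expect_true(is.na(discounting_auc(omitted)))
})

test_that("side preference is (L - R) / (L + R)", {
  expect_equal(side_bias(make_trials(rep("large", 8), side = "left")), 1)
  expect_equal(side_bias(make_trials(rep("large", 8),
                                     side = rep(c("left", "right"), 4))), 0)
  expect_equal(side_bias(make_trials(rep("large", 12),
                                     side = rep(c("left", "right"),
                                                c(9, 3)))), 0.5)
})

test_that("color preference is (G - B) / (G + B)", {
  expect_equal(color_bias(make_trials(rep("correct", 6), "choice",
                                      side = "left", color = "green")), 1)
  expect_equal(color_bias(make_trials(rep("correct", 6), "choice",
                                      side = "left",
                                      color = rep(c("green", "blue"), 3))), 0)
  expect_equal(color_bias(make_trials(rep("correct", 12), "choice",
                                      side = "left",
                                      color = rep(c("green", "blue"),
                                                  c(10, 2)))),
               8 / 12)
})

test_that("preference indices are antisymmetric under category swap", {
  set.seed(11)
  for (case in 1:20) {
    sides <- sample(c("left", "right"), 20, replace = TRUE)
    swap <- ifelse(sides == "left", "right", "left")
    b1 <- side_bias(make_trials(rep("large", 20), side = sides))
    b2 <- side_bias(make_trials(rep("large", 20), side = swap))
    expect_equal(b1, -b2)
    colors <- sample(c("green", "blue"), 20, replace = TRUE)
    cswap <- ifelse(colors == "green", "blue", "green")
    c1 <- color_bias(make_trials(rep("correct", 20), "choice",
                                 side = sides, color = colors))
    expect_equal(c1, -color_bias(make_trials(rep("correct", 20), "choice",
                                             side = sides, color = cswap)))
  }
})

test_that("percent correct excludes correction trials from the denominator", {
  trials <- rbind(
    make_trials(rep(c("correct", "incorrect"), 6), "choice", side = "left"),
    make_trials(rep("correct", 6), "correction", side = "left"))
  expect_equal(percent_correct(trials), 50)       # 6 of 12 scored
  expect_equal(percent_correct(make_trials(rep("correct", 10), "choice",
                                           side = "left")), 100)
  all_omitted <- make_trials(rep("none", 4), "choice", omitted = TRUE)
  expect_true(is.na(percent_correct(all_omitted)))
})

test_that("initiation latency averages initiated trials only", {
  trials <- make_trials(c("large", "large"), latency = c(2, 4))
  expect_equal(initiation_latency(trials), 3)
  with_omit <- rbind(trials,
                     make_trials("none", latency = NA, omitted = TRUE))
  expect_equal(initiation_latency(with_omit), 3)
  expect_true(is.na(initiation_latency(make_trials(character(0)))))
})

test_that("measured latency tracks the agent's configured mean", {
  log <- run_ddt_session(
    agent_policy("hyperbolic", k = 0, response_latency_mean = 8),
    ddt_config(delays = c(0, 5), response_window = 1e5), seed = 13)
  lat <- initiation_latency(session_trials(log))
  expect_equal(lat, 8, tolerance = 0.4)   # Monte-Carlo error at n = 24
})

test_that("all metrics are recomputable from the CSV alone", {
  log <- run_ddt_session(agent_policy("hyperbolic", k = 0.5,
                                      omission_prob = 0.1), seed = 14)
  path <- withr::local_tempfile(fileext = ".csv")
  write_session_csv(log, path)
  from_file <- summarize_session(read_session_csv(path))
  in_memory <- summarize_session(log)
  expect_equal(from_file, in_memory, tolerance = 1e-9)
})

test_that("summarize_files gives one row per session file", {
  dir <- withr::local_tempdir()
  simulate_session("ddt", agent_policy("hyperbolic", k = 0.5),
                   subject_id = "pigA", seed = 3, out_dir = dir)
  simulate_session("shaping", agent_policy("perfect"),
                   subject_id = "pigB", seed = 4, out_dir = dir)
  tab <- summarize_files(list.files(dir, full.names = TRUE))
  expect_equal(nrow(tab), 2L)
  expect_setequal(tab$subject_id, c("pigA", "pigB"))
})
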