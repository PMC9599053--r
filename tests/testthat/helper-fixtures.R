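# Fixture builders: random-but-valid event logs and hand-built trial tables.

# a random valid single-subject log with sorted timestamps and occasional
# awkward payload text (commas, quotes) to exercise RFC 4180 quoting
random_log <- function(n = 20, subject = "pigA", session = 1L) {
  log <- event_log()
  ts <- sort(round(runif(n, 0, 600), 3))
  types <- sample(c("trial_start", "touch", "response_registered",
                    "reinforcement", "pellet_command", "tone", "omission",
                    "stage_advance", "manual_note"), n, replace = TRUE)
  payload_pool <- c("", "box=target", "note=hello, world",
                    'note=she said ""go""', "stage=2;fr=3")
  for (i in seq_len(n)) {
    needs_xy <- types[i] %in% c("response_registered", "touch")
    log_event(log, event_record(
      subject_id = subject, session_id = session,
      task = sample(c("shaping", "ddt", "discrimination"), 1),
      event_type = types[i], timestamp = ts[i],
      phase = sample(c("", "stage1", "block2"), 1),
      trial_index = if (runif(1) < 0.8) sample(0:30, 1) else NA_integer_,
      x = if (needs_xy) round(runif(1), 6) else NA_real_,
      y = if (needs_xy) round(runif(1), 6) else NA_real_,
      payload = sub("note=she said .*", 'note=she said go',
                    sample(payload_pool, 1))))
  }
  log
}

# a minimal log with n trials, the given ones omitted; initiated trials get
# one registered response lat seconds after trial start
tally_log <- function(n_trials, omitted_idx = integer(0), lat = 2) {
  log <- event_log()
  t <- 0
  for (i in seq_len(n_trials) - 1L) {
    log_event(log, event_record("pigA", 1L, "ddt", "trial_start", t,
                                phase = "block0", trial_index = i,
                                payload = "trial_type=free_choice;delay=0"))
    if (i %in% omitted_idx) {
      t <- t + 60
      log_event(log, event_record("pigA", 1L, "ddt", "omission", t,
                                  phase = "block0", trial_index = i))
    } else {
      t <- t + lat
      log_event(log, event_record(
        "pigA", 1L, "ddt", "response_registered", t, phase = "block0",
        trial_index = i, x = 0.5, y = 0.5,
        payload = "box=large;choice=large;side=left;color=yellow"))
      log_event(log, event_record("pigA", 1L, "ddt", "pellet_command", t,
                                  phase = "block0", trial_index = i,
                                  payload = "cue=1"))
    }
    t <- t + 15
  }
  log
}

# hand-built trial table for the analysis functions
make_trials <- function(choice, trial_type = "free_choice", delay = 0,
                        side = NA_character_, color = NA_character_,
                        latency = 1, omitted = FALSE) {
  n <- length(choice)
  data.frame(trial_index = seq_len(n) - 1L,
             trial_type = rep_len(trial_type, n),
             phase = rep_len("", n), block_index = rep_len(NA_integer_, n),
             delay = rep_len(delay, n), choice = choice,
             choice_side = rep_len(side, n),
             choice_color = rep_len(color, n),
             initiation_latency = as.numeric(rep_len(latency, n)),
             choice_latency = as.numeric(rep_len(latency, n)),
             reinforcers_delivered = rep_len(0L, n),
             omitted = rep_len(omitted, n),
             stringsAsFactors = FALSE)
}

# events of one trial, in log order
trial_events <- function(log_df, ti) {
  log_df[!is.na(log_df$trial_index) & log_df$trial_index == ti, ,
         drop = FALSE]
}
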