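## Session analytics.
##
## Every metric is computed from the event log alone — the CSV file is the
## single source of truth, so a session can be re-analysed without any
## in-memory state. Trials are first reconstructed from the log, then the
## outcome metrics mirror the standard panels of a session report: mean
## initiation latency, omissions, trials completed, percent correct,
## discounting AUC, and side/color preference indices on a -1..1 scale.

#' Reconstruct trial results from a session log
#'
#' Walks the log's `trial_start` events and tallies, per trial: the trial
#' type, realized choice (with its side and color), initiation latency
#' (first registered response after the trial-start tone), choice latency,
#' pellet commands attributed to the trial, and the omission flag.
#'
#' @param log an `event_log` or log data frame (one subject/session).
#' @return data frame with one row per trial: `trial_index`, `trial_type`,
#'   `phase`, `block_index`, `delay`, `choice`, `choice_side`,
#'   `choice_color`, `initiation_latency`, `choice_latency`,
#'   `reinforcers_delivered`, `omitted`.
#' @export
session_trials <- function(log) {
  df <- if (inherits(log, "event_log")) as.data.frame(log) else log
  starts <- df[df$event_type == "trial_start" & !is.na(df$trial_index), ,
               drop = FALSE]
  if (nrow(starts) == 0L) return(empty_trials_df())
  rows <- lapply(seq_len(nrow(starts)), function(i) {
    ti <- starts$trial_index[[i]]
    t0 <- starts$timestamp_s[[i]]
    pl <- parse_payload(starts$payload[[i]])
    ev <- df[!is.na(df$trial_index) & df$trial_index == ti, , drop = FALSE]
    resp <- ev[ev$event_type == "response_registered", , drop = FALSE]
    omitted <- any(ev$event_type == "omission")
    choice <- NA_character_; side <- NA_character_; colr <- NA_character_
    choice_ts <- NA_real_
    if (nrow(resp) > 0L) {
      kvs <- lapply(resp$payload, parse_payload)
      has_choice <- vapply(kvs, function(kv) "choice" %in% names(kv),
                           logical(1))
      if (any(has_choice)) {
        j <- max(which(has_choice))
        choice <- kvs[[j]][["choice"]]
        side <- if ("side" %in% names(kvs[[j]])) kvs[[j]][["side"]]
                else NA_character_
        colr <- if ("color" %in% names(kvs[[j]])) kvs[[j]][["color"]]
                else NA_character_
        choice_ts <- resp$timestamp_s[[j]]
      }
    }
    getf <- function(key) if (key %in% names(pl)) pl[[key]] else NA_character_
    data.frame(
      trial_index = ti,
      trial_type = getf("trial_type"),
      phase = starts$phase[[i]],
      block_index = suppressWarnings(as.integer(getf("block"))),
      delay = suppressWarnings(as.numeric(getf("delay"))),
      choice = if (omitted || is.na(choice)) "none" else choice,
      choice_side = side,
      choice_color = colr,
      initiation_latency = if (nrow(resp) > 0L)
        resp$timestamp_s[[1]] - t0 else NA_real_,
      choice_latency = if (!is.na(choice_ts)) choice_ts - t0 else NA_real_,
      reinforcers_delivered = sum(ev$event_type == "pellet_command"),
      omitted = omitted,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

empty_trials_df <- function() {
  data.frame(trial_index = integer(), trial_type = character(),
             phase = character(), block_index = integer(), delay = numeric(),
             choice = character(), choice_side = character(),
             choice_color = character(), initiation_latency = numeric(),
             choice_latency = numeric(), reinforcers_delivered = integer(),
             omitted = logical(), stringsAsFactors = FALSE)
}

completed_free_choices <- function(trials) {
  trials[trials$trial_type %in% "free_choice" & !trials$omitted &
           trials$choice %in% c("large", "small"), , drop = FALSE]
}

#' Discounting AUC
#'
#' Summary of preference for the larger, delayed reward, bounded in
#' \[0, 1\]. The default `"proportion"` mode is the proportion of completed
#' free-choice trials on which Large was chosen, pooled across delay blocks
#' (1 = every free choice Large, 0 = never). The `"trapezoid"` mode is the
#' conventional discounting AUC: the trapezoidal area under the per-block
#' Large-choice proportion as a function of delay, normalised by the maximum
#' delay. Omitted trials are excluded from all denominators.
#'
#' @param trials a trial table from [session_trials()] (or a log / log data
#'   frame, which is converted).
#' @param mode `"proportion"` (default) or `"trapezoid"`.
#' @return AUC in \[0, 1\], or `NA` when no completed free choice exists
#'   (or, in trapezoid mode, when fewer than two delay blocks are present).
#' @export
discounting_auc <- function(trials, mode = c("proportion", "trapezoid")) {
  mode <- match.arg(mode)
  trials <- as_trials(trials)
  free <- completed_free_choices(trials)
  if (nrow(free) == 0L) return(NA_real_)
  if (mode == "proportion")
    return(mean(free$choice == "large"))
  agg <- stats::aggregate(list(p = free$choice == "large"),
                          by = list(delay = free$delay), FUN = mean)
  agg <- agg[order(agg$delay), , drop = FALSE]
  if (nrow(agg) < 2L || max(agg$delay) <= 0) return(NA_real_)
  d <- agg$delay / max(agg$delay)
  p <- agg$p
  sum(diff(d) * (utils::head(p, -1) + utils::tail(p, -1)) / 2) / (max(d) - min(d))
}

as_trials <- function(x) {
  if (is.data.frame(x) && "event_type" %in% names(x)) return(session_trials(x))
  if (inherits(x, "event_log")) return(session_trials(x))
  stopifnot(is.data.frame(x), "choice" %in% names(x))
  x
}

choice_trials <- function(trials) {
  trials[trials$trial_type %in% c("free_choice", "choice") &
           !trials$omitted & !is.na(trials$choice_side), , drop = FALSE]
}

preference_index <- function(a, b) {
  if (a + b == 0L) return(NA_real_)
  (a - b) / (a + b)
}

#' Side preference index
#'
#' `(L - R) / (L + R)` over completed, freely chosen trials (free-choice
#' trials in the discounting task; non-correction choice trials in the
#' discrimination task): +1 = all left, -1 = all right, 0 = no preference.
#'
#' @param trials a trial table, log, or log data frame.
#' @return index in \[-1, 1\], or `NA` with no eligible trials.
#' @export
side_bias <- function(trials) {
  ch <- choice_trials(as_trials(trials))
  preference_index(sum(ch$choice_side == "left"),
                   sum(ch$choice_side == "right"))
}

#' Color preference index
#'
#' `(G - B) / (G + B)` over completed choices of a green or blue box:
#' +1 = all green, -1 = all blue, 0 = no preference.
#'
#' @param trials a trial table, log, or log data frame.
#' @return index in \[-1, 1\], or `NA` with no eligible green/blue choices.
#' @export
color_bias <- function(trials) {
  ch <- choice_trials(as_trials(trials))
  ch <- ch[ch$choice_color %in% c("green", "blue"), , drop = FALSE]
  preference_index(sum(ch$choice_color == "green"),
                   sum(ch$choice_color == "blue"))
}

#' Percent correct in the discrimination task
#'
#' `100 * correct / scored` where scored trials are completed,
#' non-correction discrimination trials; correction trials are forced toward
#' the correct option, so counting them would inflate accuracy.
#'
#' @param trials a trial table, log, or log data frame.
#' @return percentage in \[0, 100\], or `NA` with no scored trial.
#' @export
percent_correct <- function(trials) {
  trials <- as_trials(trials)
  scored <- trials[trials$trial_type %in% "choice" & !trials$omitted &
                     trials$choice %in% c("correct", "incorrect"), ,
                   drop = FALSE]
  if (nrow(scored) == 0L) return(NA_real_)
  100 * mean(scored$choice == "correct")
}

#' Mean trial initiation latency
#'
#' Mean seconds from the trial-start tone (button availability) to the first
#' registered response, over initiated trials; omitted trials are excluded.
#'
#' @param trials a trial table, log, or log data frame.
#' @return mean latency in seconds, or `NA` with no initiated trial.
#' @export
initiation_latency <- function(trials) {
  trials <- as_trials(trials)
  lat <- trials$initiation_latency[!trials$omitted &
                                     !is.na(trials$initiation_latency)]
  if (length(lat) == 0L) return(NA_real_)
  mean(lat)
}

#' Summarise a session
#'
#' End-of-session summary for daily monitoring: exact tallies over the
#' trials reconstructed from the log plus the task-appropriate outcome
#' metrics. An empty log gives a zero-filled summary.
#'
#' @param log an `event_log` or log data frame (one subject/session).
#' @param auc_mode AUC definition passed to [discounting_auc()].
#' @return one-row data frame: `subject_id`, `session_id`, `task`,
#'   `trials_total`, `trials_completed`, `omissions`,
#'   `mean_initiation_latency`, `reinforcers_delivered`, `percent_correct`,
#'   `auc`, `side_bias`, `color_bias`.
#' @export
summarize_session <- function(log, auc_mode = "proportion") {
  df <- if (inherits(log, "event_log")) as.data.frame(log) else log
  trials <- session_trials(df)
  data.frame(
    subject_id = if (nrow(df) > 0L) df$subject_id[[1]] else NA_character_,
    session_id = if (nrow(df) > 0L) df$session_id[[1]] else NA_integer_,
    task = if (nrow(df) > 0L) df$task[[1]] else NA_character_,
    trials_total = nrow(trials),
    trials_completed = sum(!trials$omitted),
    omissions = sum(trials$omitted),
    mean_initiation_latency = initiation_latency(trials),
    reinforcers_delivered = sum(df$event_type == "pellet_command"),
    percent_correct = percent_correct(trials),
    auc = discounting_auc(trials, mode = auc_mode),
    side_bias = side_bias(trials),
    color_bias = color_bias(trials),
    stringsAsFactors = FALSE)
}
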