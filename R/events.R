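## Event records and the per-session event log.
##
## Every behavioral or device event is one row; a session log is an ordered
## sequence of rows, written to one comma-separated file per subject. The log
## is the single source of truth: every summary metric is recomputable from
## the CSV alone.

EVENT_TYPES <- c("trial_start", "touch", "response_registered",
                 "reinforcement", "pellet_command", "tone", "omission",
                 "correction_start", "stage_advance", "manual_note")

TASK_NAMES <- c("shaping", "ddt", "discrimination")

## Fixed CSV column order. The payload column holds free-form key=value detail
## and is always quoted (RFC 4180).
LOG_COLUMNS <- c("subject_id", "session_id", "task", "phase", "trial_index",
                 "event_type", "timestamp_s", "x", "y", "payload")

#' Create one behavioral event record
#'
#' Timestamps are seconds since session start, kept at millisecond precision;
#' coordinates are fractions of screen width/height in \[0, 1\] with the
#' origin at the top-left, so records are resolution independent.
#'
#' @param subject_id subject identifier (character scalar).
#' @param session_id session number, integer >= 1.
#' @param task one of `"shaping"`, `"ddt"`, `"discrimination"`.
#' @param event_type one of the recognised event types (see Details).
#' @param timestamp seconds since session start.
#' @param phase free-text phase label (e.g. `"stage2"`, `"block1"`).
#' @param trial_index integer trial number (>= 0) or `NA` for non-trial
#'   events such as session headers.
#' @param x,y touch coordinates as screen fractions, or `NA` when the event
#'   has no location. `response_registered` events must carry coordinates.
#' @param payload semicolon-separated `key=value` detail text.
#'
#' @details Recognised event types: `trial_start`, `touch`,
#'   `response_registered`, `reinforcement`, `pellet_command`, `tone`,
#'   `omission`, `correction_start`, `stage_advance`, `manual_note`.
#' @return an `event_record` (named list).
#' @export
event_record <- function(subject_id, session_id, task, event_type, timestamp,
                         phase = "", trial_index = NA_integer_,
                         x = NA_real_, y = NA_real_, payload = "") {
  stopifnot(is.character(subject_id), length(subject_id) == 1L,
            nzchar(subject_id))
  session_id <- as.integer(session_id)
  stopifnot(!is.na(session_id), session_id >= 1L)
  task <- match.arg(task, TASK_NAMES)
  event_type <- match.arg(event_type, EVENT_TYPES)
  stopifnot(is.numeric(timestamp), length(timestamp) == 1L, !is.na(timestamp),
            timestamp >= 0)
  trial_index <- as.integer(trial_index)
  if (!is.na(trial_index) && trial_index < 0L)
    stop("trial_index must be >= 0 or NA")
  x <- as.numeric(x); y <- as.numeric(y)
  if (xor(is.na(x), is.na(y)))
    stop("x and y must be both present or both absent")
  if (!is.na(x) && (x < 0 || x > 1 || y < 0 || y > 1))
    stop("touch coordinates must be screen fractions in [0, 1]")
  if (event_type == "response_registered" && is.na(x))
    stop("response_registered events must carry x,y coordinates")
  rec <- list(subject_id = subject_id, session_id = session_id, task = task,
              phase = as.character(phase), trial_index = trial_index,
              event_type = event_type,
              timestamp_s = round(as.numeric(timestamp), 3),
              x = if (is.na(x)) NA_real_ else round(x, 6),
              y = if (is.na(y)) NA_real_ else round(y, 6),
              payload = as.character(payload))
  class(rec) <- "event_record"
  rec
}

#' Create an empty session event log
#'
#' An `event_log` is an append-only ordered sequence of event records with
#' non-decreasing timestamps (enforced per subject/session at append time).
#'
#' @return an `event_log` object.
#' @export
event_log <- function() {
  log <- new.env(parent = emptyenv())
  log$records <- vector("list", 64L)
  log$n <- 0L
  log$last_ts <- new.env(parent = emptyenv())
  class(log) <- "event_log"
  log
}

#' Append one event record to a log
#'
#' Appending is the only mutation a log supports; each call grows the log by
#' exactly one record. A record whose timestamp precedes the last logged
#' timestamp for the same subject and session is rejected.
#'
#' @param log an `event_log`.
#' @param record an `event_record`.
#' @return the log, invisibly.
#' @export
log_event <- function(log, record) {
  stopifnot(inherits(log, "event_log"), inherits(record, "event_record"))
  key <- paste0(record$subject_id, "\r", record$session_id)
  last <- if (exists(key, envir = log$last_ts, inherits = FALSE))
    get(key, envir = log$last_ts) else -Inf
  if (record$timestamp_s < last)
    stop(sprintf(
      "out-of-order event: timestamp %.3f precedes last logged %.3f for %s session %d",
      record$timestamp_s, last, record$subject_id, record$session_id))
  assign(key, record$timestamp_s, envir = log$last_ts)
  if (log$n == length(log$records))
    length(log$records) <- 2L * log$n
  log$n <- log$n + 1L
  log$records[[log$n]] <- record
  invisible(log)
}

#' Number of events in a log
#' @param log an `event_log`.
#' @return integer count.
#' @export
log_length <- function(log) {
  stopifnot(inherits(log, "event_log"))
  log$n
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log: %d events>\n", log_length(x)))
  invisible(x)
}

#' Convert an event log to a data frame
#'
#' @param x an `event_log`.
#' @param row.names,optional,... ignored; present for S3 compatibility.
#' @return a data frame with the fixed log column order.
#' @export
as.data.frame.event_log <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  recs <- x$records[seq_len(x$n)]
  if (length(recs) == 0L) return(empty_log_df())
  pull_chr <- function(f) vapply(recs, function(r) r[[f]], character(1))
  pull_int <- function(f) vapply(recs, function(r) r[[f]], integer(1))
  pull_num <- function(f) vapply(recs, function(r) r[[f]], numeric(1))
  data.frame(subject_id = pull_chr("subject_id"),
             session_id = pull_int("session_id"),
             task = pull_chr("task"),
             phase = pull_chr("phase"),
             trial_index = pull_int("trial_index"),
             event_type = pull_chr("event_type"),
             timestamp_s = pull_num("timestamp_s"),
             x = pull_num("x"), y = pull_num("y"),
             payload = pull_chr("payload"),
             stringsAsFactors = FALSE)
}

empty_log_df <- function() {
  data.frame(subject_id = character(), session_id = integer(),
             task = character(), phase = character(),
             trial_index = integer(), event_type = character(),
             timestamp_s = numeric(), x = numeric(), y = numeric(),
             payload = character(), stringsAsFactors = FALSE)
}

## ---- payload helpers --------------------------------------------------

#' Encode / decode the payload field
#'
#' The payload is a flat `key=value` mapping joined with semicolons;
#' values must not contain `;` or `=`.
#'
#' @param ... named values (`payload_string`).
#' @param payload a payload string (`parse_payload`).
#' @return `payload_string` returns one string; `parse_payload` a named
#'   character vector (empty when the payload is empty).
#' @export
payload_string <- function(...) {
  kv <- list(...)
  if (length(kv) == 0L) return("")
  kv <- kv[!vapply(kv, function(v) length(v) == 0L || is.na(v), logical(1))]
  if (length(kv) == 0L) return("")
  vals <- vapply(kv, function(v) format(v, trim = TRUE, scientific = FALSE),
                 character(1))
  if (any(grepl("[;=]", vals)))
    stop("payload values must not contain ';' or '='")
  paste(names(kv), vals, sep = "=", collapse = ";")
}

#' @rdname payload_string
#' @export
parse_payload <- function(payload) {
  if (is.na(payload) || !nzchar(payload)) return(character(0))
  parts <- strsplit(payload, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- vapply(kv, function(p) if (length(p) >= 2L) p[[2]] else "",
                 character(1))
  names(vals) <- vapply(kv, `[[`, character(1), 1L)
  vals
}

payload_field <- function(payload, key, default = NA_character_) {
  kv <- parse_payload(payload)
  if (key %in% names(kv)) kv[[key]] else default
}

## ---- CSV I/O ----------------------------------------------------------

fmt_num <- function(v, digits) {
  ifelse(is.na(v), "", sprintf(paste0("%.", digits, "f"), v))
}

quote_csv <- function(s) {
  paste0('"', gsub('"', '""', s, fixed = TRUE), '"')
}

#' Write a session log to a comma-separated file
#'
#' One header line followed by one line per event, columns
#' `subject_id, session_id, task, phase, trial_index, event_type,
#' timestamp_s, x, y, payload`. Absent values are empty fields; timestamps
#' carry millisecond and coordinates microfraction precision; the payload
#' field is RFC 4180 quoted. UTF-8 throughout.
#'
#' @param log an `event_log` or a log data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_session_csv()] for the inverse; the round trip is the
#'   identity on the logged fields.
#' @export
write_session_csv <- function(log, path) {
  df <- if (inherits(log, "event_log")) as.data.frame(log) else log
  stopifnot(is.data.frame(df), identical(names(df), LOG_COLUMNS))
  lines <- c(paste(LOG_COLUMNS, collapse = ","),
             if (nrow(df) > 0L)
               paste(df$subject_id, df$session_id, df$task, df$phase,
                     ifelse(is.na(df$trial_index), "", df$trial_index),
                     df$event_type, fmt_num(df$timestamp_s, 3),
                     fmt_num(df$x, 6), fmt_num(df$y, 6),
                     quote_csv(df$payload), sep = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read a session log from a comma-separated file
#'
#' Validates the header and the field count of every line; a malformed line
#' raises an error naming its line number.
#'
#' @param path file written by [write_session_csv()].
#' @return a log data frame (same columns and types as
#'   `as.data.frame(event_log)`).
#' @export
read_session_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L) stop("empty file: ", path)
  if (!identical(lines[[1]], paste(LOG_COLUMNS, collapse = ",")))
    stop("line 1: unrecognised header in ", path)
  if (length(lines) == 1L) return(empty_log_df())
  nf <- tryCatch(count.fields(textConnection(lines[-1]), sep = ",",
                              quote = '"', blank.lines.skip = FALSE),
                 warning = function(w) stop("malformed quoting in ", path))
  bad <- which(is.na(nf) | nf != length(LOG_COLUMNS))
  if (length(bad) > 0L)
    stop(sprintf("line %d: expected %d fields, found %s",
                 bad[[1]] + 1L, length(LOG_COLUMNS),
                 ifelse(is.na(nf[bad[[1]]]), "an unterminated quote",
                        as.character(nf[bad[[1]]]))))
  df <- utils::read.csv(text = lines, header = TRUE,
                        colClasses = c("character", "integer", "character",
                                       "character", "integer", "character",
                                       "numeric", "numeric", "numeric",
                                       "character"),
                        na.strings = "", quote = '"',
                        stringsAsFactors = FALSE)
  names(df) <- LOG_COLUMNS
  for (col in c("phase", "payload"))
    df[[col]][is.na(df[[col]])] <- ""
  bad_type <- which(!df$event_type %in% EVENT_TYPES)
  if (length(bad_type) > 0L)
    stop(sprintf("line %d: unknown event_type '%s'",
                 bad_type[[1]] + 1L, df$event_type[bad_type[[1]]]))
  df
}

#' Write one CSV per subject
#'
#' Splits a multi-subject log and writes `<subject>_s<session>.csv` files
#' under `dir`. Existing files are handled per `overwrite`: `"error"`
#' refuses, `"suffix"` appends `_1`, `_2`, ... to the basename,
#' `"replace"` overwrites.
#'
#' @param log an `event_log` or log data frame.
#' @param dir output directory (created if missing).
#' @param overwrite collision policy, one of `"error"`, `"suffix"`,
#'   `"replace"`.
#' @return character vector of paths written, invisibly.
#' @export
write_subject_csvs <- function(log, dir,
                               overwrite = c("error", "suffix", "replace")) {
  overwrite <- match.arg(overwrite)
  df <- if (inherits(log, "event_log")) as.data.frame(log) else log
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  keys <- unique(df[, c("subject_id", "session_id")])
  paths <- character(0)
  for (i in seq_len(nrow(keys))) {
    sub <- df[df$subject_id == keys$subject_id[i] &
              df$session_id == keys$session_id[i], , drop = FALSE]
    base <- sprintf("%s_s%d", keys$subject_id[i], keys$session_id[i])
    path <- file.path(dir, paste0(base, ".csv"))
    if (file.exists(path)) {
      if (overwrite == "error")
        stop("refusing to overwrite existing log: ", path)
      if (overwrite == "suffix") {
        k <- 1L
        while (file.exists(file.path(dir, sprintf("%s_%d.csv", base, k))))
          k <- k + 1L
        path <- file.path(dir, sprintf("%s_%d.csv", base, k))
      }
    }
    write_session_csv(sub, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
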