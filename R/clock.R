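#' Session clocks
#'
#' Tasks never read the system time directly; they read a clock object so a
#' whole session can run faster than real time. A simulated clock starts at 0
#' and only moves when advanced; a wall clock tracks elapsed real time and
#' advancing it sleeps.
#'
#' @param start starting time in seconds (simulated mode).
#' @return a `task_clock` object.
#' @export
sim_clock <- function(start = 0) {
  stopifnot(is.numeric(start), length(start) == 1L, start >= 0)
  clk <- new.env(parent = emptyenv())
  clk$mode <- "simulated"
  clk$now <- as.numeric(start)
  class(clk) <- "task_clock"
  clk
}

#' @rdname sim_clock
#' @export
wall_clock <- function() {
  clk <- new.env(parent = emptyenv())
  clk$mode <- "wall"
  clk$origin <- proc.time()[["elapsed"]]
  clk$last <- 0
  class(clk) <- "task_clock"
  clk
}

#' Read the current time of a clock
#'
#' Reads are monotone non-decreasing in both modes.
#'
#' @param clock a `task_clock`.
#' @return time in seconds.
#' @export
clock_now <- function(clock) {
  stopifnot(inherits(clock, "task_clock"))
  if (clock$mode == "simulated") return(clock$now)
  t <- proc.time()[["elapsed"]] - clock$origin
  clock$last <- max(clock$last, t)
  clock$last
}

#' Advance a clock by a number of seconds
#'
#' In simulated mode the clock jumps forward by exactly `d`; in wall mode the
#' call sleeps for `d` seconds.
#'
#' @param clock a `task_clock`.
#' @param d non-negative seconds.
#' @return the clock, invisibly.
#' @export
clock_advance <- function(clock, d) {
  stopifnot(inherits(clock, "task_clock"), is.numeric(d), length(d) == 1L,
            !is.na(d), d >= 0)
  if (clock$mode == "simulated") {
    clock$now <- clock$now + d
  } else {
    Sys.sleep(d)
  }
  invisible(clock)
}

#' @export
print.task_clock <- function(x, ...) {
  cat(sprintf("<task_clock: %s, now = %.3f s>\n", x$mode, clock_now(x)))
  invisible(x)
}
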