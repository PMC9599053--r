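## Simulated subjects.
##
## An agent closes the loop that an animal would: it chooses among the
## options a trial presents and produces touch events aimed at boxes, with
## the touch topology real pigs showed — scatter around the box centre and a
## systematic upward swipe offset. Choice among delayed rewards follows the
## standard hyperbolic (Mazur-form) discounted value, optionally softened by
## a softmax; the engine measures discounting, it does not assume this model,
## so the agent is purely a data generator.

AGENT_KINDS <- c("perfect", "nonresponder", "random_toucher", "hyperbolic",
                 "biased")

#' Define a simulated subject
#'
#' @param kind behavioral preset: `"perfect"` (immediate, always picks the
#'   highest-valued option, never omits), `"nonresponder"` (never touches),
#'   `"random_toucher"` (uniform choice among active options),
#'   `"hyperbolic"` (value-guided with discounting rate `k`), `"biased"`
#'   (contingency-naive: ignores the reward structure and chooses by its
#'   side/color bias terms plus softmax noise). The preset sets defaults;
#'   every parameter can still be overridden.
#' @param k hyperbolic discounting rate per second, >= 0.
#' @param temperature softmax inverse-precision, >= 0; 0 means greedy
#'   argmax choice.
#' @param side_bias,color_bias additive preference in \[-1, 1\]: positive
#'   favors left over right, green over blue. Biases enter the choice values
#'   scaled by the option magnitude range.
#' @param touch_sd touch scatter (screen fraction SD around the box centre).
#' @param swipe_offset mean upward press displacement (screen fraction),
#'   modelling the press-and-swipe-up topology.
#' @param response_latency_mean mean response latency, seconds
#'   (exponentially distributed; 0 = instantaneous).
#' @param omission_prob per-trial probability of withholding any response.
#' @return an `agent_policy`.
#' @export
agent_policy <- function(kind = AGENT_KINDS, k = 0, temperature = 0,
                         side_bias = 0, color_bias = 0, touch_sd = 0,
                         swipe_offset = 0, response_latency_mean = NULL,
                         omission_prob = NULL) {
  kind <- match.arg(kind)
  if (is.null(response_latency_mean))
    response_latency_mean <- switch(kind, perfect = 1, nonresponder = 0, 2)
  if (is.null(omission_prob))
    omission_prob <- if (kind == "nonresponder") 1 else 0
  stopifnot(k >= 0, temperature >= 0, touch_sd >= 0,
            abs(side_bias) <= 1, abs(color_bias) <= 1,
            omission_prob >= 0, omission_prob <= 1,
            response_latency_mean >= 0)
  structure(list(kind = kind, k = k, temperature = temperature,
                 side_bias = side_bias, color_bias = color_bias,
                 touch_sd = touch_sd, swipe_offset = swipe_offset,
                 response_latency_mean = response_latency_mean,
                 omission_prob = omission_prob),
            class = "agent_policy")
}

#' @export
print.agent_policy <- function(x, ...) {
  cat(sprintf(paste0("<agent_policy: %s (k=%g, temp=%g, side_bias=%g, ",
                     "color_bias=%g, omit=%g)>\n"),
              x$kind, x$k, x$temperature, x$side_bias, x$color_bias,
              x$omission_prob))
  invisible(x)
}

#' Hyperbolic discounted value
#'
#' The Mazur-form subjective value of `A` reward units delivered after `D`
#' seconds: `A / (1 + k D)`. Equal to `A` at zero delay or zero discounting
#' rate, and strictly decreasing in delay for `k > 0`.
#'
#' @param A reward magnitude (e.g. pellets), >= 0. Vectorised.
#' @param D delay to delivery, seconds, >= 0. Vectorised.
#' @param k discounting rate per second, >= 0.
#' @return discounted value(s).
#' @export
hyperbolic_value <- function(A, D, k) {
  stopifnot(all(A >= 0), all(D >= 0), k >= 0)
  A / (1 + k * D)
}

#' Choose among the options of a trial
#'
#' Options carry a reward magnitude, a delay, and side/color attributes. The
#' agent first draws an omission (probability `omission_prob`); otherwise a
#' single active option is taken directly (forced trials), and among several
#' the agent scores each option by its hyperbolic discounted value plus bias
#' offsets (side and color biases scaled by half the option magnitude range)
#' and picks the argmax (`temperature = 0`, seeded tie-break) or samples from
#' a softmax over the scores.
#'
#' @param agent an `agent_policy`.
#' @param options data frame with columns `id`, `magnitude`, `delay`,
#'   `side`, `color`, `active` (one row per option, >= 1 active).
#' @return the chosen option `id`, or `NA_character_` for an omission.
#' @export
agent_choose <- function(agent, options) {
  stopifnot(inherits(agent, "agent_policy"), is.data.frame(options),
            all(c("id", "magnitude", "delay", "side", "color", "active")
                %in% names(options)))
  act <- options[options$active, , drop = FALSE]
  if (nrow(act) == 0L) stop("trial has no active option")
  if (agent$omission_prob > 0 && stats::runif(1) < agent$omission_prob)
    return(NA_character_)
  if (nrow(act) == 1L) return(act$id[[1]])
  if (agent$kind == "random_toucher")
    return(act$id[[sample.int(nrow(act), 1L)]])
  # biased agents are contingency-naive: the reward structure does not enter
  # their scores, only the side/color biases (plus softmax noise) do
  v <- if (agent$kind == "biased") rep(0, nrow(act))
       else hyperbolic_value(act$magnitude, act$delay, agent$k)
  scale <- max(diff(range(act$magnitude)), 1) / 2
  v <- v + agent$side_bias * scale *
    ifelse(act$side == "left", 1, ifelse(act$side == "right", -1, 0))
  v <- v + agent$color_bias * scale *
    ifelse(act$color == "green", 1, ifelse(act$color == "blue", -1, 0))
  if (agent$temperature > 0) {
    w <- exp((v - max(v)) / agent$temperature)
    return(act$id[[sample.int(nrow(act), 1L, prob = w)]])
  }
  best <- which(v == max(v))
  if (length(best) > 1L) best <- best[[sample.int(length(best), 1L)]]
  act$id[[best]]
}

#' Draw a response latency
#'
#' Exponential with the agent's mean latency (0 means instantaneous).
#'
#' @param agent an `agent_policy`.
#' @return latency in seconds.
#' @export
agent_latency <- function(agent) {
  if (agent$response_latency_mean <= 0) return(0)
  stats::rexp(1, rate = 1 / agent$response_latency_mean)
}

#' Produce the touch events for one press at a target box
#'
#' The press lands at the box centre plus isotropic Gaussian scatter
#' (`touch_sd`) displaced upward by `swipe_offset`; the matching release is
#' displaced further upward (the swipe). Points are clamped to the unit
#' square. A `nonresponder` produces no events.
#'
#' @param agent an `agent_policy`.
#' @param box the target `response_box`.
#' @param timestamp press time, seconds; the release follows
#'   `release_after` seconds later.
#' @param release_after press-to-release interval, seconds.
#' @return list of `touch_event`s (press then release), or an empty list.
#' @export
emit_touch <- function(agent, box, timestamp = 0, release_after = 0.1) {
  stopifnot(inherits(agent, "agent_policy"), inherits(box, "response_box"))
  if (agent$kind == "nonresponder") return(list())
  clamp <- function(v) pmin(1, pmax(0, v))
  cx <- box$x + box$w / 2
  cy <- box$y + box$h / 2
  scatter <- if (agent$touch_sd > 0) stats::rnorm(2, 0, agent$touch_sd)
             else c(0, 0)
  px <- clamp(cx + scatter[[1]])
  py <- clamp(cy + scatter[[2]] - agent$swipe_offset)
  ry <- clamp(py - agent$swipe_offset -
                if (agent$touch_sd > 0) abs(stats::rnorm(1, 0, agent$touch_sd))
                else 0)
  list(touch_event(px, py, "press", timestamp),
       touch_event(px, ry, "release", timestamp + release_after))
}
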