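## Screen geometry and press-on-touch hit testing.
##
## All coordinates are fractions of the screen in [0, 1], origin top-left.
## Responses register on the initial press, never on release: pigs press and
## then swipe upward, so acting on release misattributes the response. An
## optional invisible hit region extending above the visible rectangle
## absorbs presses that land slightly above the button.

BOX_COLORS <- c("yellow", "blue", "green", "inactive_gray")

## token -> default RGB rendering for display backends
COLOR_RGB <- c(yellow = "#FFFF00", blue = "#0000FF", green = "#00FF00",
               inactive_gray = "#808080")

#' Define a response box
#'
#' A rectangular on-screen button. `active = FALSE` boxes are rendered (e.g.
#' the disabled option of a correction trial) but never register responses.
#' `hit_extension_above` enlarges the touchable region upward by that screen
#' fraction without changing the visible rectangle.
#'
#' @param id box identifier (character scalar).
#' @param x,y top-left corner, screen fractions.
#' @param w,h width and height, screen fractions.
#' @param color one of `"yellow"`, `"blue"`, `"green"`, `"inactive_gray"`.
#' @param active logical; inactive boxes never register presses.
#' @param hit_extension_above extra touchable region above the box, screen
#'   fraction >= 0 (default 0 = off).
#' @param fr_requirement fixed-ratio requirement, integer >= 1.
#' @return a `response_box`.
#' @export
response_box <- function(id, x, y, w, h, color = "yellow", active = TRUE,
                         hit_extension_above = 0, fr_requirement = 1L) {
  color <- match.arg(color, BOX_COLORS)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            w > 0, h > 0, x >= 0, y >= 0, x + w <= 1 + 1e-9, y + h <= 1 + 1e-9,
            hit_extension_above >= 0, fr_requirement >= 1)
  box <- list(id = id, x = x, y = y, w = w, h = h, color = color,
              active = isTRUE(active),
              hit_extension_above = hit_extension_above,
              fr_requirement = as.integer(fr_requirement), fr_count = 0L)
  class(box) <- "response_box"
  box
}

box_hit_rect <- function(box) {
  c(x0 = box$x, y0 = max(0, box$y - box$hit_extension_above),
    x1 = box$x + box$w, y1 = box$y + box$h)
}

rects_overlap <- function(a, b) {
  a[["x0"]] < b[["x1"]] && b[["x0"]] < a[["x1"]] &&
    a[["y0"]] < b[["y1"]] && b[["y0"]] < a[["y1"]]
}

#' Assemble a screen layout
#'
#' Validates at construction time that every box lies within the unit square
#' and that no two *active* touchable regions (visible rectangle plus upward
#' hit extension) overlap, so hit testing is never ambiguous.
#'
#' @param ... `response_box` objects, or a single list of them.
#' @return a `screen_geometry` (list of boxes).
#' @export
screen_geometry <- function(...) {
  boxes <- list(...)
  if (length(boxes) == 1L && !inherits(boxes[[1]], "response_box"))
    boxes <- boxes[[1]]
  stopifnot(length(boxes) >= 1L,
            all(vapply(boxes, inherits, logical(1), "response_box")))
  ids <- vapply(boxes, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate box ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  act <- which(vapply(boxes, `[[`, logical(1), "active"))
  if (length(act) > 1L) {
    rects <- lapply(boxes[act], box_hit_rect)
    for (i in seq_along(act)[-1]) for (j in seq_len(i - 1L))
      if (rects_overlap(rects[[i]], rects[[j]]))
        stop(sprintf("active boxes '%s' and '%s' overlap",
                     ids[act[i]], ids[act[j]]))
  }
  names(boxes) <- ids
  structure(boxes, class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry: %d boxes>\n", length(x)))
  for (b in x)
    cat(sprintf("  %-8s %s%s at (%.2f, %.2f) %.2f x %.2f fr=%d\n", b$id,
                b$color, if (b$active) "" else " (inactive)",
                b$x, b$y, b$w, b$h, b$fr_requirement))
  invisible(x)
}

#' Create a touch event
#'
#' @param x,y touch point, screen fractions in \[0, 1\].
#' @param kind `"press"` or `"release"`.
#' @param timestamp seconds.
#' @return a `touch_event`.
#' @export
touch_event <- function(x, y, kind = c("press", "release"), timestamp = 0) {
  kind <- match.arg(kind)
  stopifnot(x >= 0, x <= 1, y >= 0, y <= 1, timestamp >= 0)
  structure(list(x = x, y = y, kind = kind, timestamp = timestamp),
            class = "touch_event")
}

#' Hit-test a touch against a screen layout
#'
#' Only initial presses are eligible: release events never register (the
#' stock toolkit default of responding on release is deliberately inverted).
#' A press registers on the unique active box whose visible rectangle,
#' extended upward by its `hit_extension_above`, contains the point.
#'
#' @param geometry a `screen_geometry`.
#' @param touch a `touch_event`.
#' @return the matching box id, or `NA_character_` when nothing registers.
#' @export
hit_test <- function(geometry, touch) {
  stopifnot(inherits(geometry, "screen_geometry"),
            inherits(touch, "touch_event"))
  if (touch$kind != "press") return(NA_character_)
  for (box in geometry) {
    if (!box$active) next
    r <- box_hit_rect(box)
    if (touch$x >= r[["x0"]] && touch$x <= r[["x1"]] &&
        touch$y >= r[["y0"]] && touch$y <= r[["y1"]])
      return(box$id)
  }
  NA_character_
}

#' Register one press against a fixed-ratio requirement
#'
#' Increments the box's press counter; the requirement is fulfilled when the
#' counter reaches `fr_requirement`, at which point the counter resets. Under
#' FR-n, `floor(presses / n)` fulfilments occur.
#'
#' @param box an active `response_box`.
#' @return list with elements `box` (updated) and `fulfilled` (logical).
#' @export
fr_register <- function(box) {
  stopifnot(inherits(box, "response_box"))
  if (!box$active) stop("cannot register a press on an inactive box")
  box$fr_count <- box$fr_count + 1L
  fulfilled <- box$fr_count >= box$fr_requirement
  if (fulfilled) box$fr_count <- 0L
  list(box = box, fulfilled = fulfilled)
}
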