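#' Construct a writing session
#'
#' A writing session is the raw record of one subject writing the task
#' character ten times on a touch screen: an ordered stream of touch events
#' plus screen geometry and task constants. Events carry integer-millisecond
#' timestamps (`t_ms`), pixel coordinates (`x_px`, `y_px`; origin top-left,
#' y down) and a `phase` in `down`/`move`/`up`. The phase sequence must form
#' `(down move* up)*`: every finger-down has a matching later finger-up, and
#' a single pointer is assumed.
#'
#' Sessions whose last event falls beyond the task time limit are not
#' truncated: they are flagged invalid (`valid = FALSE`) and carry the
#' reason, mirroring the paradigm rule that subjects exceeding the limit
#' are excluded rather than censored.
#'
#' @param events Data frame with columns `t_ms`, `x_px`, `y_px`, `phase`.
#' @param subject_id Opaque subject identifier.
#' @param screen_w,screen_h Screen size in pixels.
#' @param task_char_count Number of characters the task asks for (10).
#' @param time_limit Task time limit in seconds (180).
#' @return An object of class `writing_session`.
#' @examples
#' ev <- tibble::tibble(
#'   t_ms = c(0L, 16L, 33L), x_px = c(10, 12, 14), y_px = c(10, 10, 10),
#'   phase = c("down", "move", "up")
#' )
#' writing_session(ev, subject_id = "s01")
#' @export
writing_session <- function(events, subject_id = "anon",
                            screen_w = 1920, screen_h = 1080,
                            task_char_count = 10, time_limit = 180) {
  events <- validate_events(events)
  s <- structure(
    list(
      subject_id = as.character(subject_id),
      events = events,
      screen_w = screen_w, screen_h = screen_h,
      task_char_count = as.integer(task_char_count),
      time_limit = time_limit,
      valid = TRUE, invalid_reason = NA_character_
    ),
    class = "writing_session"
  )
  if (nrow(events) > 0 && max(events$t_ms) > time_limit * 1000) {
    s$valid <- FALSE
    s$invalid_reason <- sprintf(
      "task duration %.1f s exceeds the %d s limit",
      max(events$t_ms) / 1000, as.integer(time_limit)
    )
  }
  s
}

# validate the raw event table: schema, ordering, phase grammar.
# Errors name the first offending row.
validate_events <- function(events) {
  events <- as_tibble(events)
  req <- c("t_ms", "x_px", "y_px", "phase")
  missing_cols <- setdiff(req, names(events))
  if (length(missing_cols) > 0) {
    abort(paste0("events lack required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "graphomarker_schema_error")
  }
  events <- events[req]
  if (nrow(events) == 0) {
    events$t_ms <- integer(0)
    return(events)
  }
  if (any(is.na(events$t_ms)) || any(events$t_ms != round(events$t_ms))) {
    abort("t_ms must be integer milliseconds with no missing values",
          class = "graphomarker_schema_error")
  }
  events$t_ms <- as.integer(round(events$t_ms))
  if (any(events$t_ms < 0)) {
    abort(sprintf("negative timestamp at row %d",
                  which(events$t_ms < 0)[1]),
          class = "graphomarker_schema_error")
  }
  if (any(is.na(events$x_px)) || any(is.na(events$y_px)) ||
      any(events$x_px < 0) || any(events$y_px < 0)) {
    abort("coordinates must be non-negative and non-missing",
          class = "graphomarker_schema_error")
  }
  # storage type must not depend on the source dialect
  events$x_px <- as.numeric(events$x_px)
  events$y_px <- as.numeric(events$y_px)
  bad_phase <- !events$phase %in% c("down", "move", "up")
  if (any(bad_phase)) {
    abort(sprintf("unknown phase '%s' at row %d",
                  events$phase[which(bad_phase)[1]], which(bad_phase)[1]),
          class = "graphomarker_schema_error")
  }
  dt <- diff(events$t_ms)
  if (any(dt < 0)) {
    abort(sprintf("timestamps not sorted: row %d precedes row %d in time",
                  which(dt < 0)[1] + 1L, which(dt < 0)[1]),
          class = "graphomarker_order_error")
  }
  if (any(dt == 0)) {
    abort(sprintf(
      "tied timestamps at rows %d-%d: multi-touch is not supported",
      which(dt == 0)[1], which(dt == 0)[1] + 1L
    ), class = "graphomarker_order_error")
  }
  check_phase_grammar(events$phase)
  events
}

# enforce (down move* up)*; errors carry the first offending event index.
# Vectorised: the finger state before event i is the running balance of
# downs minus ups; a down needs balance 0, move/up need balance 1.
check_phase_grammar <- function(phase) {
  if (length(phase) == 0) return(invisible(TRUE))
  balance <- cumsum(phase == "down") - cumsum(phase == "up")
  before <- c(0L, balance[-length(balance)])
  bad <- (phase == "down" & before != 0L) |
    (phase != "down" & before != 1L)
  if (any(bad)) {
    i <- which(bad)[1]
    what <- if (phase[i] == "down") "down while finger already down"
            else paste0(phase[i], " without a preceding down")
    abort(sprintf("malformed phase sequence: %s at event %d", what, i),
          class = "graphomarker_phase_error")
  }
  if (balance[length(balance)] != 0L) {
    abort("malformed phase sequence: stream ends with the finger down (dangling stroke)",
          class = "graphomarker_phase_error")
  }
  invisible(TRUE)
}

#' @export
print.writing_session <- function(x, ...) {
  n_down <- sum(x$events$phase == "down")
  cat(sprintf(
    "<writing_session> subject %s: %d events, %d strokes, %.2f s%s\n",
    x$subject_id, nrow(x$events), n_down,
    if (nrow(x$events)) max(x$events$t_ms) / 1000 else 0,
    if (x$valid) "" else paste0(" [INVALID: ", x$invalid_reason, "]")
  ))
  invisible(x)
}

#' @export
format.writing_session <- function(x, ...) {
  sprintf("<writing_session %s: %d events>", x$subject_id, nrow(x$events))
}
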