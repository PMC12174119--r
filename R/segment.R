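#' Segment a writing session into strokes and pauses
#'
#' Splits the touch-event stream into strokes (each finger-down to the
#' matching finger-up) and the pauses around them. All times are converted
#' from integer milliseconds to seconds at this boundary; downstream
#' biomarker math works in seconds and pixels.
#'
#' The decomposition is exact by construction:
#' `total_time = initial_pause + sum(durations) + sum(gaps)`,
#' where `initial_pause` runs from session start (t = 0) to the first
#' finger-down, each stroke duration from its down to its up, and each
#' inter-stroke gap from one stroke's up to the next stroke's down.
#'
#' @param session A [writing_session()].
#' @return An object of class `segmented_session`: a list with
#'   * `strokes` — tibble with one row per stroke: `j`, `t_start`, `t_end`,
#'     `duration` (s), `length` (px), `speed` (px/s, `length/duration`,
#'     0 for zero-duration strokes), and a `points` list-column of
#'     per-stroke `(t, x, y)` tibbles (t in seconds);
#'   * `gaps` — numeric vector of the `J - 1` inter-stroke pauses (s);
#'   * `initial_pause`, `total_time` (s);
#'   * `subject_id`, `task_char_count` carried over from the session.
#' @examples
#' ev <- tibble::tibble(
#'   t_ms = c(2000L, 3000L, 5000L, 7000L),
#'   x_px = c(0, 50, 0, 80), y_px = c(0, 0, 10, 10),
#'   phase = c("down", "up", "down", "up")
#' )
#' seg <- segment_strokes(writing_session(ev))
#' seg$initial_pause  # 2
#' seg$gaps           # 2
#' seg$total_time     # 7
#' @export
segment_strokes <- function(session) {
  stopifnot(inherits(session, "writing_session"))
  ev <- session$events
  if (nrow(ev) == 0 || !any(ev$phase == "down")) {
    abort("session contains no strokes", class = "graphomarker_empty_error")
  }
  # grammar already validated at construction; recheck defensively so the
  # function is safe on hand-built lists too
  check_phase_grammar(ev$phase)

  downs <- which(ev$phase == "down")
  ups <- which(ev$phase == "up")

  J <- length(downs)
  t_start <- t_end <- duration <- len <- numeric(J)
  points <- vector("list", J)
  for (j in seq_len(J)) {
    idx <- downs[j]:ups[j]
    pts <- fast_points(ev$t_ms[idx] / 1000, ev$x_px[idx], ev$y_px[idx])
    n <- length(idx)
    t_start[j] <- pts$t[1]
    t_end[j] <- pts$t[n]
    duration[j] <- pts$t[n] - pts$t[1]
    len[j] <- polyline_length(pts$x, pts$y)
    points[[j]] <- pts
  }
  strokes <- tibble(
    j = seq_len(J), t_start = t_start, t_end = t_end,
    duration = duration, length = len,
    speed = ifelse(duration > 0, len / duration, 0),
    points = points
  )

  gaps <- if (nrow(strokes) > 1) {
    strokes$t_start[-1] - strokes$t_end[-nrow(strokes)]
  } else {
    numeric(0)
  }

  structure(
    list(
      strokes = strokes,
      gaps = gaps,
      initial_pause = strokes$t_start[1],
      total_time = strokes$t_end[nrow(strokes)],
      subject_id = session$subject_id,
      task_char_count = session$task_char_count
    ),
    class = "segmented_session"
  )
}

# minimal-overhead data frame for per-stroke (t, x, y) points
fast_points <- function(t, x, y) {
  structure(list(t = t, x = x, y = y), class = "data.frame",
            row.names = c(NA_integer_, -length(t)))
}

#' @export
print.segmented_session <- function(x, ...) {
  cat(sprintf(
    "<segmented_session> %s: J = %d strokes, initial pause %.2f s, total %.2f s\n",
    x$subject_id, nrow(x$strokes), x$initial_pause, x$total_time
  ))
  invisible(x)
}
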