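#' @title Writing-process digital biomarkers
#' @description
#' Twenty-one per-session features quantify how a subject plans and executes
#' the writing task. Ten information-processing-speed biomarkers
#' (`IPSDB_1..10`) are timing and pause features; eleven executive-function
#' biomarkers (`EFDB_1..11`) are stroke-count, trajectory-length, speed and
#' task-score features. With `J` strokes of duration `t_j`, length `D_j`
#' (px), speed `v_j = D_j / t_j` and inter-stroke gaps `g_1..g_{J-1}`:
#'
#' * `IPSDB_1` total task time (s): session start to last finger-up.
#' * `IPSDB_2` task process time: `IPSDB_1 - IPSDB_5`.
#' * `IPSDB_3` writing time: `sum(t_j)`.
#' * `IPSDB_4` total pause time: `IPSDB_5 + IPSDB_6`.
#' * `IPSDB_5` initial pause: session start to first finger-down.
#' * `IPSDB_6` total process pause: `sum(g)`.
#' * `IPSDB_7` maximum process pause: `max(g)`.
#' * `IPSDB_8` average process pause: `IPSDB_6 / (J - 1)`.
#' * `IPSDB_9` pause variability: coefficient of variation of the gaps
#'   (population SD / mean).
#' * `IPSDB_10` number of within-stroke pauses, see
#'   [count_within_stroke_pauses()].
#' * `EFDB_1` task score in 0..2, see [score_task()].
#' * `EFDB_2` stroke count `J`.
#' * `EFDB_3` strokes per minute: `J / IPSDB_1 * 60`.
#' * `EFDB_4` writing efficiency: `IPSDB_3 / IPSDB_1`.
#' * `EFDB_5` total trajectory length: `sum(D_j)`.
#' * `EFDB_6` maximum trajectory length: `max(D_j)`.
#' * `EFDB_7` average trajectory length: `EFDB_5 / J`.
#' * `EFDB_8` trajectory-length variability: CV of `D_j`.
#' * `EFDB_9` maximum stroke speed: `max(v_j)`.
#' * `EFDB_10` average stroke speed: `mean(v_j)`.
#' * `EFDB_11` speed variability: population SD of `v_j` / `EFDB_10`.
#'
#' Gap statistics (`IPSDB_7/8/9`) are undefined for single-stroke sessions
#' and returned as `NA`, never 0. Coefficients of variation use the
#' population (divide-by-n) standard deviation throughout. Zero-duration
#' strokes with positive length would make `v_j` infinite; they are
#' excluded from the speed statistics with a warning.
#'
#' @param seg A [segment_strokes()] result.
#' @param min_pause_ms Within-stroke stationary-run duration threshold for
#'   `IPSDB_10`, in milliseconds (default 50).
#' @param template Glyph template for the task score, see
#'   [glyph_template()].
#' @return A one-row tibble with the ten `IPSDB_*` (or eleven `EFDB_*`)
#'   columns.
#' @examples
#' s <- simulate_session(group = "HC", seed = 1)
#' seg <- segment_strokes(s)
#' compute_ipsdb(seg)
#' compute_efdb(seg)
#' @name biomarkers
NULL

# population (divide-by-n) standard deviation
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

pop_cv <- function(x) {
  m <- mean(x, na.rm = TRUE)
  if (!is.finite(m) || m == 0) return(NA_real_)
  pop_sd(x) / m
}

#' @rdname biomarkers
#' @export
compute_ipsdb <- function(seg, min_pause_ms = 50) {
  stopifnot(inherits(seg, "segmented_session"))
  J <- nrow(seg$strokes)
  g <- seg$gaps
  ipsdb_1 <- seg$total_time
  ipsdb_5 <- seg$initial_pause
  ipsdb_3 <- sum(seg$strokes$duration)
  ipsdb_6 <- sum(g)
  tibble(
    IPSDB_1 = ipsdb_1,
    IPSDB_2 = ipsdb_1 - ipsdb_5,
    IPSDB_3 = ipsdb_3,
    IPSDB_4 = ipsdb_5 + ipsdb_6,
    IPSDB_5 = ipsdb_5,
    IPSDB_6 = ipsdb_6,
    IPSDB_7 = if (J > 1) max(g) else NA_real_,
    IPSDB_8 = if (J > 1) ipsdb_6 / (J - 1) else NA_real_,
    IPSDB_9 = if (J > 1) pop_cv(g) else NA_real_,
    IPSDB_10 = count_within_stroke_pauses(seg, min_pause_ms = min_pause_ms)
  )
}

#' @rdname biomarkers
#' @export
compute_efdb <- function(seg, template = glyph_template()) {
  stopifnot(inherits(seg, "segmented_session"))
  st <- seg$strokes
  J <- nrow(st)
  ipsdb_1 <- seg$total_time
  ipsdb_3 <- sum(st$duration)

  # speed stats exclude degenerate zero-duration strokes that still moved
  degenerate <- st$duration == 0 & st$length > 0
  if (any(degenerate)) {
    warn(sprintf(
      "%d zero-duration stroke(s) with positive length excluded from speed statistics",
      sum(degenerate)
    ))
  }
  v <- st$speed[!degenerate]

  efdb_5 <- sum(st$length)
  tibble(
    EFDB_1 = score_task(seg, template)$score,
    EFDB_2 = J,
    EFDB_3 = J / ipsdb_1 * 60,
    EFDB_4 = ipsdb_3 / ipsdb_1,
    EFDB_5 = efdb_5,
    EFDB_6 = max(st$length),
    EFDB_7 = efdb_5 / J,
    EFDB_8 = pop_cv(st$length),
    EFDB_9 = if (length(v)) max(v) else NA_real_,
    EFDB_10 = if (length(v)) mean(v) else NA_real_,
    EFDB_11 = if (length(v)) pop_sd(v) / mean(v) else NA_real_
  )
}

#' Count within-stroke stationary pauses
#'
#' The raw device signal for a "pause" inside a stroke is a run of
#' consecutive samples with identical coordinates. With
#' `min_pause_ms = 0` this returns the raw count of duplicated adjacent
#' coordinate pairs inside strokes (so a held position spanning `m`
#' samples contributes `m - 1`). With a positive threshold it instead
#' counts maximal stationary runs whose duration reaches the threshold,
#' which de-couples the count from the device sampling rate; the default of
#' 50 ms suppresses single-sample coincidences at typical 60 Hz sampling.
#'
#' @param seg A [segment_strokes()] result.
#' @param min_pause_ms Minimum stationary-run duration in milliseconds.
#' @return Integer pause count (the `IPSDB_10` biomarker).
#' @export
count_within_stroke_pauses <- function(seg, min_pause_ms = 50) {
  stopifnot(inherits(seg, "segmented_session"), min_pause_ms >= 0)
  total <- 0L
  for (pts in seg$strokes$points) {
    n <- nrow(pts)
    if (n < 2) next
    same <- pts$x[-1] == pts$x[-n] & pts$y[-1] == pts$y[-n]
    if (min_pause_ms == 0) {
      total <- total + sum(same)
    } else {
      # maximal runs of `same`; run over pairs i..k covers samples i..k+1,
      # so its duration is t[k + 1] - t[i]
      r <- rle(same)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (q in which(r$values)) {
        dur_ms <- (pts$t[ends[q] + 1L] - pts$t[starts[q]]) * 1000
        if (dur_ms >= min_pause_ms) total <- total + 1L
      }
    }
  }
  as.integer(total)
}

#' Extract the full biomarker vector from a session
#'
#' Convenience wrapper: segments the session and binds the ten
#' information-processing-speed and eleven executive-function biomarkers
#' into one row, keyed by subject.
#'
#' @param session A [writing_session()].
#' @param min_pause_ms Threshold passed to [count_within_stroke_pauses()].
#' @param template Glyph template passed to [score_task()].
#' @return A one-row tibble: `subject_id`, `valid`, then the 21 biomarkers.
#' @examples
#' extract_biomarkers(simulate_session(group = "HC", seed = 1))
#' @export
extract_biomarkers <- function(session, min_pause_ms = 50,
                               template = glyph_template()) {
  seg <- segment_strokes(session)
  dplyr::bind_cols(
    tibble(subject_id = session$subject_id, valid = session$valid),
    compute_ipsdb(seg, min_pause_ms = min_pause_ms),
    compute_efdb(seg, template = template)
  )
}
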