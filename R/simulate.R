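#' Simulation parameters for synthetic writing sessions
#'
#' The generator emulates the writing paradigm: ten instances of the
#' six-stroke task character, laid out left-to-right / top-to-bottom on a
#' touch screen, traversed stroke by stroke at sampled speeds with sampled
#' pauses in between. It is hierarchical: subject-level latents (median
#' pause, writing speed, glyph size, ...) are drawn from group-level
#' log-normal distributions, and within-session quantities (individual
#' gaps, per-stroke speeds) are drawn around the subject latents. Group
#' contrasts therefore show up in the extracted biomarker distributions
#' the same way they would across a cohort of real subjects.
#'
#' Group-level parameters (`med` = median of the subject latent, `sig` =
#' between-subject log-scale SD):
#' * `initial_pause_med/_sig` — initial pause before the first stroke (s).
#' * `gap_med/_sig` — within-character inter-stroke gap (s);
#'   `gap_cv_med/_sig` — within-subject log-scale SD of the gaps, the knob
#'   behind pause variability; `char_gap_mult` — multiplier applied to the
#'   nine between-character gaps (between-character pauses are longer than
#'   within-character ones).
#' * `stroke_time_med/_sig` — subject's base stroke duration (s).
#'   Following the isochrony principle of handwriting (stroke duration is
#'   roughly independent of stroke extent, i.e. speed scales with stroke
#'   length), each stroke takes `t_base * exp(E)` seconds regardless of
#'   its length, with `E ~ Exp(mean = slow_tail_med)` truncated at
#'   `slow_tail_cap` — a right-skewed slowdown term. Stroke speed is then
#'   `length / duration`, so average speed (`EFDB_10`) is set by the base
#'   duration and speed variability (`EFDB_11`) by the slowdown tail
#'   (plus the stroke-length spread).
#' * `scale_med/_sig` — glyph size (px); `style_sig` — log-scale SD of a
#'   subject's personal per-template-stroke length multipliers (each
#'   subject draws six once and writes every character with their own
#'   stroke proportions, the dominant source of between-subject spread in
#'   trajectory-length variability); `style_sig_sig` — log-scale SD of the
#'   subject-to-subject variation in that style spread (some subjects
#'   write very evenly, others do not); `stroke_len_jitter` — small
#'   residual per-stroke-instance length jitter.
#' * `speed_max_med/_sig` — the subject's personal ceiling on sweep
#'   speed (px/s): a stroke whose isochronous duration would imply a
#'   faster sweep is slowed to it. Peak sweep speed is limited by the
#'   hand rather than by cognition, so the group medians are nearly
#'   equal (the group spreads are set from the published maximum-speed
#'   IQRs, which differ strongly); most subjects' fastest strokes
#'   saturate at their ceiling, which therefore sets the maximum-speed
#'   biomarker directly.
#' * `pause_rate_med/_sig` — expected injected stationary holds per stroke
#'   (Poisson), driving the within-stroke pause count; `hold_ms` — hold
#'   duration (longer freezes slow the affected strokes, adding to speed
#'   variability without touching peak sweep speed).
#' * `order_error_rate` — probability the session scrambles stroke order
#'   within characters; `char_count_error_rate` — probability of writing
#'   9 or 11 characters instead of 10.
#' * `sampling_rate` (Hz), `jitter_px` (coordinate noise SD), `n_chars`.
#'
#' `default_sim_params()` ships the study calibration: parameters fitted
#' with [calibrate_sim_params()] so the extracted biomarker medians match
#' the published per-group summaries (see
#' [reference_group_summaries()]), with between-subject sigmas set from
#' the published IQRs by log-normal quantile matching.
#'
#' @param ... Named overrides of the defaults listed above.
#' @return `sim_group_params()`: a named list for one group;
#'   `default_sim_params()`: a list with `HC` and `MCI` entries.
#' @export
sim_group_params <- function(...) {
  p <- list(
    initial_pause_med = 3.40, initial_pause_sig = 1.05,
    gap_med = 0.2078, gap_sig = 0.37,
    gap_cv_med = 0.1081, gap_cv_sig = 0.89, gap_cv_cap = 1.2,
    char_gap_mult = 1.1, gap_max_s = 15,
    stroke_time_med = 0.05925, stroke_time_sig = 0.23,
    slow_tail_med = 0.9103, slow_tail_sig = 0.45,
    slow_tail_cap = 4,
    scale_med = 266.1, scale_sig = 0.24,
    style_sig = 0.4467, style_sig_sig = 0.8,
    stroke_len_jitter = 0.06,
    speed_max_med = 1350, speed_max_sig = 0.215,
    pause_rate_med = 0.7142, pause_rate_sig = 0.12,
    hold_ms = 70,
    order_error_rate = 0.62, char_count_error_rate = 0.58,
    sampling_rate = 60, jitter_px = 1, n_chars = 10,
    time_limit = 180
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown) > 0) {
    abort(paste0("unknown simulation parameter(s): ",
                 paste(unknown, collapse = ", ")))
  }
  modifyList(p, dots)
}

#' @rdname sim_group_params
#' @export
default_sim_params <- function() {
  list(
    HC = sim_group_params(),
    MCI = sim_group_params(
      initial_pause_med = 7.05, initial_pause_sig = 0.62,
      gap_med = 0.2275, gap_sig = 0.45,
      gap_cv_med = 0.4218, gap_cv_sig = 1.05,
      char_gap_mult = 2.5,
      stroke_time_med = 0.01907, stroke_time_sig = 0.41,
      slow_tail_med = 2.2, slow_tail_sig = 0.46,
      scale_med = 240.7, scale_sig = 0.33,
      style_sig = 0.78,
      speed_max_med = 1350, speed_max_sig = 0.47,
      pause_rate_med = 0.7951, pause_rate_sig = 0.30,
      hold_ms = 170,
      order_error_rate = 0.70, char_count_error_rate = 0.72
    )
  )
}

# run code under a private, restored RNG state with fixed generators so
# sessions are reproducible across platforms
with_sim_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

#' Simulate one writing session
#'
#' Generates the full touch-event stream of one synthetic subject writing
#' the task character `n_chars` times: characters laid out on a grid,
#' each stroke traversed at its sampled speed with events emitted at the
#' device sampling rate, integer-millisecond timestamps and integer pixel
#' coordinates. Fully reproducible given `(params, group, seed)`.
#'
#' @param params A two-group parameter list, see [default_sim_params()].
#' @param group `"HC"` or `"MCI"` — which group's parameters to draw from.
#' @param seed Integer seed.
#' @param subject_id Subject identifier (default derived from group/seed).
#' @return A [writing_session()].
#' @examples
#' s <- simulate_session(group = "MCI", seed = 42)
#' extract_biomarkers(s)
#' @export
simulate_session <- function(params = default_sim_params(), group = "HC",
                             seed = 1, subject_id = NULL) {
  stopifnot(group %in% names(params))
  p <- params[[group]]
  subject_id <- subject_id %||% sprintf("%s_seed%d", group, as.integer(seed))

  with_sim_seed(seed, {
    # subject-level latents
    initial_pause <- rlnorm(1, log(p$initial_pause_med), p$initial_pause_sig)
    gap_s <- rlnorm(1, log(p$gap_med), p$gap_sig)
    gap_cv_s <- min(rlnorm(1, log(max(p$gap_cv_med, 1e-6)), p$gap_cv_sig),
                    p$gap_cv_cap)
    time_s <- rlnorm(1, log(p$stroke_time_med), p$stroke_time_sig)
    tail_s <- rlnorm(1, log(max(p$slow_tail_med, 1e-6)), p$slow_tail_sig)
    scale_s <- rlnorm(1, log(p$scale_med), p$scale_sig)
    rate_s <- rlnorm(1, log(max(p$pause_rate_med, 1e-9)), p$pause_rate_sig)
    vmax_s <- rlnorm(1, log(p$speed_max_med), p$speed_max_sig)
    # personal glyph proportions: per-template-stroke length multipliers,
    # with the spread itself varying between subjects
    style_sig_s <- rlnorm(1, log(max(p$style_sig, 1e-6)), p$style_sig_sig)
    # clamp: even idiosyncratic writers keep strokes within the glyph
    style_s <- pmin(pmax(exp(rnorm(6, 0, style_sig_s)), 0.4), 2.5)

    n_chars <- p$n_chars
    if (runif(1) < p$char_count_error_rate) {
      n_chars <- n_chars + sample(c(-1L, 1L), 1)
    }
    scramble <- runif(1) < p$order_error_rate

    template <- glyph_template()
    tmpl_pts <- split(template[c("x", "y")], template$stroke)
    n_tmpl <- length(tmpl_pts)

    # grid layout: 5 characters per row
    per_row <- 5
    spacing <- scale_s * 1.3
    margin <- scale_s * 0.25

    dt_ms <- 1000 / p$sampling_rate
    hold_n <- max(2L, as.integer(ceiling(p$hold_ms / dt_ms)) + 1L)

    t_ms <- numeric(0); x_px <- numeric(0); y_px <- numeric(0)
    phase <- character(0)
    cursor <- initial_pause * 1000
    first_stroke <- TRUE

    for (ch in seq_len(n_chars)) {
      col <- (ch - 1) %% per_row
      row <- (ch - 1) %/% per_row
      x0 <- margin + col * spacing
      y0 <- margin + row * spacing

      order_idx <- seq_len(n_tmpl)
      if (scramble) {
        # any non-identity permutation
        repeat {
          order_idx <- sample(n_tmpl)
          if (!identical(order_idx, seq_len(n_tmpl))) break
        }
      }

      for (s_i in order_idx) {
        # pause before this stroke
        if (!first_stroke) {
          mult <- if (s_i == order_idx[1]) p$char_gap_mult else 1
          gap <- min(mult * rlnorm(1, log(gap_s), gap_cv_s), p$gap_max_s)
          cursor <- cursor + max(gap * 1000, 2)
        }
        first_stroke <- FALSE

        base <- tmpl_pts[[s_i]]
        len_mult <- style_s[s_i] * exp(rnorm(1, 0, p$stroke_len_jitter))
        cx <- mean(base$x); cy <- mean(base$y)
        sx <- x0 + (cx + (base$x - cx) * len_mult) * scale_s
        sy <- y0 + (cy + (base$y - cy) * len_mult) * scale_s
        # jitter is applied to the stroke's control vertices (a wobble of
        # the drawn path), not per sample: independent per-sample noise
        # would inflate the polyline length by a random-walk term growing
        # with the sample count
        if (p$jitter_px > 0) {
          sx <- sx + rnorm(length(sx), 0, p$jitter_px)
          sy <- sy + rnorm(length(sy), 0, p$jitter_px)
        }

        len <- polyline_length(sx, sy)
        slow <- min(stats::rexp(1, rate = 1 / tail_s), p$slow_tail_cap)
        dur_ms <- max(time_s * exp(slow), len / vmax_s) * 1000
        n_pts <- max(2L, as.integer(round(dur_ms / dt_ms)) + 1L)

        # arc-length resampling of the stroke polyline
        seg_len <- sqrt(diff(sx)^2 + diff(sy)^2)
        cum <- c(0, cumsum(seg_len))
        at <- seq(0, cum[length(cum)], length.out = n_pts)
        px <- stats::approx(cum, sx, xout = at, ties = "ordered")$y
        py <- stats::approx(cum, sy, xout = at, ties = "ordered")$y
        ts <- cursor + (seq_len(n_pts) - 1) * dt_ms

        # injected stationary holds: repeat a sample in place
        n_holds <- rpois(1, rate_s)
        if (n_holds > 0) {
          # a freeze can happen at any sample from touch-down up to (but
          # not at) lift-off, including very short strokes
          pool <- seq(1L, n_pts - 1L)
          at_idx <- sort(pool[sample.int(length(pool),
                                         min(n_holds, length(pool)))])
          for (h in rev(at_idx)) {
            px <- append(px, rep(px[h], hold_n - 1L), after = h)
            py <- append(py, rep(py[h], hold_n - 1L), after = h)
            extra <- (seq_len(hold_n - 1L)) * dt_ms
            ts <- c(ts[1:h], ts[h] + extra, ts[(h + 1):length(ts)] +
                      (hold_n - 1L) * dt_ms)
          }
        }

        n <- length(ts)
        ph <- c("down", rep("move", n - 2L), "up")
        t_ms <- c(t_ms, ts)
        x_px <- c(x_px, pmax(0, round(px)))
        y_px <- c(y_px, pmax(0, round(py)))
        phase <- c(phase, ph)
        cursor <- ts[n]
      }
    }

    t_int <- as.integer(round(t_ms))
    # guard strict monotonicity against rounding collisions
    for (i in seq_along(t_int)[-1]) {
      if (t_int[i] <= t_int[i - 1]) t_int[i] <- t_int[i - 1] + 1L
    }

    rows <- ceiling(n_chars / per_row)
    writing_session(
      tibble(t_ms = t_int, x_px = x_px, y_px = y_px, phase = phase),
      subject_id = subject_id,
      screen_w = ceiling(2 * margin + (per_row - 1) * spacing + scale_s),
      screen_h = ceiling(2 * margin + (rows - 1) * spacing + scale_s),
      task_char_count = p$n_chars,
      time_limit = p$time_limit
    )
  })
}

#' Simulate a two-group cohort of writing sessions
#'
#' Draws per-subject child seeds deterministically from the master seed,
#' simulates each subject's session, and samples demographics
#' (age, sex, education with no group effect; MMSE/MoCA around the
#' published group medians). Defaults reproduce the study's group sizes
#' (38 MCI, 34 HC).
#'
#' @param params Two-group parameter list, see [default_sim_params()].
#' @param n_mci,n_hc Group sizes.
#' @param seed Master seed.
#' @param dir Optional directory: one session CSV per subject plus a
#'   `metadata.csv` are written there.
#' @return A list with `sessions` (list of [writing_session()]) and
#'   `metadata` (tibble: subject_id, group, demographics).
#' @examples
#' cohort <- simulate_cohort(n_mci = 3, n_hc = 3, seed = 1)
#' extract_cohort(cohort$sessions, cohort$metadata)
#' @export
simulate_cohort <- function(params = default_sim_params(), n_mci = 38,
                            n_hc = 34, seed = 1, dir = NULL) {
  stopifnot(n_mci >= 1, n_hc >= 1)
  n <- n_mci + n_hc
  groups <- c(rep("MCI", n_mci), rep("HC", n_hc))
  ids <- c(sprintf("MCI_%03d", seq_len(n_mci)),
           sprintf("HC_%03d", seq_len(n_hc)))

  demo <- with_sim_seed(seed, {
    child_seeds <- sample.int(2147483646L, n)
    tibble(
      subject_id = ids,
      group = groups,
      age = round(pmin(pmax(rnorm(n, 62, 7.4), 50), 88)),
      sex = ifelse(runif(n) < 0.6, "female", "male"),
      education = round(pmin(pmax(rnorm(n, 10.5, 3), 2), 22)),
      mmse = round(pmin(pmax(
        rnorm(n, ifelse(groups == "MCI", 25.5, 28), 1.6), 18), 30)),
      moca = round(pmin(pmax(
        rnorm(n, ifelse(groups == "MCI", 20, 26), 2.5), 8), 30)),
      seed = child_seeds
    )
  })

  sessions <- purrr::pmap(
    list(demo$group, demo$subject_id, demo$seed),
    function(g, id, s) simulate_session(params, group = g, seed = s,
                                        subject_id = id)
  )

  metadata <- select(demo, -"seed")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (s in sessions) {
      write_session(s, file.path(dir, paste0(s$subject_id, ".csv")))
    }
    utils::write.csv(metadata, file.path(dir, "metadata.csv"),
                     row.names = FALSE)
  }
  list(sessions = sessions, metadata = metadata)
}

#' Simulate a cohort and extract its feature table in one step
#'
#' @inheritParams simulate_cohort
#' @param min_pause_ms Passed to [extract_cohort()].
#' @return Cohort tibble ready for [compare_groups()] /
#'   [run_screening_pipeline()].
#' @export
simulate_cohort_table <- function(params = default_sim_params(), n_mci = 38,
                                  n_hc = 34, seed = 1, min_pause_ms = 50) {
  cohort <- simulate_cohort(params, n_mci = n_mci, n_hc = n_hc, seed = seed)
  validate_cohort(extract_cohort(cohort$sessions, cohort$metadata,
                                 min_pause_ms = min_pause_ms))
}
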