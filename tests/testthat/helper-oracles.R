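# Independent oracles used across the suite. Each recomputes a quantity
# from first principles by a route different from the package code.

# single-pass event-scan recomputation of all timing/pause/length/speed
# biomarkers straight from the raw event table, never building stroke
# objects: pairs each down with the next up while walking the stream once
oracle_biomarkers <- function(session, min_pause_ms = 50) {
  ev <- session$events
  t <- ev$t_ms / 1000
  n <- nrow(ev)
  durations <- lengths_px <- numeric(0)
  gaps <- numeric(0)
  first_down <- NA_real_
  last_up <- NA_real_
  prev_up <- NA_real_
  pause_count <- 0L
  i <- 1
  while (i <= n) {
    if (ev$phase[i] == "down") {
      j <- i
      while (ev$phase[j] != "up") j <- j + 1
      if (is.na(first_down)) first_down <- t[i]
      if (!is.na(prev_up)) gaps <- c(gaps, t[i] - prev_up)
      xs <- ev$x_px[i:j]; ys <- ev$y_px[i:j]
      durations <- c(durations, t[j] - t[i])
      lengths_px <- c(lengths_px, sum(sqrt(diff(xs)^2 + diff(ys)^2)))
      # stationary runs within this stroke
      k <- i
      while (k < j) {
        if (ev$x_px[k + 1] == ev$x_px[k] && ev$y_px[k + 1] == ev$y_px[k]) {
          m <- k
          while (m < j && ev$x_px[m + 1] == ev$x_px[m] &&
                 ev$y_px[m + 1] == ev$y_px[m]) m <- m + 1
          if (min_pause_ms == 0) {
            pause_count <- pause_count + (m - k)
          } else if ((t[m] - t[k]) * 1000 >= min_pause_ms) {
            pause_count <- pause_count + 1L
          }
          k <- m
        } else {
          k <- k + 1
        }
      }
      prev_up <- t[j]
      last_up <- t[j]
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  J <- length(durations)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  speeds <- ifelse(durations > 0, lengths_px / durations, 0)
  ip1 <- last_up
  ip5 <- first_down
  ip3 <- sum(durations)
  ip6 <- sum(gaps)
  list(
    IPSDB_1 = ip1, IPSDB_2 = ip1 - ip5, IPSDB_3 = ip3,
    IPSDB_4 = ip5 + ip6, IPSDB_5 = ip5, IPSDB_6 = ip6,
    IPSDB_7 = if (J > 1) max(gaps) else NA_real_,
    IPSDB_8 = if (J > 1) ip6 / (J - 1) else NA_real_,
    IPSDB_9 = if (J > 1) pop_sd(gaps) / mean(gaps) else NA_real_,
    IPSDB_10 = pause_count,
    EFDB_2 = J, EFDB_3 = J / ip1 * 60, EFDB_4 = ip3 / ip1,
    EFDB_5 = sum(lengths_px), EFDB_6 = max(lengths_px),
    EFDB_7 = sum(lengths_px) / J,
    EFDB_8 = pop_sd(lengths_px) / mean(lengths_px),
    EFDB_9 = max(speeds), EFDB_10 = mean(speeds),
    EFDB_11 = pop_sd(speeds) / mean(speeds)
  )
}

# brute-force AUC: pairwise concordance with ties counted 1/2
oracle_auc <- function(scores, labels, positive = "MCI") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  s <- 0
  for (p in pos) for (q in neg) {
    s <- s + (p > q) + 0.5 * (p == q)
  }
  s / (length(pos) * length(neg))
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
oracle_mw_exact_p <- function(x, y) {
  all_v <- c(x, y)
  n <- length(all_v)
  m <- length(x)
  r <- rank(all_v)
  w_obs <- sum(r[seq_len(m)])
  combos <- utils::combn(n, m)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- m * (n + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# build a session from explicit stroke descriptions:
# strokes = list of list(t0_ms, pts = matrix(t_off_ms, x, y))
make_session <- function(strokes, subject_id = "toy", ...) {
  rows <- lapply(strokes, function(s) {
    k <- nrow(s$pts)
    stopifnot(k >= 2)
    data.frame(
      t_ms = as.integer(s$t0_ms + s$pts[, 1]),
      x_px = s$pts[, 2], y_px = s$pts[, 3],
      phase = c("down", rep("move", k - 2), "up")
    )
  })
  writing_session(do.call(rbind, rows), subject_id = subject_id, ...)
}

# a minimal two-point stroke from (t0, x0, y0) to (t1, x1, y1), ms
simple_stroke <- function(t0, t1, x0, y0, x1, y1) {
  list(t0_ms = t0, pts = cbind(c(0, t1 - t0), c(x0, x1), c(y0, y1)))
}

# noise-free simulation parameters: every latent pinned to its median,
# no jitter, no holds, no task errors — biomarkers become closed-form
constant_params <- function(gap = 0.5, stroke_time = 0.2, scale = 300,
                            initial_pause = 2) {
  base <- sim_group_params(
    initial_pause_med = initial_pause, initial_pause_sig = 0,
    gap_med = gap, gap_sig = 0, gap_cv_med = 1e-6, gap_cv_sig = 0,
    char_gap_mult = 1, stroke_time_med = stroke_time, stroke_time_sig = 0,
    slow_tail_med = 1e-6, slow_tail_sig = 0,
    scale_med = scale, scale_sig = 0, style_sig = 1e-6, style_sig_sig = 0,
    stroke_len_jitter = 0, pause_rate_med = 1e-9, pause_rate_sig = 0,
    jitter_px = 0, order_error_rate = 0, char_count_error_rate = 0
  )
  list(HC = base, MCI = base)
}
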