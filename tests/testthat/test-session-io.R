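test_that("a minimal legal stream parses into a one-stroke session", {
  ev <- tibble::tibble(
    t_ms = c(0L, 16L, 33L), x_px = c(10, 12, 14), y_px = c(10, 10, 10),
    phase = c("down", "move", "up")
  )
  s <- writing_session(ev)
  expect_true(s$valid)
  seg <- segment_strokes(s)
  expect_equal(nrow(seg$strokes), 1)
  expect_equal(seg$strokes$duration, 0.033)
})

test_that("structural defects are rejected with the offending position", {
  base <- data.frame(t_ms = c(0L, 10L), x_px = 0, y_px = 0,
                     phase = c("down", "up"))
  # move before any down
  expect_error(
    writing_session(data.frame(t_ms = 0L, x_px = 0, y_px = 0,
                               phase = "move")),
    "event 1", class = "graphomarker_phase_error"
  )
  # double down
  expect_error(
    writing_session(data.frame(t_ms = c(0L, 5L, 9L), x_px = 0, y_px = 0,
                               phase = c("down", "down", "up"))),
    "event 2", class = "graphomarker_phase_error"
  )
  # dangling stroke at stream end
  expect_error(
    writing_session(data.frame(t_ms = c(0L, 5L), x_px = 0, y_px = 0,
                               phase = c("down", "move"))),
    "dangling", class = "graphomarker_phase_error"
  )
  # unsorted timestamps name the rows
  expect_error(
    writing_session(data.frame(t_ms = c(10L, 0L), x_px = 0, y_px = 0,
                               phase = c("down", "up"))),
    "not sorted", class = "graphomarker_order_error"
  )
  # tied timestamps = multi-touch
  expect_error(
    writing_session(data.frame(t_ms = c(0L, 0L), x_px = 0, y_px = 0,
                               phase = c("down", "up"))),
    "multi-touch", class = "graphomarker_order_error"
  )
  expect_silent(writing_session(base))
})

test_that("sessions past the task time limit are flagged, not truncated", {
  ev <- data.frame(t_ms = c(0L, 200000L), x_px = 0, y_px = 0,
                   phase = c("down", "up"))
  s <- writing_session(ev)
  expect_false(s$valid)
  expect_match(s$invalid_reason, "exceeds")
  expect_equal(nrow(s$events), 2)  # nothing dropped
})

test_that("sessions round-trip bit-identically through both dialects", {
  s <- simulate_session(group = "HC", seed = 1)
  for (ext in c(".csv", ".json")) {
    f <- tempfile(fileext = ext)
    write_session(s, f)
    r <- read_session(f, subject_id = s$subject_id)
    expect_identical(r$events, s$events)
    # idempotence over repeated round trips (integer times cannot drift)
    write_session(r, f)
    r2 <- read_session(f, subject_id = s$subject_id)
    write_session(r2, f)
    r3 <- read_session(f, subject_id = s$subject_id)
    expect_identical(r3$events, s$events)
    unlink(f)
  }
})

test_that("an empty session writes a header-only file and re-reads empty", {
  s <- writing_session(data.frame(t_ms = integer(0), x_px = numeric(0),
                                  y_px = numeric(0), phase = character(0)))
  f <- tempfile(fileext = ".csv")
  write_session(s, f)
  expect_identical(readLines(f)[1], "t_ms,x_px,y_px,phase")
  r <- read_session(f)
  expect_equal(nrow(r$events), 0)
  unlink(f)
})

test_that("every accepted session satisfies the phase grammar", {
  # independent scanner: explicit finite-state machine over phases
  fsm_ok <- function(phase) {
    state <- "up"
    for (p in phase) {
      if (p == "down" && state != "up") return(FALSE)
      if (p != "down" && state == "up") return(FALSE)
      state <- if (p == "up") "up" else "down"
    }
    state == "up"
  }
  for (seed in 1:10) {
    s <- simulate_session(group = sample(c("HC", "MCI"), 1), seed = seed)
    expect_true(fsm_ok(s$events$phase))
  }
})

test_that("cohort tables validate and round-trip losslessly", {
  cohort <- simulate_cohort_table(n_mci = 4, n_hc = 4, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_cohort(cohort, f)
  r <- read_cohort(f)
  expect_equal(as.data.frame(r), as.data.frame(cohort), tolerance = 1e-12)

  bad <- cohort
  bad$subject_id[2] <- bad$subject_id[1]
  expect_error(validate_cohort(bad), bad$subject_id[1],
               class = "graphomarker_schema_error")

  bad2 <- cohort
  bad2$group <- as.character(bad2$group)
  bad2$group[1] <- "OTHER"
  expect_error(validate_cohort(bad2), "exactly the levels",
               class = "graphomarker_schema_error")

  expect_error(validate_cohort(cohort[setdiff(names(cohort), "group")]),
               "group", class = "graphomarker_schema_error")
  unlink(f)
})

test_that("extract_cohort maps a session directory onto a feature table", {
  dir <- tempfile()
  out <- simulate_cohort(n_mci = 2, n_hc = 2, seed = 5, dir = dir)
  files <- list.files(dir, pattern = "csv$")
  expect_length(files, 5)  # 4 sessions + metadata
  tab <- extract_cohort(dir, metadata = out$metadata)
  expect_equal(nrow(tab), 4)
  expect_true(all(paste0("IPSDB_", 1:10) %in% names(tab)))
  expect_true(all(paste0("EFDB_", 1:11) %in% names(tab)))
  unlink(dir, recursive = TRUE)
})
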