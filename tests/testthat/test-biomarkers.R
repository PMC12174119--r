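# the two-stroke reference session: strokes at [2,3] s and [5,7] s
two_stroke_seg <- function() {
  segment_strokes(make_session(list(
    simple_stroke(2000, 3000, 0, 0, 50, 0),
    simple_stroke(5000, 7000, 0, 10, 80, 10)
  )))
}

test_that("timing biomarkers match their stated arithmetic on a toy session", {
  ip <- compute_ipsdb(two_stroke_seg())
  expect_equal(ip$IPSDB_1, 7)
  expect_equal(ip$IPSDB_2, 5)
  expect_equal(ip$IPSDB_3, 3)
  expect_equal(ip$IPSDB_4, 4)
  expect_equal(ip$IPSDB_5, 2)
  expect_equal(ip$IPSDB_6, 2)
  expect_equal(ip$IPSDB_7, 2)
  expect_equal(ip$IPSDB_8, 2)
  expect_equal(ip$IPSDB_9, 0)  # a single gap has zero variance
})

test_that("equal gaps give zero pause variability", {
  s <- make_session(list(
    simple_stroke(0, 500, 0, 0, 10, 0),
    simple_stroke(1500, 2000, 20, 0, 30, 0),
    simple_stroke(3000, 3500, 40, 0, 50, 0),
    simple_stroke(4500, 5000, 60, 0, 70, 0)
  ))
  ip <- compute_ipsdb(segment_strokes(s))
  expect_equal(ip$IPSDB_9, 0)
})

test_that("stroke-geometry biomarkers follow their definitions", {
  # two strokes: lengths 100 and 300 px, durations 1 s each, total time 10 s
  s <- make_session(list(
    simple_stroke(0, 1000, 0, 0, 100, 0),
    simple_stroke(9000, 10000, 0, 50, 300, 50)
  ))
  seg <- segment_strokes(s)
  ef <- compute_efdb(seg)
  expect_equal(ef$EFDB_2, 2)
  expect_equal(ef$EFDB_3, 12)         # 2 / 10 * 60
  expect_equal(ef$EFDB_5, 400)
  expect_equal(ef$EFDB_6, 300)
  expect_equal(ef$EFDB_7, 200)
  expect_equal(ef$EFDB_9, 300)
  expect_equal(ef$EFDB_10, 200)
  # population SD of speeds {100, 300} is 100
  expect_equal(ef$EFDB_11, 100 / 200)
  expect_equal(ef$EFDB_8, 100 / 200)
})

test_that("identical strokes give zero length and speed variability", {
  s <- make_session(list(
    simple_stroke(0, 1000, 0, 0, 100, 0),
    simple_stroke(2000, 3000, 0, 50, 100, 50),
    simple_stroke(4000, 5000, 0, 100, 100, 100)
  ))
  ef <- compute_efdb(segment_strokes(s))
  expect_equal(ef$EFDB_8, 0)
  expect_equal(ef$EFDB_11, 0)
})

test_that("single-stroke sessions return missing gap statistics, never zero", {
  seg <- segment_strokes(make_session(list(
    simple_stroke(1000, 2000, 0, 0, 10, 0)
  )))
  ip <- compute_ipsdb(seg)
  expect_true(is.na(ip$IPSDB_7))
  expect_true(is.na(ip$IPSDB_8))
  expect_true(is.na(ip$IPSDB_9))
})

test_that("within-stroke pause counting matches both threshold readings", {
  # stroke with one duplicated pair: [(0,5,5),(16,5,5),(33,6,5)]
  s <- writing_session(data.frame(
    t_ms = c(0L, 16L, 33L), x_px = c(5, 5, 6), y_px = c(5, 5, 5),
    phase = c("down", "move", "up")
  ))
  seg <- segment_strokes(s)
  expect_equal(count_within_stroke_pauses(seg, min_pause_ms = 0), 1)
  # the 16 ms run is below a 50 ms threshold
  expect_equal(count_within_stroke_pauses(seg, min_pause_ms = 50), 0)

  # strictly moving stroke counts nothing
  s2 <- make_session(list(simple_stroke(0, 100, 0, 0, 50, 50)))
  expect_equal(count_within_stroke_pauses(segment_strokes(s2), 0), 0)

  # a 3-sample hold (0-32 ms .. run duration 32 ms) vs thresholds;
  # duplicate-pair reading counts 2 pairs
  s3 <- writing_session(data.frame(
    t_ms = c(0L, 16L, 32L, 48L), x_px = c(5, 5, 5, 9), y_px = 5,
    phase = c("down", "move", "move", "up")
  ))
  seg3 <- segment_strokes(s3)
  expect_equal(count_within_stroke_pauses(seg3, 0), 2)
  expect_equal(count_within_stroke_pauses(seg3, 30), 1)
  expect_equal(count_within_stroke_pauses(seg3, 50), 0)
})

test_that("pause counts equal a run-length oracle on sessions with injected holds", {
  for (seed in c(3, 11)) {
    s <- simulate_session(group = "MCI", seed = seed)
    seg <- segment_strokes(s)
    orc <- oracle_biomarkers(s, min_pause_ms = 50)
    expect_equal(count_within_stroke_pauses(seg, 50), orc$IPSDB_10)
  }
})

test_that("every biomarker equals an independent event-scan recomputation", {
  set.seed(42)
  seeds <- sample.int(2^31 - 2, 30)
  groups <- sample(c("HC", "MCI"), 30, replace = TRUE)
  for (i in seq_along(seeds)) {
    s <- simulate_session(group = groups[i], seed = seeds[i])
    seg <- segment_strokes(s)
    got <- dplyr::bind_cols(compute_ipsdb(seg), compute_efdb(seg))
    orc <- oracle_biomarkers(s)
    for (m in names(orc)) {
      expect_equal(got[[m]], orc[[m]], tolerance = 1e-10,
                   info = paste(m, "seed", seeds[i]))
    }
  }
})

test_that("exact timing identities hold to machine precision", {
  set.seed(9)
  for (seed in sample.int(2^31 - 2, 20)) {
    seg <- segment_strokes(
      simulate_session(group = sample(c("HC", "MCI"), 1), seed = seed)
    )
    ip <- compute_ipsdb(seg)
    ef <- compute_efdb(seg)
    expect_equal(ip$IPSDB_1, ip$IPSDB_5 + ip$IPSDB_2, tolerance = 1e-12)
    expect_equal(ip$IPSDB_4, ip$IPSDB_5 + ip$IPSDB_6, tolerance = 1e-12)
    expect_equal(ip$IPSDB_2, ip$IPSDB_3 + ip$IPSDB_6, tolerance = 1e-12)
    expect_equal(ip$IPSDB_1, ip$IPSDB_3 + ip$IPSDB_4, tolerance = 1e-12)
    expect_equal(ef$EFDB_5, ef$EFDB_7 * ef$EFDB_2, tolerance = 1e-12)
    expect_gte(ef$EFDB_6, ef$EFDB_7)
    expect_gte(ef$EFDB_9, ef$EFDB_10)
    expect_gt(ef$EFDB_4, 0)
    expect_lte(ef$EFDB_4, 1)
  }
})

test_that("re-zeroed time shifts and spatial isometries leave biomarkers unchanged", {
  s <- simulate_session(group = "HC", seed = 12)
  base <- dplyr::bind_cols(
    compute_ipsdb(segment_strokes(s)),
    compute_efdb(segment_strokes(s))
  )

  # shift all timestamps by a constant, then re-zero the session clock:
  # identical session, every biomarker unchanged
  shifted <- s
  shifted$events$t_ms <- shifted$events$t_ms + 5000L - 5000L
  expect_identical(shifted$events, s$events)

  # rotation + translation of coordinates: all length/speed biomarkers
  # unchanged (timing features never touch coordinates except IPSDB_10)
  th <- 0.3
  rot <- s
  x <- s$events$x_px; y <- s$events$y_px
  rot$events$x_px <- cos(th) * x - sin(th) * y + 500
  rot$events$y_px <- sin(th) * x + cos(th) * y + 300
  seg_r <- segment_strokes(rot)
  ef_r <- compute_efdb(seg_r)
  ef_b <- compute_efdb(segment_strokes(s))
  for (m in c("EFDB_5", "EFDB_6", "EFDB_7", "EFDB_8", "EFDB_9",
              "EFDB_10", "EFDB_11")) {
    expect_equal(ef_r[[m]], ef_b[[m]], tolerance = 1e-9, info = m)
  }
})

test_that("zero-duration strokes with extent are excluded from speed stats", {
  # a 2-event stroke whose up shares... times must differ, so use a
  # 1 ms stroke flagged via duration 0 after rounding is impossible;
  # instead drive the guard directly with a hand-built segmented session
  seg <- segment_strokes(make_session(list(
    simple_stroke(0, 1000, 0, 0, 100, 0),
    simple_stroke(2000, 3000, 0, 50, 300, 50)
  )))
  seg$strokes$duration[2] <- 0
  seg$strokes$speed[2] <- 0
  expect_warning(ef <- compute_efdb(seg), "zero-duration")
  expect_equal(ef$EFDB_10, 100)  # only the first stroke's speed remains
})
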