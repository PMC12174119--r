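test_that("sessions are byte-identical given the same parameters and seed", {
  a <- simulate_session(group = "MCI", seed = 123)
  b <- simulate_session(group = "MCI", seed = 123)
  expect_identical(a$events, b$events)
  c <- simulate_session(group = "MCI", seed = 124)
  expect_false(identical(a$events, c$events))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(55)
  before <- rnorm(1)
  set.seed(55)
  invisible(simulate_session(group = "HC", seed = 9))
  after <- rnorm(1)
  expect_identical(before, after)
})

test_that("noise-free parameters make biomarkers closed-form predictable", {
  par <- constant_params(gap = 0.5, stroke_time = 0.2, scale = 300,
                         initial_pause = 2)
  s <- simulate_session(par, "HC", seed = 1)
  seg <- segment_strokes(s)
  ip <- compute_ipsdb(seg)
  ef <- compute_efdb(seg)
  J <- 60
  # every gap equals the constant, so the totals follow exactly
  # (timestamps are quantised to the 60 Hz sampling grid, hence the
  # millisecond-scale tolerance)
  expect_equal(nrow(seg$strokes), J)
  expect_equal(ip$IPSDB_5, 2, tolerance = 1e-3)
  expect_equal(ip$IPSDB_6, (J - 1) * 0.5, tolerance = 0.05)
  expect_equal(ip$IPSDB_8, 0.5, tolerance = 1e-2)
  expect_equal(ip$IPSDB_7, max(seg$gaps), tolerance = 1e-12)
  expect_lte(ip$IPSDB_9, 0.04)
  expect_equal(ip$IPSDB_10, 0)
  # all strokes share one duration; speed variability reduces to the
  # template's length variability
  expect_lte(abs(ef$EFDB_8 - ef$EFDB_11), 0.06)
  tmpl_cv <- {
    lens <- graphomarker:::glyph_stroke_lengths()
    sqrt(mean((lens - mean(lens))^2)) / mean(lens)
  }
  expect_equal(ef$EFDB_8, tmpl_cv, tolerance = 0.05)
  expect_equal(ef$EFDB_2, 60)
})

test_that("cohorts have the requested sizes, unique subjects and demographics", {
  out <- simulate_cohort(n_mci = 5, n_hc = 4, seed = 1)
  expect_length(out$sessions, 9)
  expect_equal(sum(out$metadata$group == "MCI"), 5)
  expect_equal(sum(out$metadata$group == "HC"), 4)
  expect_false(any(duplicated(out$metadata$subject_id)))
  expect_true(all(c("age", "sex", "education", "mmse", "moca") %in%
                    names(out$metadata)))
  # distinct master seeds give distinct sessions
  out2 <- simulate_cohort(n_mci = 5, n_hc = 4, seed = 2)
  expect_false(identical(out$sessions[[1]]$events,
                         out2$sessions[[1]]$events))
})

test_that("parameters implying over-limit sessions get flagged downstream", {
  par <- constant_params(gap = 4, stroke_time = 0.2, initial_pause = 30)
  s <- simulate_session(par, "HC", seed = 2)
  expect_false(s$valid)
  expect_message(
    tab <- extract_cohort(list(s, simulate_session(group = "HC", seed = 3))),
    "invalid"
  )
  expect_equal(nrow(tab), 1)
})

test_that("calibration is a fixed point when targets are already met", {
  par <- default_sim_params()
  targets <- tibble::tibble(
    marker = "IPSDB_8", group = c("HC", "MCI"),
    target = c(0.22, 0.34), tolerance = 0.15
  )
  res <- calibrate_sim_params(par, targets, n_probe = 60, seed = 5,
                              max_iter = 3)
  expect_true(res$converged)
  # untouched within one damped step
  expect_equal(res$params$HC$gap_med, par$HC$gap_med, tolerance = 0.1)
  expect_equal(res$params$MCI$gap_med, par$MCI$gap_med, tolerance = 0.1)
})

test_that("infeasible or unmapped calibration targets are rejected", {
  bad <- tibble::tibble(marker = "IPSDB_8", group = "HC",
                        target = -1, tolerance = 0.1)
  expect_error(calibrate_sim_params(targets = bad), "positive",
               class = "graphomarker_calibration_error")
  unmapped <- tibble::tibble(marker = "IPSDB_1", group = "HC",
                             target = 47, tolerance = 0.1)
  expect_error(calibrate_sim_params(targets = unmapped), "IPSDB_1",
               class = "graphomarker_calibration_error")
})

test_that("reference summaries expose both column conventions", {
  txt <- reference_group_summaries()
  printed <- reference_group_summaries(columns_as_printed = TRUE)
  i_mci <- txt$marker == "IPSDB_1" & txt$group == "MCI"
  i_hc <- txt$marker == "IPSDB_1" & txt$group == "HC"
  # text direction: MCI total task time higher; printed order reversed
  expect_gt(txt$center[i_mci], txt$center[i_hc])
  expect_lt(printed$center[i_mci], printed$center[i_hc])
  # all other rows agree between the two conventions
  expect_equal(txt$center[txt$marker != "IPSDB_1"],
               printed$center[printed$marker != "IPSDB_1"])
  expect_equal(nrow(txt), 42)
})

test_that("calibrated pause markers stochastically separate the groups", {
  set.seed(77)
  seeds <- sample.int(2^31 - 2, 60)
  feats <- lapply(c("HC", "MCI"), function(g) {
    purrr::map_dfr(seeds, function(s) {
      seg <- segment_strokes(simulate_session(group = g, seed = s))
      compute_ipsdb(seg)
    })
  })
  for (m in c("IPSDB_4", "IPSDB_5", "IPSDB_6", "IPSDB_7", "IPSDB_8",
              "IPSDB_9")) {
    p <- wilcox.test(feats[[2]][[m]], feats[[1]][[m]],
                     alternative = "greater", exact = FALSE)$p.value
    expect_lt(p, 0.05)
  }
})
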