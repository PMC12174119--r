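mini_cohort <- function(x, y, marker = "IPSDB_5") {
  tibble::tibble(
    subject_id = paste0("s", seq_len(length(x) + length(y))),
    group = c(rep("MCI", length(x)), rep("HC", length(y))),
    !!marker := c(x, y)
  )
}

test_that("the Mann-Whitney routine reproduces exact small-sample results", {
  # x = [1,2], y = [3,4]: U = 0, exact two-sided p = 1/3
  mw <- graphomarker:::mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p.value, 1 / 3)
  # identical groups are indistinguishable
  mw2 <- graphomarker:::mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_gte(mw2$p.value, 0.99)
})

test_that("Mann-Whitney p equals exhaustive permutation for groups <= 7", {
  set.seed(11)
  for (rep in 1:12) {
    repeat {
      n1 <- sample(3:7, 1); n2 <- sample(3:7, 1)
      x <- round(rnorm(n1, 0, 2), 2)
      y <- round(rnorm(n2, 0.8, 2), 2)
      if (!anyDuplicated(c(x, y))) break  # exact route needs untied data
    }
    mw <- graphomarker:::mann_whitney(x, y)
    expect_equal(mw$p.value, oracle_mw_exact_p(x, y), tolerance = 1e-9,
                 info = paste("rep", rep))
  }
})

test_that("normality routing chooses the test and the descriptive style", {
  set.seed(3)
  gauss <- mini_cohort(rnorm(25, 10, 2), rnorm(25, 12, 2))
  skew <- mini_cohort(rlnorm(25, 0, 1.2), rlnorm(25, 0.8, 1.2))
  r1 <- compare_groups(gauss, markers = "IPSDB_5")
  r2 <- compare_groups(skew, markers = "IPSDB_5")
  expect_equal(r1$test, "t_independent")
  expect_match(r1$desc_mci, "±")
  expect_equal(r2$test, "mann_whitney")
  expect_match(r2$desc_mci, "\\(")
})

test_that("the demographics chi-square matches the published sex comparison", {
  # 22/16 female/male in MCI, 21/13 in HC -> p = 0.738
  cohort <- tibble::tibble(
    subject_id = paste0("s", 1:72),
    group = c(rep("MCI", 38), rep("HC", 34)),
    sex = c(rep("female", 22), rep("male", 16),
            rep("female", 21), rep("male", 13))
  )
  r <- compare_groups(cohort, markers = "sex")
  expect_equal(r$test, "chi_square")
  # independent 2x2 Pearson formula oracle
  o <- c(22, 16, 21, 13)
  n <- sum(o)
  e <- outer(c(38, 34), c(43, 29)) / n
  x2 <- sum((matrix(o, 2, byrow = TRUE) - e)^2 / e)
  expect_equal(r$statistic, x2, tolerance = 1e-9)
  expect_equal(r$p_value, pchisq(x2, 1, lower.tail = FALSE))
  expect_equal(round(r$p_value, 3), 0.738)
})

test_that("markers with too few observations are skipped with a warning", {
  cohort <- mini_cohort(c(1, 2), c(3, 4, 5, 6))
  expect_warning(
    expect_error(compare_groups(cohort, markers = "IPSDB_5"),
                 "no marker"),
    "skipped"
  )
})

test_that("missing values are excluded per marker", {
  set.seed(4)
  cohort <- mini_cohort(c(rnorm(10, 5), NA, NA), rnorm(10, 5))
  r <- compare_groups(cohort, markers = "IPSDB_5")
  expect_equal(nrow(r), 1)
  expect_true(is.finite(r$p_value))
})

test_that("a BH column is reported but never drives the significance flag", {
  set.seed(8)
  cohort <- tibble::tibble(
    subject_id = paste0("s", 1:40),
    group = rep(c("MCI", "HC"), each = 20),
    IPSDB_5 = c(rlnorm(20, 1, 0.4), rlnorm(20, 0.2, 0.4)),
    IPSDB_6 = rlnorm(40, 1, 0.5),
    IPSDB_7 = rlnorm(40, 1, 0.5)
  )
  r <- compare_groups(cohort)
  expect_true(all(r$p_bh >= r$p_value - 1e-12))
  expect_equal(r$significant, r$p_value < 0.05)
})
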