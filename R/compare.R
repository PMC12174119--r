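#' Two-group differential battery with normality routing
#'
#' Compares each marker between the MCI and HC groups, routing each
#' numeric marker to the test the cohort's distribution supports:
#' if both groups pass a Shapiro-Wilk normality test at
#' `normality_alpha`, an independent-samples t-test is used and the
#' groups are described as mean ± SD; otherwise a Mann-Whitney U test is
#' used and the groups are described as median (IQR). Categorical markers
#' (e.g. sex) always use a Pearson chi-square test without continuity
#' correction. Missing values are excluded per marker; a marker with
#' fewer than 3 non-missing values in either group is skipped with a
#' warning.
#'
#' The Mann-Whitney p-value is exact (enumeration) when both groups have
#' at most 7 untied observations, and otherwise uses the normal
#' approximation with tie and continuity corrections.
#'
#' A Benjamini-Hochberg adjusted column (`p_bh`) is reported for
#' information only; the screening pipeline selects on the raw p-values,
#' as the original analysis did.
#'
#' @param cohort Cohort tibble with a `group` column (levels `MCI`, `HC`).
#' @param markers Character vector of column names to compare; defaults
#'   to all 21 biomarker columns present.
#' @param normality_alpha Shapiro-Wilk routing threshold (default 0.05).
#' @param alpha Significance threshold for the `significant` flag
#'   (default 0.05).
#' @return Tibble with one row per marker: `marker`, `test`
#'   (`t_independent` / `mann_whitney` / `chi_square`), formatted
#'   `desc_mci` / `desc_hc`, numeric `center_mci` / `center_hc`,
#'   `statistic`, `p_value`, `p_bh`, `significant`.
#' @examples
#' cohort <- simulate_cohort_table(n_mci = 10, n_hc = 10, seed = 1)
#' compare_groups(cohort, markers = c("IPSDB_5", "IPSDB_8"))
#' @export
compare_groups <- function(cohort, markers = NULL, normality_alpha = 0.05,
                           alpha = 0.05) {
  cohort <- validate_cohort(cohort)
  markers <- markers %||% intersect(BIOMARKER_NAMES, names(cohort))
  missing_mk <- setdiff(markers, names(cohort))
  if (length(missing_mk) > 0) {
    abort(paste0("marker(s) not in cohort table: ",
                 paste(missing_mk, collapse = ", ")))
  }
  is_mci <- cohort$group == "MCI"
  if (!any(is_mci) || !any(!is_mci)) {
    abort("both groups must be non-empty",
          class = "graphomarker_stats_error")
  }

  rows <- purrr::map(markers, function(m) {
    v <- cohort[[m]]
    if (!is.numeric(v)) {
      return(compare_categorical(m, v, is_mci))
    }
    x <- v[is_mci & !is.na(v)]
    y <- v[!is_mci & !is.na(v)]
    if (length(x) < 3 || length(y) < 3) {
      warn(sprintf("marker %s skipped: fewer than 3 non-missing values in a group", m))
      return(NULL)
    }
    normal <- group_normal(x, normality_alpha) &&
      group_normal(y, normality_alpha)
    if (normal) {
      ht <- t.test(x, y, var.equal = TRUE)
      tibble(
        marker = m, test = "t_independent",
        desc_mci = sprintf("%.2f ± %.2f", mean(x), sd(x)),
        desc_hc = sprintf("%.2f ± %.2f", mean(y), sd(y)),
        center_mci = mean(x), center_hc = mean(y),
        statistic = unname(ht$statistic), p_value = ht$p.value
      )
    } else {
      ht <- mann_whitney(x, y)
      tibble(
        marker = m, test = "mann_whitney",
        desc_mci = sprintf("%.2f (%.2f)", median(x), IQR(x)),
        desc_hc = sprintf("%.2f (%.2f)", median(y), IQR(y)),
        center_mci = median(x), center_hc = median(y),
        statistic = ht$statistic, p_value = ht$p.value
      )
    }
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) {
    abort("no marker could be compared", class = "graphomarker_stats_error")
  }
  out %>%
    mutate(
      p_bh = stats::p.adjust(.data$p_value, method = "BH"),
      significant = .data$p_value < alpha
    )
}

# Shapiro-Wilk, treating degenerate (constant) samples as non-normal
group_normal <- function(x, alpha) {
  if (length(unique(x)) < 3 || length(x) < 3) return(FALSE)
  p <- tryCatch(shapiro.test(x)$p.value, error = function(e) 0)
  p > alpha
}

# Mann-Whitney U: exact enumeration for small untied samples, otherwise
# normal approximation with tie and continuity corrections (the behaviour
# of stats::wilcox.test, steered to the documented routing rule)
mann_whitney <- function(x, y) {
  small <- max(length(x), length(y)) <= 7
  has_ties <- anyDuplicated(c(x, y)) > 0
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = small && !has_ties,
                correct = TRUE, alternative = "two.sided")
  )
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

compare_categorical <- function(m, v, is_mci) {
  tab <- table(factor(ifelse(is_mci, "MCI", "HC"), levels = c("MCI", "HC")),
               v)
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  fmt <- function(r) paste(r, collapse = "/")
  tibble(
    marker = m, test = "chi_square",
    desc_mci = fmt(tab["MCI", ]), desc_hc = fmt(tab["HC", ]),
    center_mci = NA_real_, center_hc = NA_real_,
    statistic = unname(ht$statistic), p_value = ht$p.value
  )
}
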