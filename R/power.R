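#' A priori sample size for a two-sample t-test
#'
#' Computes the smallest group sizes whose two-sample t-test reaches the
#' requested power at effect size `d` (Cohen's d), via the noncentral-t
#' distribution of the test statistic: with `n1`, `n2` per group the
#' statistic has `n1 + n2 - 2` degrees of freedom and noncentrality
#' `d * sqrt(n1 * n2 / (n1 + n2))`. The search increases `n1` (with
#' `n2 = ceiling(ratio * n1)`) until the power constraint is met.
#'
#' At the conventional screening design (d = 0.7, alpha = 0.05,
#' power = 0.8, ratio 1, two-tailed) this yields 34 per group,
#' 68 in total.
#'
#' @param d Effect size (Cohen's d), must be positive.
#' @param alpha Type-I error probability.
#' @param power Target power.
#' @param ratio Allocation ratio `n2 / n1`.
#' @param tails 1 or 2.
#' @return One-row tibble: `n_group1`, `n_group2`, `n_total`,
#'   `achieved_power`, plus the input design.
#' @examples
#' sample_size_ttest(d = 0.7)
#' @export
sample_size_ttest <- function(d, alpha = 0.05, power = 0.8, ratio = 1,
                              tails = 2) {
  if (!is.finite(d) || d <= 0) {
    abort("effect size d must be positive",
          class = "graphomarker_stats_error")
  }
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1, ratio > 0,
            tails %in% c(1, 2))
  n1 <- 2L
  repeat {
    n2 <- as.integer(ceiling(ratio * n1))
    pw <- ttest_power(n1, n2, d, alpha, tails)
    if (pw >= power) break
    n1 <- n1 + 1L
    if (n1 > 1e6) {
      abort("sample-size search did not terminate",
            class = "graphomarker_stats_error")
    }
  }
  tibble(
    n_group1 = n1, n_group2 = n2, n_total = n1 + n2,
    achieved_power = pw, d = d, alpha = alpha, power_target = power,
    ratio = ratio, tails = tails
  )
}

# power of the two-sample t-test under the noncentral-t alternative
ttest_power <- function(n1, n2, d, alpha = 0.05, tails = 2) {
  df <- n1 + n2 - 2
  if (df < 1) return(0)
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  if (tails == 2) {
    tc <- qt(1 - alpha / 2, df)
    pt(tc, df, ncp = ncp, lower.tail = FALSE) + pt(-tc, df, ncp = ncp)
  } else {
    tc <- qt(1 - alpha, df)
    pt(tc, df, ncp = ncp, lower.tail = FALSE)
  }
}
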