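#' ROC curve and AUC with DeLong confidence interval
#'
#' Builds the ROC curve of a risk score against the two-level group
#' label, with MCI as the positive class. The AUC equals the pairwise
#' concordance probability (ties counted 1/2); its 95% confidence
#' interval uses the DeLong variance estimator by default, with a
#' stratified bootstrap available as an alternative. Curve construction
#' and interval estimation are delegated to \pkg{pROC}.
#'
#' @param scores Numeric per-subject risk scores.
#' @param labels Group labels (`MCI` / `HC`), or any two-level factor
#'   whose positive level is given by `positive`.
#' @param positive Positive-class label (default `"MCI"`).
#' @param direction `"higher"` — higher scores indicate the positive
#'   class; `"lower"` — the reverse; `"auto"` — orient so AUC >= 0.5
#'   (recorded in the result).
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param conf_level Confidence level (default 0.95).
#' @param boot_n Bootstrap replicates when `ci_method = "bootstrap"`.
#' @return An object of class `roc_result`: `auc`, `ci_lo`, `ci_hi`,
#'   `curve` (tibble `threshold`, `fpr`, `tpr`), `direction` (resolved),
#'   `n_pos`, `n_neg`, `positive`, `ci_method`.
#' @examples
#' roc_auc(c(0.1, 0.2, 0.8, 0.9), c("HC", "HC", "MCI", "MCI"))$auc  # 1
#' @export
roc_auc <- function(scores, labels, positive = "MCI",
                    direction = c("higher", "lower", "auto"),
                    ci_method = c("delong", "bootstrap"),
                    conf_level = 0.95, boot_n = 500) {
  direction <- match.arg(direction)
  ci_method <- match.arg(ci_method)
  labels <- as.character(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  lev <- unique(labels)
  if (length(lev) != 2 || !positive %in% lev) {
    abort(paste0("labels must contain exactly two classes including '",
                 positive, "'"),
          class = "graphomarker_stats_error")
  }
  negative <- setdiff(lev, positive)

  # pROC direction "<": controls (negative) are lower than cases
  proc_dir <- switch(direction, higher = "<", lower = ">", auto = "auto")
  r <- pROC::roc(
    response = labels, predictor = scores,
    levels = c(negative, positive), direction = proc_dir,
    quiet = TRUE
  )
  ci <- if (ci_method == "delong") {
    pROC::ci.auc(r, method = "delong", conf.level = conf_level)
  } else {
    pROC::ci.auc(r, method = "bootstrap", conf.level = conf_level,
                 boot.n = boot_n, progress = "none")
  }

  curve <- tibble(
    threshold = r$thresholds,
    fpr = 1 - r$specificities,
    tpr = r$sensitivities
  ) %>%
    arrange(.data$fpr, .data$tpr)

  structure(
    list(
      auc = as.numeric(pROC::auc(r)),
      ci_lo = as.numeric(ci[1]), ci_hi = as.numeric(ci[3]),
      conf_level = conf_level,
      curve = curve,
      direction = if (r$direction == "<") "higher" else "lower",
      n_pos = sum(labels == positive), n_neg = sum(labels == negative),
      positive = positive, ci_method = ci_method
    ),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC = %.3f (%d%% CI %.3f-%.3f, %s), positive = %s (%s scores), n = %d/%d\n",
    x$auc, round(x$conf_level * 100), x$ci_lo, x$ci_hi, x$ci_method,
    x$positive, x$direction, x$n_pos, x$n_neg
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.roc_result <- function(x, ...) {
  x$curve
}

#' @exportS3Method generics::glance
glance.roc_result <- function(x, ...) {
  tibble(
    auc = x$auc, ci_lo = x$ci_lo, ci_hi = x$ci_hi,
    conf_level = x$conf_level, ci_method = x$ci_method,
    direction = x$direction, n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.roc_result <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_step(linewidth = 0.8) +
    coord_equal() +
    labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("ROC: AUC = %.3f (%.3f-%.3f)",
                      object$auc, object$ci_lo, object$ci_hi)
    ) +
    theme_minimal()
}
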