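#' Screening-pipeline configuration
#'
#' Bundles every tunable threshold of the cohort pipeline in one place.
#' Defaults follow the published analysis where it states a value
#' (significance at p < 0.05) and the documented package conventions
#' elsewhere.
#'
#' @param alpha Significance threshold for the differential battery.
#' @param normality_alpha Shapiro-Wilk routing threshold.
#' @param p_enter,p_remove Stepwise entry/removal LR p-value thresholds.
#' @param ci_method ROC interval method, `"delong"` or `"bootstrap"`.
#' @param min_pause_ms Within-stroke pause threshold for extraction.
#' @return A named list of class `screening_config`.
#' @export
screening_config <- function(alpha = 0.05, normality_alpha = 0.05,
                             p_enter = 0.05, p_remove = 0.10,
                             ci_method = "delong", min_pause_ms = 50) {
  structure(
    list(alpha = alpha, normality_alpha = normality_alpha,
         p_enter = p_enter, p_remove = p_remove, ci_method = ci_method,
         min_pause_ms = min_pause_ms),
    class = "screening_config"
  )
}

#' Run the full cohort screening pipeline
#'
#' Reproduces the cohort analysis end to end on a feature table:
#'
#' 1. demographics comparison (age, sex, education, MMSE, MoCA where
#'    present), chi-square for categorical and normality-routed
#'    t-test / Mann-Whitney for numeric columns;
#' 2. the 21-marker differential battery ([compare_groups()]);
#' 3. the significant-marker list at `alpha`;
#' 4. stepwise logistic selection among the significant markers
#'    ([stepwise_logistic()]);
#' 5. per-marker ROC curves for each selected marker (auto-oriented so
#'    AUC >= 0.5, orientation recorded) and the joint-model ROC on the
#'    fitted probabilities ([roc_auc()]).
#'
#' @param cohort Cohort tibble (see [read_cohort()] /
#'   [simulate_cohort_table()]).
#' @param config A [screening_config()].
#' @return An object of class `screening_report`: `demographics`,
#'   `battery`, `significant` (character vector), `model`
#'   ([stepwise_logistic()] result or NULL), `roc_markers` (named list of
#'   `roc_result`), `roc_joint` (`roc_result` or NULL), `config`, `log`
#'   (character vector of stage messages).
#' @examples
#' \donttest{
#' cohort <- simulate_cohort_table(n_mci = 12, n_hc = 12, seed = 3)
#' report <- run_screening_pipeline(cohort)
#' report$significant
#' }
#' @export
run_screening_pipeline <- function(cohort, config = screening_config()) {
  stopifnot(inherits(config, "screening_config"))
  log <- character(0)
  note <- function(...) {
    log <<- c(log, sprintf(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "graphomarker_pipeline_error")
    })
  }

  cohort <- stage("validate", validate_cohort(cohort))
  n_tab <- table(cohort$group)
  if (nrow(cohort) < 4 || any(n_tab < 2)) {
    abort(sprintf(
      "pipeline stage 'validate' failed: need at least 2 subjects per group, got MCI = %d, HC = %d",
      sum(cohort$group == "MCI"), sum(cohort$group == "HC")
    ), class = "graphomarker_pipeline_error")
  }
  note("cohort: %d MCI, %d HC", n_tab[["MCI"]], n_tab[["HC"]])

  demog_cols <- intersect(DEMOG_NAMES, names(cohort))
  demographics <- if (length(demog_cols)) {
    stage("compare_groups", compare_groups(
      cohort, markers = demog_cols,
      normality_alpha = config$normality_alpha, alpha = config$alpha
    ))
  } else {
    NULL
  }

  markers <- intersect(BIOMARKER_NAMES, names(cohort))
  if (length(markers) == 0) {
    abort("pipeline stage 'compare_groups' failed: no biomarker columns present",
          class = "graphomarker_pipeline_error")
  }
  battery <- stage("compare_groups", compare_groups(
    cohort, markers = markers,
    normality_alpha = config$normality_alpha, alpha = config$alpha
  ))
  significant <- battery$marker[battery$significant]
  note("differential battery: %d of %d markers significant at p < %g",
       length(significant), nrow(battery), config$alpha)

  model <- stage("stepwise_logistic", stepwise_logistic(
    cohort, candidates = significant,
    p_enter = config$p_enter, p_remove = config$p_remove
  ))
  note("stepwise selection retained %d marker(s): %s",
       length(model$selected),
       if (length(model$selected)) paste(model$selected, collapse = ", ")
       else "(none)")

  roc_markers <- list()
  roc_joint <- NULL
  if (length(model$selected) > 0) {
    roc_markers <- stage("roc_auc", setNames(lapply(
      model$selected,
      function(m) roc_auc(cohort[[m]], cohort$group, direction = "auto",
                          ci_method = config$ci_method)
    ), model$selected))
    keep <- cohort$subject_id %in% model$probabilities$subject_id
    roc_joint <- stage("roc_auc", roc_auc(
      model$probabilities$prob,
      cohort$group[match(model$probabilities$subject_id,
                         cohort$subject_id)],
      direction = "higher", ci_method = config$ci_method
    ))
    note("joint-model AUC = %.3f (%.3f-%.3f)",
         roc_joint$auc, roc_joint$ci_lo, roc_joint$ci_hi)
  } else {
    note("no markers selected; ROC stage skipped")
  }

  structure(
    list(
      demographics = demographics, battery = battery,
      significant = significant, model = model,
      roc_markers = roc_markers, roc_joint = roc_joint,
      config = config, log = log
    ),
    class = "screening_report"
  )
}

#' @export
print.screening_report <- function(x, ...) {
  cat("<screening_report>\n")
  for (line in x$log) cat(" -", line, "\n")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.screening_report <- function(x, ...) {
  tibble(
    n = nrow(x$battery %||% tibble()),
    n_significant = length(x$significant),
    n_selected = length(x$model$selected),
    auc_joint = if (is.null(x$roc_joint)) NA_real_ else x$roc_joint$auc,
    auc_ci_lo = if (is.null(x$roc_joint)) NA_real_ else x$roc_joint$ci_lo,
    auc_ci_hi = if (is.null(x$roc_joint)) NA_real_ else x$roc_joint$ci_hi
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.screening_report <- function(object, ...) {
  curves <- list()
  if (!is.null(object$roc_joint)) {
    curves[["joint model"]] <- object$roc_joint$curve
  }
  for (m in names(object$roc_markers)) {
    curves[[m]] <- object$roc_markers[[m]]$curve
  }
  if (length(curves) == 0) {
    abort("report has no ROC curves to plot")
  }
  df <- dplyr::bind_rows(curves, .id = "score")
  ggplot(df, aes(x = .data$fpr, y = .data$tpr, colour = .data$score)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_step(linewidth = 0.7) +
    coord_equal() +
    labs(x = "False positive rate", y = "True positive rate",
         colour = NULL, title = "Screening ROC curves") +
    theme_minimal()
}

#' Plot the pen trajectory of a session
#'
#' Draws each stroke's polyline on the screen plane (y axis flipped so
#' the rendering matches what the subject wrote).
#'
#' @param session A [writing_session()].
#' @return A ggplot object.
#' @export
plot_session <- function(session) {
  seg <- segment_strokes(session)
  df <- purrr::imap_dfr(seg$strokes$points, function(p, j) {
    mutate(p, stroke = j)
  })
  ggplot(df, aes(x = .data$x, y = -.data$y, group = .data$stroke)) +
    geom_path(linewidth = 0.5) +
    coord_equal() +
    labs(x = "x (px)", y = "y (px, flipped)",
         title = sprintf("Session %s", session$subject_id)) +
    theme_minimal()
}
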