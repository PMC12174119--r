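#' Stepwise binary logistic biomarker selection
#'
#' Screens candidate biomarkers into a binary logistic model for group
#' membership (MCI = 1) by bidirectional stepwise selection on
#' likelihood-ratio p-values: at each step the candidate whose addition
#' has the smallest LR p-value enters if that p-value is below `p_enter`,
#' then every included term whose removal LR p-value exceeds `p_remove`
#' is dropped. Selection runs on internally standardised candidates
#' (making it invariant to affine rescaling of the columns); the reported
#' model is refit on the original scale. The procedure is deterministic
#' given the table.
#'
#' If the final fit shows signs of complete separation (non-convergence
#' or diverging coefficients), a ridge-stabilised logistic fit (small L2
#' penalty via iteratively reweighted least squares) replaces it and the
#' result is flagged.
#'
#' @param cohort Cohort tibble with a `group` column.
#' @param candidates Character vector of candidate column names.
#' @param p_enter LR p-value below which a candidate enters (default 0.05).
#' @param p_remove LR p-value above which an included term leaves
#'   (default 0.10).
#' @param max_steps Safety cap on selection steps.
#' @return An object of class `stepwise_logit`: `selected` (character),
#'   `model` (the final `glm`, or ridge coefficients when flagged),
#'   `coefficients` (named vector, original scale), `probabilities`
#'   (tibble `subject_id`, `prob`), `steps` (log tibble),
#'   `separation` (logical flag).
#' @examples
#' cohort <- simulate_cohort_table(n_mci = 15, n_hc = 15, seed = 2)
#' fit <- stepwise_logistic(cohort, c("IPSDB_8", "EFDB_11"))
#' tidy(fit)
#' @export
stepwise_logistic <- function(cohort, candidates, p_enter = 0.05,
                              p_remove = 0.10, max_steps = 50) {
  cohort <- validate_cohort(cohort)
  stopifnot(p_enter > 0, p_enter < 1, p_remove >= p_enter, p_remove < 1)
  missing_c <- setdiff(candidates, names(cohort))
  if (length(missing_c) > 0) {
    abort(paste0("candidate(s) not in cohort table: ",
                 paste(missing_c, collapse = ", ")))
  }
  y <- as.integer(cohort$group == "MCI")

  if (length(candidates) == 0) {
    fit <- glm(y ~ 1, family = binomial())
    return(new_stepwise_logit(
      selected = character(0), model = fit,
      coefficients = coef(fit),
      probabilities = tibble(subject_id = cohort$subject_id,
                             prob = unname(fitted(fit))),
      steps = tibble(step = integer(0), action = character(0),
                     term = character(0), p = numeric(0)),
      separation = FALSE
    ))
  }

  keep <- complete.cases(cohort[candidates])
  yk <- y[keep]
  X <- as.data.frame(lapply(cohort[keep, candidates], function(v) {
    s <- sd(v)
    if (is.na(s) || s == 0) v - mean(v) else (v - mean(v)) / s
  }))
  names(X) <- candidates

  lr_p <- function(fit0, fit1, df = 1) {
    stat <- 2 * (as.numeric(logLik(fit1)) - as.numeric(logLik(fit0)))
    pchisq(max(stat, 0), df = df, lower.tail = FALSE)
  }
  fit_set <- function(terms) {
    if (length(terms) == 0) {
      glm(yk ~ 1, family = binomial())
    } else {
      suppressWarnings(
        glm(yk ~ ., data = X[terms], family = binomial())
      )
    }
  }

  selected <- character(0)
  steps <- list()
  current <- fit_set(selected)
  for (step_i in seq_len(max_steps)) {
    changed <- FALSE
    # forward: best addition by LR p
    pool <- setdiff(candidates, selected)
    if (length(pool) > 0) {
      p_add <- vapply(pool, function(tm) {
        lr_p(current, fit_set(c(selected, tm)))
      }, numeric(1))
      best <- which.min(p_add)
      if (p_add[best] < p_enter) {
        selected <- c(selected, pool[best])
        current <- fit_set(selected)
        steps[[length(steps) + 1]] <- tibble(
          step = step_i, action = "add", term = pool[best],
          p = unname(p_add[best])
        )
        changed <- TRUE
      }
    }
    # backward: drop any term whose removal p exceeds p_remove
    repeat {
      if (length(selected) == 0) break
      p_drop <- vapply(selected, function(tm) {
        lr_p(fit_set(setdiff(selected, tm)), current)
      }, numeric(1))
      worst <- which.max(p_drop)
      if (p_drop[worst] > p_remove) {
        steps[[length(steps) + 1]] <- tibble(
          step = step_i, action = "remove", term = selected[worst],
          p = unname(p_drop[worst])
        )
        selected <- selected[-worst]
        current <- fit_set(selected)
        changed <- TRUE
      } else {
        break
      }
    }
    if (!changed) break
  }

  # final refit on the original scale
  dat <- data.frame(.y = yk, cohort[keep, selected, drop = FALSE])
  final <- suppressWarnings(
    glm(.y ~ ., data = dat, family = binomial())
  )
  separation <- !final$converged ||
    (length(selected) > 0 && any(abs(coef(fit_set(selected))[-1]) > 15))
  if (separation) {
    co <- ridge_logit(cbind(1, as.matrix(cohort[keep, selected,
                                                drop = FALSE])), yk)
    names(co) <- c("(Intercept)", selected)
    probs <- as.numeric(
      plogis(cbind(1, as.matrix(cohort[keep, selected, drop = FALSE])) %*%
               co)
    )
    warn("possible complete separation: ridge-stabilised fit reported")
    coefficients <- co
  } else {
    coefficients <- coef(final)
    probs <- unname(fitted(final))
  }

  new_stepwise_logit(
    selected = selected, model = final, coefficients = coefficients,
    probabilities = tibble(subject_id = cohort$subject_id[keep],
                           prob = probs),
    steps = if (length(steps)) dplyr::bind_rows(steps) else
      tibble(step = integer(0), action = character(0),
             term = character(0), p = numeric(0)),
    separation = separation
  )
}

new_stepwise_logit <- function(selected, model, coefficients,
                               probabilities, steps, separation) {
  structure(
    list(selected = selected, model = model, coefficients = coefficients,
         probabilities = probabilities, steps = steps,
         separation = separation),
    class = "stepwise_logit"
  )
}

# logistic regression with a small L2 penalty, by penalised IRLS;
# stabilises fits under complete separation
ridge_logit <- function(X, y, lambda = 1e-2, max_iter = 100,
                        tol = 1e-8) {
  beta <- rep(0, ncol(X))
  pen <- diag(lambda, ncol(X)); pen[1, 1] <- 0  # intercept unpenalised
  for (i in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, w * X) + pen, crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  as.numeric(beta)
}

#' @export
print.stepwise_logit <- function(x, ...) {
  cat(sprintf(
    "<stepwise_logit> %d term(s) selected%s: %s\n",
    length(x$selected),
    if (x$separation) " [separation: ridge-stabilised]" else "",
    if (length(x$selected)) paste(x$selected, collapse = ", ")
    else "(intercept only)"
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.stepwise_logit <- function(x, ...) {
  if (x$separation) {
    return(tibble(term = names(x$coefficients),
                  estimate = unname(x$coefficients),
                  std.error = NA_real_, statistic = NA_real_,
                  p.value = NA_real_))
  }
  s <- summary(x$model)$coefficients
  tibble(
    term = rownames(s), estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4]
  )
}

#' @exportS3Method generics::glance
glance.stepwise_logit <- function(x, ...) {
  tibble(
    n = nrow(x$probabilities),
    n_selected = length(x$selected),
    deviance = x$model$deviance,
    null_deviance = x$model$null.deviance,
    aic = x$model$aic,
    separation = x$separation
  )
}

#' @export
predict.stepwise_logit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$probabilities$prob)
  X <- cbind(1, as.matrix(newdata[, object$selected, drop = FALSE]))
  as.numeric(plogis(X %*% object$coefficients))
}
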