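# Cohort-level statistical evaluation of delta: group comparisons, Cox
# proportional-hazards survival modelling, discrimination and agreement.

#' Z-score a numeric vector
#'
#' Standardises to mean 0 and sample SD 1 (denominator n-1), returning the
#' transform parameters so effects can be reported per SD of the original
#' scale.
#'
#' @param values numeric vector, `n >= 2`, non-constant.
#' @return A list: `z` (standardised values), `center` (mean), `scale` (SD).
#' @export
zscore <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop_spo2("zscore needs at least 2 values",
              c("spo2_degenerate_error", "spo2_data_error"))
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0)
    stop_spo2("constant (or non-finite) covariate cannot be standardised",
              c("spo2_nonidentifiable_error", "spo2_numeric_error"))
  m <- mean(values)
  list(z = (values - m) / s, center = m, scale = s)
}

#' Two-group comparison by Student's t-test
#'
#' Independent-samples t-test, pooled-variance (Student's) by default with a
#' Welch switch, two-sided. Group means and SDs are returned alongside the
#' statistic for table-style reporting.
#'
#' @param values_a,values_b numeric vectors, each with `n >= 2`.
#' @param var_equal pooled-variance Student's t if `TRUE` (default), Welch
#'   otherwise.
#' @return A list: `statistic`, `df`, `p_value`, `mean_a`, `sd_a`, `n_a`,
#'   `mean_b`, `sd_b`, `n_b`, `method`.
#' @export
two_group_t <- function(values_a, values_b, var_equal = TRUE) {
  values_a <- as.numeric(values_a)
  values_b <- as.numeric(values_b)
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop_spo2("each group needs at least 2 observations",
              c("spo2_degenerate_error", "spo2_data_error"))
  tt <- stats::t.test(values_a, values_b, var.equal = var_equal)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       mean_a = mean(values_a), sd_a = stats::sd(values_a),
       n_a = length(values_a),
       mean_b = mean(values_b), sd_b = stats::sd(values_b),
       n_b = length(values_b),
       method = if (var_equal) "student" else "welch")
}

#' Fit a Cox proportional-hazards model
#'
#' Maximum partial-likelihood Cox regression (via [survival::coxph()]) of
#' survival on one or more covariates, with Efron tie handling by default
#' (ICU day-resolution times tie often) and a Breslow switch. With
#' `standardize = TRUE`, continuous covariates (more than two distinct
#' values) are z-scored first so hazard ratios are per SD; binary covariates
#' are left on their natural scale. 95\% CIs are `exp(beta +- 1.96 * se)`.
#'
#' @param data data frame with survival columns and covariates.
#' @param covariates character vector of covariate column names.
#' @param time_col,event_col survival time (days) and event indicator
#'   (1 = died, 0 = censored) columns.
#' @param ties `"efron"` or `"breslow"`.
#' @param standardize z-score continuous covariates before fitting.
#' @return An object of class `"cox_model_fit"`: `coefficients` (one row per
#'   covariate: `term`, `beta`, `se`, `hazard_ratio`, `ci95_low`,
#'   `ci95_high`, `p_value`, `per_sd`), `model` (log partial likelihood, `n`,
#'   `n_events`, `n_iterations`, `converged`, `monotone_likelihood`),
#'   `standardization`, and the underlying `fit`.
#' @export
cox_fit <- function(data, covariates, time_col = "time_days",
                    event_col = "event", ties = c("efron", "breslow"),
                    standardize = FALSE) {
  ties <- match.arg(ties)
  if (!is.data.frame(data) ||
      !all(c(time_col, event_col, covariates) %in% names(data)))
    stop_spo2("data must contain the survival columns and every covariate",
              c("spo2_schema_error", "spo2_data_error"))
  if (length(covariates) < 1L)
    stop_spo2("need at least one covariate", "spo2_config_error")
  d <- data.frame(.time = as.numeric(data[[time_col]]),
                  .event = as.numeric(data[[event_col]]))
  if (sum(d$.event) < 1)
    stop_spo2("need at least one event",
              c("spo2_degenerate_error", "spo2_data_error"))

  X <- as.matrix(data[covariates])
  storage.mode(X) <- "double"
  if (any(!is.finite(X)))
    stop_spo2("covariates must be finite",
              c("spo2_data_error"))
  const <- apply(X, 2L, function(col) length(unique(col)) < 2L)
  if (any(const))
    stop_spo2(sprintf("constant covariate(s): %s",
                      paste(covariates[const], collapse = ", ")),
              c("spo2_nonidentifiable_error", "spo2_numeric_error"))
  if (qr(scale(X, center = TRUE, scale = FALSE))$rank < ncol(X))
    stop_spo2("covariate matrix is rank deficient (collinear columns)",
              c("spo2_nonidentifiable_error", "spo2_numeric_error"))

  std <- data.frame(term = covariates, center = 0, scale = 1,
                    per_sd = FALSE, stringsAsFactors = FALSE)
  if (standardize) {
    for (j in seq_along(covariates)) {
      if (length(unique(X[, j])) > 2L) {
        zs <- zscore(X[, j])
        X[, j] <- zs$z
        std$center[j] <- zs$center
        std$scale[j] <- zs$scale
        std$per_sd[j] <- TRUE
      }
    }
  }
  d <- cbind(d, as.data.frame(X))

  converged <- TRUE
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(
      stats::as.formula(paste("survival::Surv(.time, .event) ~",
                              paste(sprintf("`%s`", covariates),
                                    collapse = " + "))),
      data = d, ties = ties),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("did not converge", msg, fixed = TRUE))
        converged <<- FALSE
      if (grepl("infinite", msg) || grepl("Loglik converged before", msg))
        monotone <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  beta <- stats::coef(fit)
  if (anyNA(beta)) converged <- FALSE
  se <- sqrt(diag(fit$var))
  coefs <- data.frame(
    term = covariates,
    beta = unname(beta),
    se = unname(se),
    hazard_ratio = exp(unname(beta)),
    ci95_low = exp(unname(beta) - 1.96 * unname(se)),
    ci95_high = exp(unname(beta) + 1.96 * unname(se)),
    p_value = 2 * stats::pnorm(-abs(unname(beta) / unname(se))),
    per_sd = std$per_sd,
    stringsAsFactors = FALSE
  )
  structure(
    list(coefficients = coefs,
         model = list(loglik = unname(fit$loglik[length(fit$loglik)]),
                      n = fit$n, n_events = fit$nevent,
                      n_iterations = fit$iter, converged = converged,
                      monotone_likelihood = monotone),
         standardization = std,
         ties = ties,
         fit = fit),
    class = "cox_model_fit"
  )
}

#' @export
print.cox_model_fit <- function(x, ...) {
  cat(sprintf("<cox_model_fit> n = %d, events = %d, ties = %s, loglik = %.3f%s\n",
              x$model$n, x$model$n_events, x$ties, x$model$loglik,
              if (x$model$converged) "" else " [NOT CONVERGED]"))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Proportional-hazards diagnostic
#'
#' Tests the proportional-hazards assumption per covariate via scaled
#' Schoenfeld residuals: the correlation of each covariate's scaled
#' Schoenfeld residuals with the rank of the event times, with the p-value
#' from [survival::cox.zph()] (rank transform). Purely diagnostic: it flags
#' at `alpha` but never blocks a fit. With fewer than 3 events the
#' diagnostic is undefined and returned with a reason.
#'
#' @param fit a [cox_fit()] result.
#' @param alpha flagging threshold (default 0.05).
#' @return A data frame (`term`, `rho`, `p_value`, `flagged`), or a list with
#'   a `reason` when undefined.
#' @export
ph_check <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "cox_model_fit"))
  if (!fit$model$converged)
    stop_spo2("ph_check requires a converged fit",
              c("spo2_numeric_error"))
  if (fit$model$n_events < 3)
    return(list(reason = "fewer than 3 events: diagnostic undefined"))
  zph <- survival::cox.zph(fit$fit, transform = "rank")
  sch <- stats::residuals(fit$fit, type = "scaledsch")
  sch <- as.matrix(sch)
  etimes <- as.numeric(rownames(sch))
  if (!length(etimes) || anyNA(etimes))
    etimes <- sort(fit$fit$y[fit$fit$y[, "status"] == 1, "time"])
  rho <- apply(sch, 2L, function(col) stats::cor(rank(etimes), col))
  tab <- zph$table
  terms <- fit$coefficients$term
  p <- tab[match(terms, rownames(tab)), "p"]
  data.frame(term = terms, rho = unname(rho), p_value = unname(p),
             flagged = unname(p) < alpha, stringsAsFactors = FALSE)
}

#' ROC area under the curve with a normal-approximation CI
#'
#' AUC via the rank (Mann-Whitney) estimator with midrank tie correction:
#' the proportion of (case, control) pairs in which the case scores higher,
#' ties counted as half. The 95\% CI uses the Hanley-McNeil
#' normal-approximation variance of the rank statistic, clipped to \[0, 1\].
#'
#' @param risk_scores numeric risk scores (higher = more likely event).
#' @param outcome binary outcome at the horizon (logical or 0/1).
#' @return A list: `auc`, `ci95_low`, `ci95_high`, `se`, `n_pos`, `n_neg`,
#'   and `reason` (`NA` unless undefined because only one class is present).
#' @export
roc_auc <- function(risk_scores, outcome) {
  risk_scores <- as.numeric(risk_scores)
  outcome <- as.logical(outcome)
  stopifnot(length(risk_scores) == length(outcome), !anyNA(outcome))
  n_pos <- sum(outcome)
  n_neg <- sum(!outcome)
  if (n_pos == 0L || n_neg == 0L)
    return(list(auc = NA_real_, ci95_low = NA_real_, ci95_high = NA_real_,
                se = NA_real_, n_pos = n_pos, n_neg = n_neg,
                reason = "single_class"))
  r <- rank(risk_scores)   # midranks handle ties
  auc <- (sum(r[outcome]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
  se <- sqrt(max(v, 0))
  list(auc = auc,
       ci95_low = max(0, auc - 1.96 * se),
       ci95_high = min(1, auc + 1.96 * se),
       se = se, n_pos = n_pos, n_neg = n_neg, reason = NA_character_)
}

#' Bland-Altman agreement between two paired measurements
#'
#' Differences `d = a - b`; bias is `mean(d)`; limits of agreement are
#' `bias -+ 1.96 * sd(d)` (sample SD, denominator n-1); pairs outside the
#' limits are counted with strict inequality.
#'
#' @param measure_a,measure_b paired numeric vectors of equal length,
#'   `n >= 3`.
#' @return An object of class `"agreement_report"`: `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n_outside`, `n_total`, `differences`, `means`.
#' @export
bland_altman <- function(measure_a, measure_b) {
  measure_a <- as.numeric(measure_a)
  measure_b <- as.numeric(measure_b)
  if (length(measure_a) != length(measure_b))
    stop_spo2("paired measurements must have equal length",
              c("spo2_schema_error", "spo2_data_error"))
  if (length(measure_a) < 3L)
    stop_spo2("Bland-Altman needs at least 3 pairs",
              c("spo2_degenerate_error", "spo2_data_error"))
  d <- measure_a - measure_b
  bias <- mean(d)
  s <- stats::sd(d)
  loa_low <- bias - 1.96 * s
  loa_high <- bias + 1.96 * s
  structure(
    list(bias = bias, sd_diff = s, loa_low = loa_low, loa_high = loa_high,
         n_outside = sum(d < loa_low | d > loa_high),
         n_total = length(d),
         differences = d, means = (measure_a + measure_b) / 2),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> bias = %.4g, limits of agreement [%.4g, %.4g], %d/%d pair(s) outside\n",
              x$bias, x$loa_low, x$loa_high, x$n_outside, x$n_total))
  invisible(x)
}

#' Survivor vs non-survivor feature summary
#'
#' Per disease group and feature: mean and SD among survivors (`event == 0`)
#' and non-survivors (`event == 1`), with the two-sided pooled-variance
#' Student's t-test p-value. Cells with fewer than 2 usable values per arm
#' are reported as `NA` rather than raising errors.
#'
#' @param cohort data frame with `group`, `event`, and the feature columns.
#' @param features feature columns to summarise; defaults to whichever of
#'   `mean_spo2`, `sampen`, `delta`, `sofa`, `meld` are present.
#' @param group_col,event_col column names.
#' @param var_equal passed to [two_group_t()].
#' @return A data frame with one row per (group, feature).
#' @export
survivor_table <- function(cohort,
                           features = intersect(c("mean_spo2", "sampen",
                                                  "delta", "sofa", "meld"),
                                                names(cohort)),
                           group_col = "group", event_col = "event",
                           var_equal = TRUE) {
  if (!is.data.frame(cohort) ||
      !all(c(group_col, event_col) %in% names(cohort)))
    stop_spo2("cohort needs group and event columns",
              c("spo2_schema_error", "spo2_data_error"))
  if (!length(features))
    stop_spo2("no feature columns to summarise",
              c("spo2_schema_error", "spo2_data_error"))
  groups <- unique(as.character(cohort[[group_col]]))
  out <- list()
  for (g in groups) {
    sub <- cohort[cohort[[group_col]] == g, , drop = FALSE]
    surv <- sub[sub[[event_col]] == 0, , drop = FALSE]
    nons <- sub[sub[[event_col]] == 1, , drop = FALSE]
    for (f in features) {
      a <- surv[[f]][is.finite(surv[[f]])]
      b <- nons[[f]][is.finite(nons[[f]])]
      ok <- length(a) >= 2L && length(b) >= 2L
      # a near-constant feature makes the t statistic undefined; report NA
      p <- if (ok) tryCatch(two_group_t(a, b, var_equal = var_equal)$p_value,
                            error = function(e) NA_real_)
           else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        group = g, feature = f,
        n_survivor = length(a), n_nonsurvivor = length(b),
        mean_survivor = if (length(a)) mean(a) else NA_real_,
        sd_survivor = if (length(a) >= 2L) stats::sd(a) else NA_real_,
        mean_nonsurvivor = if (length(b)) mean(b) else NA_real_,
        sd_nonsurvivor = if (length(b) >= 2L) stats::sd(b) else NA_real_,
        p_value = p,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
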