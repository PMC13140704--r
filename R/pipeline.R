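# End-to-end orchestration: reference fit -> entropy -> delta -> survival
# analysis -> reports. Pure functions of (config, inputs); every subject gets
# a logged disposition so the analysed n is auditable.

#' Run configuration
#'
#' Bundles the knobs shared by [run_reference()] and [run_cohort()]:
#' entropy parameters, per-group segment durations (20 min for patient
#' groups, 10 min for acute liver failure where long clean recordings are
#' scarce, 8 min for reference exposures), tie handling, the survival
#' horizon, the predictors screened univariately, and the multivariate model
#' definitions.
#'
#' @param seed integer seed (orchestration itself is deterministic; the seed
#'   is recorded and forwarded to any simulation step).
#' @param embed_dim,tolerance_factor,tolerance_mode,max_scale forwarded to
#'   [entropy_params()].
#' @param durations named list of required segment durations (seconds) per
#'   group label, plus `reference`; groups not listed fall back to `default`.
#' @param fit_mode reference fit mode, see [fit_reference()].
#' @param ties Cox tie handling, see [cox_fit()].
#' @param horizon survival horizon in days.
#' @param predictors covariates screened with univariate Cox models.
#' @param models named list of covariate sets for multivariate Cox models.
#' @param agreement_durations optional length-2 vector `c(long_s, short_s)`;
#'   in signal mode, delta is recomputed at both durations and their
#'   Bland-Altman agreement reported.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(seed = 1L, embed_dim = 2L, tolerance_factor = 0.2,
                       tolerance_mode = "relative_sd", max_scale = 5L,
                       durations = list(sepsis = 1200, copd = 1200,
                                        cirrhosis = 1200, alf = 600,
                                        healthy = 1200, synthetic = 1200,
                                        other = 1200, default = 1200,
                                        reference = 480),
                       fit_mode = "group_mean",
                       ties = "efron", horizon = 30,
                       predictors = c("mean_spo2", "sampen", "delta", "sofa",
                                      "meld", "mech_vent"),
                       models = list(model1 = c("delta", "sofa",
                                                "mech_vent")),
                       agreement_durations = NULL) {
  structure(
    list(seed = as.integer(seed),
         params = entropy_params(embed_dim, tolerance_factor,
                                 tolerance_mode, max_scale),
         durations = durations, fit_mode = fit_mode, ties = ties,
         horizon = horizon, predictors = predictors, models = models,
         agreement_durations = agreement_durations),
    class = "run_config"
  )
}

read_table_input <- function(input, what) {
  if (is.data.frame(input)) return(input)
  if (is.character(input) && length(input) == 1L) {
    if (!file.exists(input))
      stop_spo2(sprintf("%s input not found: %s", what, input),
                c("spo2_missing_input_error", "spo2_config_error"))
    return(utils::read.csv(input, stringsAsFactors = FALSE))
  }
  stop_spo2(sprintf("%s input must be a data frame or a CSV path", what),
            c("spo2_config_error"))
}

group_duration <- function(config, group) {
  d <- config$durations[[as.character(group)]]
  if (is.null(d)) d <- config$durations$default
  if (is.null(d)) d <- 1200
  as.integer(d)
}

#' Fit the reference line from a table or a directory of signals
#'
#' Accepts either a reference point table (columns `fio2`, `mean_spo2`,
#' `sampen`, optionally `subject_id`) or a signal manifest (columns `path`,
#' `fio2`, optionally `subject_id`) whose files are read, quality-controlled
#' at the reference duration, segmented with the `"final"` policy and run
#' through the entropy module. The fitted line, the per-level means and a
#' report are returned and, when `output_dir` is given, written to
#' `reference_line.json`, `reference_points.csv` and
#' `reference_report.json`.
#'
#' @param input data frame or CSV path (point table or signal manifest).
#' @param config a [run_config()].
#' @param output_dir optional output directory.
#' @return A list: `line`, `points`, `report`, `exclusions`.
#' @export
run_reference <- function(input, config = run_config(), output_dir = NULL) {
  tbl <- read_table_input(input, "reference")
  exclusions <- data.frame(subject_id = character(), disposition = character(),
                           reason = character(), stringsAsFactors = FALSE)

  if ("path" %in% names(tbl)) {
    if (!"fio2" %in% names(tbl))
      stop_spo2("signal manifest needs columns 'path' and 'fio2'",
                c("spo2_schema_error", "spo2_data_error"))
    dur <- as.integer(config$durations$reference %||% 480)
    rows <- list()
    for (i in seq_len(nrow(tbl))) {
      id <- if ("subject_id" %in% names(tbl)) tbl$subject_id[i] else NULL
      rec <- read_spo2_csv(tbl$path[i], id = id)
      qc <- qc_record(rec, dur)
      if (!qc$passed) {
        exclusions <- rbind(exclusions, data.frame(
          subject_id = rec$subject_id, disposition = "excluded",
          reason = sprintf("insufficient valid duration: longest run %d s < %d s",
                           qc$longest_valid_run_s, dur),
          stringsAsFactors = FALSE))
        next
      }
      seg <- extract_segment(rec, dur, policy = "final",
                             group_label = "healthy")
      ent <- sample_entropy(seg, config$params)
      if (is.na(ent$sampen)) {
        exclusions <- rbind(exclusions, data.frame(
          subject_id = rec$subject_id, disposition = "excluded",
          reason = sprintf("undefined entropy (%s)", ent$reason),
          stringsAsFactors = FALSE))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        fio2 = tbl$fio2[i], subject_id = rec$subject_id,
        mean_spo2 = mean(seg$values), sampen = ent$sampen,
        stringsAsFactors = FALSE)
      exclusions <- rbind(exclusions, data.frame(
        subject_id = rec$subject_id, disposition = "analysed", reason = "",
        stringsAsFactors = FALSE))
    }
    if (!length(rows))
      stop_spo2("no reference subject passed quality control",
                c("spo2_run_error", "spo2_data_error"))
    points <- do.call(rbind, rows)
  } else {
    points <- tbl
  }

  line <- fit_reference(points, fit_mode = config$fit_mode)
  level_means <- if ("fio2" %in% names(points)) {
    stats::aggregate(cbind(mean_spo2, sampen) ~ fio2, data = points,
                     FUN = mean)
  } else NULL
  report <- list(slope = line$slope, intercept = line$intercept,
                 r_squared = line$r_squared, n_points = line$n_points,
                 fit_mode = line$fit_mode,
                 n_subjects = nrow(points),
                 level_means = level_means)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    save_reference_line(line, file.path(output_dir, "reference_line.json"))
    utils::write.csv(points, file.path(output_dir, "reference_points.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(output_dir,
                                           "reference_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  list(line = line, points = points, report = report,
       exclusions = exclusions)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full cohort analysis
#'
#' From either a feature table (columns `subject_id`, `group`, `time_days`,
#' `event`, `mean_spo2`, `sampen`, optional scores) or a signal manifest
#' (same columns with `path` instead of the entropy features), computes per
#' subject: QC at the group's required duration, earliest-policy
#' segmentation, entropy, and delta; then the survivor/non-survivor summary,
#' univariate Cox screens for each configured predictor (z-scored), the
#' configured multivariate models with proportional-hazards diagnostics and
#' ROC discrimination of their linear predictors, and (in signal mode, if
#' configured) long-vs-short duration Bland-Altman agreement of delta.
#' Every subject receives a logged disposition.
#'
#' @param input data frame or CSV path.
#' @param line a `"reference_line"` or path to its JSON.
#' @param config a [run_config()].
#' @param output_dir optional output directory (writes `cohort.csv`,
#'   `survivor_table.csv`, `models.json`, `run_log.jsonl`).
#' @return A list: `cohort`, `survivor_table`, `univariate`, `models`,
#'   `ph`, `auc`, `agreement`, `log`.
#' @export
run_cohort <- function(input, line, config = run_config(),
                       output_dir = NULL) {
  if (is.character(line)) line <- load_reference_line(line)
  tbl <- read_table_input(input, "cohort")
  need <- c("subject_id", "group", "time_days", "event")
  if (!all(need %in% names(tbl)))
    stop_spo2(sprintf("cohort input needs columns: %s",
                      paste(need, collapse = ", ")),
              c("spo2_schema_error", "spo2_data_error"))

  log <- list()
  note <- function(id, disposition, reason = "") {
    log[[length(log) + 1L]] <<- data.frame(
      subject_id = id, disposition = disposition, reason = reason,
      stringsAsFactors = FALSE)
  }

  agreement_pairs <- NULL
  if ("path" %in% names(tbl)) {
    rows <- list()
    agree <- list()
    for (i in seq_len(nrow(tbl))) {
      id <- tbl$subject_id[i]
      grp <- tbl$group[i]
      dur <- group_duration(config, grp)
      rec <- read_spo2_csv(tbl$path[i], id = id)
      qc <- qc_record(rec, dur)
      if (!qc$passed) {
        note(id, "excluded",
             sprintf("insufficient duration: longest valid run %d s < %d s required",
                     qc$longest_valid_run_s, dur))
        next
      }
      seg <- extract_segment(rec, dur, policy = "earliest",
                             group_label = if (grp %in% GROUP_LABELS) grp else "other")
      prof <- multiscale_entropy(seg, config$params)
      if (is.na(prof$sampen)) {
        note(id, "excluded", "undefined entropy at scale 1")
        next
      }
      row <- tbl[i, setdiff(names(tbl), "path"), drop = FALSE]
      row$mean_spo2 <- mean(seg$values)
      row$sampen <- prof$sampen
      row$mse_mean <- prof$mse_mean
      rows[[length(rows) + 1L]] <- row
      note(id, "analysed")
      if (!is.null(config$agreement_durations)) {
        long_s <- as.integer(config$agreement_durations[1])
        short_s <- as.integer(config$agreement_durations[2])
        if (length(seg$values) >= long_s) {
          vl <- seg$values[seq_len(long_s)]
          vs <- seg$values[seq_len(short_s)]
          agree[[length(agree) + 1L]] <- data.frame(
            subject_id = id,
            x_long = mean(vl), y_long = sample_entropy(vl, config$params)$sampen,
            x_short = mean(vs), y_short = sample_entropy(vs, config$params)$sampen,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (!length(rows))
      stop_spo2("no subject passed quality control",
                c("spo2_run_error", "spo2_data_error"))
    cohort <- do.call(rbind, rows)
    if (length(agree)) agreement_pairs <- do.call(rbind, agree)
  } else {
    if (!all(c("mean_spo2", "sampen") %in% names(tbl)))
      stop_spo2("feature-table input needs 'mean_spo2' and 'sampen'",
                c("spo2_schema_error", "spo2_data_error"))
    cohort <- tbl
    for (id in cohort$subject_id) note(id, "analysed")
  }

  cohort <- batch_delta(cohort, line)
  usable <- cohort[!cohort$delta_flagged & is.finite(cohort$time_days) &
                     cohort$time_days > 0, , drop = FALSE]
  for (id in setdiff(cohort$subject_id, usable$subject_id)) {
    note(id, "excluded", "undefined entropy or invalid survival time")
  }

  surv_tab <- tryCatch(survivor_table(usable),
                       spo2delta_error = function(e) NULL)

  preds <- intersect(config$predictors, names(usable))
  preds <- preds[vapply(preds, function(p) {
    v <- usable[[p]]
    is.numeric(v) && all(is.finite(v)) && length(unique(v)) > 1L
  }, logical(1))]
  univariate <- lapply(preds, function(p) {
    cox_fit(usable, p, ties = config$ties, standardize = TRUE)
  })
  names(univariate) <- preds

  models <- list()
  ph <- list()
  auc <- list()
  for (mn in names(config$models)) {
    covs <- intersect(config$models[[mn]], preds)
    if (length(covs) < 1L) next
    fit <- cox_fit(usable, covs, ties = config$ties, standardize = TRUE)
    models[[mn]] <- fit
    ph[[mn]] <- tryCatch(ph_check(fit), spo2delta_error = function(e) NULL)
    lp <- unname(stats::predict(fit$fit, type = "lp"))
    auc[[mn]] <- roc_auc(lp, usable$event == 1)
  }

  agreement <- NULL
  if (!is.null(agreement_pairs) && nrow(agreement_pairs) >= 3L) {
    d_long <- parenclitic_delta(agreement_pairs$x_long,
                                agreement_pairs$y_long, line)$delta
    d_short <- parenclitic_delta(agreement_pairs$x_short,
                                 agreement_pairs$y_short, line)$delta
    agreement <- bland_altman(d_long, d_short)
  }

  log <- do.call(rbind, log)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cohort, file.path(output_dir, "cohort.csv"),
                     row.names = FALSE)
    if (!is.null(surv_tab))
      utils::write.csv(surv_tab, file.path(output_dir, "survivor_table.csv"),
                       row.names = FALSE)
    model_json <- list(
      univariate = lapply(univariate, function(f) f$coefficients),
      models = lapply(models, function(f) f$coefficients),
      auc = auc
    )
    jsonlite::write_json(model_json, file.path(output_dir, "models.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    writeLines(
      vapply(seq_len(nrow(log)), function(i)
        as.character(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE)),
        character(1)),
      file.path(output_dir, "run_log.jsonl"))
  }

  list(cohort = cohort, survivor_table = surv_tab, univariate = univariate,
       models = models, ph = ph, auc = auc, agreement = agreement, log = log)
}
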