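# The healthy hypoxia-response reference line and directional parenclitic
# deviation (delta).
#
# Healthy subjects exposed to graded normobaric hypoxia show an inverse
# linear relationship between mean SpO2 (x) and SampEn (y): entropy rises as
# oxygen availability falls. Ordinary least squares over that reference
# population gives a line y = m*x + b, and each subject's signed
# perpendicular distance from it,
#
#     delta = (m*x - y + b) / sqrt(m^2 + 1),
#
# is the directional parenclitic deviation. No absolute value is taken:
# points below the line (entropy lower than expected for the observed
# saturation) get positive delta, points above get negative delta. The axes
# are used in their raw units (percent saturation, entropy), so delta carries
# the mixed units of that plane.

#' Fit the healthy reference regression
#'
#' Ordinary least-squares regression of SampEn (`sampen`, y) on mean SpO2
#' (`mean_spo2`, x) over a reference table. Under the default
#' `fit_mode = "group_mean"` the per-subject points are first averaged within
#' each inspired-oxygen (`fio2`) level and the line is fitted to the level
#' means, each level weighted equally; this is the mode under which a
#' graded-hypoxia protocol yields a near-perfect linear fit. The
#' `"per_subject"` mode fits all individual points and is kept for
#' sensitivity analysis.
#'
#' @param points data frame with columns `mean_spo2` and `sampen`, plus
#'   `fio2` when `fit_mode = "group_mean"`.
#' @param fit_mode `"group_mean"` or `"per_subject"`.
#' @return An object of class `"reference_line"`: `slope`, `intercept`,
#'   `r_squared`, `n_points` (points actually fitted), `fit_mode`.
#' @export
fit_reference <- function(points, fit_mode = c("group_mean", "per_subject")) {
  fit_mode <- match.arg(fit_mode)
  if (!is.data.frame(points) ||
      !all(c("mean_spo2", "sampen") %in% names(points)))
    stop_spo2("reference points need columns 'mean_spo2' and 'sampen'",
              c("spo2_schema_error", "spo2_data_error"))
  pts <- points[is.finite(points$mean_spo2) & is.finite(points$sampen), ,
                drop = FALSE]
  if (fit_mode == "group_mean") {
    if (!"fio2" %in% names(pts))
      stop_spo2("group_mean fit needs a 'fio2' column",
                c("spo2_schema_error", "spo2_data_error"))
    pts <- stats::aggregate(cbind(mean_spo2, sampen) ~ fio2, data = pts,
                            FUN = mean)
  }
  if (nrow(pts) < 2L)
    stop_spo2("need at least 2 reference points with finite values",
              c("spo2_degenerate_error", "spo2_data_error"))
  if (length(unique(pts$mean_spo2)) < 2L)
    stop_spo2("all mean_spo2 values identical: slope not identifiable",
              c("spo2_nonidentifiable_error", "spo2_numeric_error"))

  fit <- stats::lm(sampen ~ mean_spo2, data = pts)
  ss_tot <- sum((pts$sampen - mean(pts$sampen))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot

  structure(
    list(slope = unname(stats::coef(fit)[["mean_spo2"]]),
         intercept = unname(stats::coef(fit)[["(Intercept)"]]),
         r_squared = r2,
         n_points = nrow(pts),
         fit_mode = fit_mode),
    class = "reference_line"
  )
}

#' @export
print.reference_line <- function(x, ...) {
  cat(sprintf("<reference_line> SampEn = %.5g + %.5g * meanSpO2 (R^2 = %.4f, %d %s point(s))\n",
              x$intercept, x$slope, x$r_squared, x$n_points, x$fit_mode))
  invisible(x)
}

#' Directional parenclitic deviation from the reference line
#'
#' Signed perpendicular distance of the point(s) `(x, y)` from the reference
#' line `y = slope * x + intercept`:
#' `delta = (slope * x - y + intercept) / sqrt(slope^2 + 1)`.
#' Direction is preserved (no absolute value): `delta > 0` below the line
#' (lower-than-expected entropy), `delta < 0` above it. A missing `y`
#' propagates to a missing `delta`.
#'
#' @param x mean SpO2 in percent (vectorised).
#' @param y scale-1 SampEn (vectorised, recycled against `x`).
#' @param line a [fit_reference()] result (or any list with finite `slope`
#'   and `intercept`).
#' @return A data frame with columns `x`, `y`, `y_hat` (predicted entropy)
#'   and `delta`.
#' @export
parenclitic_delta <- function(x, y, line) {
  if (!is.list(line) || !is.finite(line$slope) || !is.finite(line$intercept))
    stop_spo2("reference line must have finite slope and intercept",
              c("spo2_config_error"))
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  m <- line$slope
  b <- line$intercept
  y_hat <- m * x + b
  delta <- (m * x - y + b) / sqrt(m^2 + 1)
  data.frame(x = x, y = y, y_hat = y_hat, delta = delta)
}

#' Add a delta column to a cohort feature table
#'
#' Row-wise [parenclitic_delta()] over a feature table. Rows whose entropy is
#' undefined are flagged (`delta_flagged = TRUE`, `delta = NA`) and are meant
#' to be excluded from downstream statistics; the count of flagged rows is
#' reported via `message()` and stored in the `n_flagged` attribute.
#'
#' @param tbl data frame containing the `x_col` and `y_col` columns.
#' @param line a [fit_reference()] result.
#' @param x_col,y_col column names holding mean SpO2 and SampEn.
#' @return `tbl` with added `delta` and `delta_flagged` columns.
#' @export
batch_delta <- function(tbl, line, x_col = "mean_spo2", y_col = "sampen") {
  if (!is.data.frame(tbl) || !all(c(x_col, y_col) %in% names(tbl)))
    stop_spo2(sprintf("feature table needs columns '%s' and '%s'",
                      x_col, y_col),
              c("spo2_schema_error", "spo2_data_error"))
  d <- parenclitic_delta(tbl[[x_col]], tbl[[y_col]], line)
  tbl$delta <- d$delta
  tbl$delta_flagged <- !is.finite(d$y)
  n_flagged <- sum(tbl$delta_flagged)
  if (n_flagged > 0)
    message(sprintf("batch_delta: %d row(s) with undefined entropy flagged and excluded from delta",
                    n_flagged))
  attr(tbl, "n_flagged") <- n_flagged
  tbl
}

#' Persist a reference line as JSON
#'
#' The reference line is the only artefact patient analysis needs from the
#' reference population, so it is serialisable to a small JSON config
#' (`slope`, `intercept`, `r_squared`, `n_points`, `fit_mode`) and can be
#' loaded without access to the raw reference signals.
#'
#' @param line a `"reference_line"`.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
save_reference_line <- function(line, path) {
  stopifnot(inherits(line, "reference_line"))
  jsonlite::write_json(unclass(line), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_reference_line
#' @return `load_reference_line()` returns the `"reference_line"` object.
#' @export
load_reference_line <- function(path) {
  if (!file.exists(path))
    stop_spo2(sprintf("reference line file not found: %s", path),
              c("spo2_missing_input_error", "spo2_config_error"))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("slope", "intercept")
  if (!all(need %in% names(obj)) || !all(is.finite(unlist(obj[need]))))
    stop_spo2("reference line JSON must contain finite 'slope' and 'intercept'",
              c("spo2_schema_error", "spo2_data_error"))
  structure(
    list(slope = obj$slope, intercept = obj$intercept,
         r_squared = if (is.null(obj$r_squared)) NA_real_ else obj$r_squared,
         n_points = if (is.null(obj$n_points)) NA_integer_ else obj$n_points,
         fit_mode = if (is.null(obj$fit_mode)) NA_character_ else obj$fit_mode),
    class = "reference_line"
  )
}
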