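# Reading, validating and segmenting 1 Hz SpO2 recordings.
#
# A "record" is the raw per-second export (possibly with missing seconds and
# out-of-range values); a "segment" is a gap-free, in-range slice that has
# passed quality control and is the atomic unit all entropy analysis runs on.

GROUP_LABELS <- c("healthy", "sepsis", "copd", "alf", "cirrhosis",
                  "synthetic", "other")

#' Construct a gap-free SpO2 segment
#'
#' An oximetry segment is a contiguous 1 Hz SpO2 series for one subject: at
#' least two samples, every value in \[0, 100\] percent, no missing entries.
#' Sampling at 1 Hz is implied by position, so the segment stores only the
#' values and the offset (in seconds) of its first sample from the start of
#' the source recording.
#'
#' @param values numeric vector of SpO2 values in percent, one per second.
#' @param subject_id opaque subject identifier.
#' @param group_label one of `"healthy"`, `"sepsis"`, `"copd"`, `"alf"`,
#'   `"cirrhosis"`, `"synthetic"`, `"other"`.
#' @param start_offset seconds from the start of the source recording.
#' @return An object of class `"oximetry_segment"`.
#' @export
oximetry_segment <- function(values, subject_id = "unknown",
                             group_label = "other", start_offset = 0) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop_spo2("an oximetry segment needs at least 2 samples",
              c("spo2_degenerate_error", "spo2_data_error"))
  if (anyNA(values) || any(!is.finite(values)))
    stop_spo2("oximetry segments are gap-free by construction; found missing/non-finite values",
              c("spo2_format_error", "spo2_data_error"))
  if (any(values < 0 | values > 100))
    stop_spo2("SpO2 values must lie in [0, 100] percent",
              c("spo2_format_error", "spo2_data_error"))
  group_label <- match.arg(group_label, GROUP_LABELS)
  structure(
    list(subject_id = as.character(subject_id), group_label = group_label,
         start_offset = as.numeric(start_offset), values = values),
    class = "oximetry_segment"
  )
}

#' @export
print.oximetry_segment <- function(x, ...) {
  cat(sprintf("<oximetry_segment> subject %s (%s): %d s at 1 Hz, offset %gs, mean SpO2 %.2f%%\n",
              x$subject_id, x$group_label, length(x$values), x$start_offset,
              mean(x$values)))
  invisible(x)
}

#' @export
length.oximetry_segment <- function(x) length(x$values)

# Accept either a bare numeric vector or an oximetry_segment.
seg_values <- function(x) {
  if (inherits(x, "oximetry_segment")) x$values else as.numeric(x)
}

#' Read a 1 Hz SpO2 export
#'
#' Reads a plain-text SpO2 export: either a two-column CSV (`t_s,spo2`,
#' integer seconds plus percent saturation, header optional) or a
#' single-column value-per-line file taken to be 1 Hz starting at second 0
#' (the WFDB-style numeric dialect). Gzip-compressed files are accepted.
#' Out-of-range and missing values are retained and flagged, not dropped:
#' quality control happens in [qc_record()].
#'
#' Duplicated timestamps are rejected outright (sub-second or duplicated
#' stamps indicate an export this reader is not meant to repair), and
#' timestamps must be whole seconds.
#'
#' @param path path to the file.
#' @param id subject identifier; defaults to the file name without extension.
#' @return An object of class `"spo2_record"`: integer timestamps `t_s`,
#'   numeric `spo2` (possibly `NA`), and gap / out-of-range counts.
#' @export
read_spo2_csv <- function(path, id = NULL) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop_spo2(sprintf("input file not found: %s", path),
              c("spo2_missing_input_error", "spo2_config_error"))
  if (is.null(id))
    id <- sub("\\.(csv|txt)(\\.gz)?$", "", basename(path))

  lines <- readLines(path, warn = FALSE)   # file() auto-detects gzip
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    stop_spo2(sprintf("empty input file: %s", path),
              c("spo2_empty_error", "spo2_data_error"))

  has_header <- grepl("[A-Za-z]", lines[[1L]])
  body <- if (has_header) lines[-1L] else lines
  if (!length(body))
    stop_spo2(sprintf("no data rows in: %s", path),
              c("spo2_empty_error", "spo2_data_error"))

  parts <- strsplit(body, ",", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols > 2L) || length(unique(ncols)) != 1L)
    stop_spo2("expected a one-column or uniform two-column file",
              c("spo2_format_error", "spo2_data_error"))

  parse_num <- function(tok, what) {
    tok <- trimws(tok)
    missing <- tok %in% c("", "NA", "NaN", "nan")
    out <- suppressWarnings(as.numeric(tok))
    if (any(is.na(out) & !missing))
      stop_spo2(sprintf("unparseable %s value(s), e.g. '%s'",
                        what, tok[which(is.na(out) & !missing)[1L]]),
                c("spo2_format_error", "spo2_data_error"))
    out
  }

  if (ncols[1L] == 1L) {
    spo2 <- parse_num(vapply(parts, `[`, "", 1L), "SpO2")
    t_s <- seq_along(spo2) - 1L
  } else {
    t_s <- parse_num(vapply(parts, `[`, "", 1L), "timestamp")
    spo2 <- parse_num(vapply(parts, `[`, "", 2L), "SpO2")
    if (anyNA(t_s))
      stop_spo2("missing timestamps are not allowed",
                c("spo2_format_error", "spo2_data_error"))
    if (any(t_s != floor(t_s)))
      stop_spo2("timestamps must be whole seconds (1 Hz export)",
                c("spo2_format_error", "spo2_data_error"))
    if (anyDuplicated(t_s))
      stop_spo2("duplicated timestamps rejected",
                c("spo2_format_error", "spo2_data_error"))
    o <- order(t_s)
    t_s <- t_s[o]
    spo2 <- spo2[o]
  }

  t_s <- as.integer(t_s)
  n_gaps <- if (length(t_s) > 1L) sum(diff(t_s) - 1L) else 0L
  out_of_range <- is.finite(spo2) & (spo2 < 0 | spo2 > 100)

  structure(
    list(subject_id = as.character(id), t_s = t_s, spo2 = spo2,
         n_gaps = as.integer(n_gaps),
         n_out_of_range = as.integer(sum(out_of_range))),
    class = "spo2_record"
  )
}

#' @export
print.spo2_record <- function(x, ...) {
  cat(sprintf("<spo2_record> subject %s: %d samples, %d missing second(s), %d out-of-range\n",
              x$subject_id, length(x$t_s), x$n_gaps, x$n_out_of_range))
  invisible(x)
}

# A second is "valid" iff a sample exists for it, is finite, and lies in
# [0, 100]. Out-of-range values break a run exactly as a missing second does:
# the analysis is restricted to noise-free series and performs no imputation.
# Returns a data.frame of maximal valid runs (row indices into the record).
valid_runs <- function(record) {
  ok <- is.finite(record$spo2) & record$spo2 >= 0 & record$spo2 <= 100
  n <- length(ok)
  if (n == 0L)
    return(data.frame(start = integer(), end = integer(), length = integer()))
  # a run breaks where validity switches off or where timestamps jump
  contig <- c(TRUE, diff(record$t_s) == 1L)
  idx <- which(ok)
  if (!length(idx))
    return(data.frame(start = integer(), end = integer(), length = integer()))
  brk <- c(TRUE, diff(idx) != 1L | !contig[idx[-1L]])
  run_id <- cumsum(brk)
  start <- idx[!duplicated(run_id)]
  end <- idx[rev(!duplicated(rev(run_id)))]
  data.frame(start = start, end = end, length = end - start + 1L)
}

#' Quality-control report for an SpO2 record
#'
#' Checks whether the record contains a contiguous run of valid seconds (a
#' sample for every second, each value finite and in \[0, 100\]) at least
#' `required_duration_s` long. A report is always produced; nothing is
#' imputed or repaired.
#'
#' @param record an `"spo2_record"` from [read_spo2_csv()].
#' @param required_duration_s required continuous duration in seconds
#'   (e.g. 1200 for 20-min patient segments, 600 for 10-min, 480 for the
#'   8-min reference exposures).
#' @return An object of class `"qc_report"`.
#' @export
qc_record <- function(record, required_duration_s) {
  stopifnot(inherits(record, "spo2_record"))
  if (!is_count(required_duration_s))
    stop_spo2("required_duration_s must be a positive whole number of seconds",
              c("spo2_config_error"))
  runs <- valid_runs(record)
  longest <- if (nrow(runs)) max(runs$length) else 0L
  structure(
    list(subject_id = record$subject_id,
         n_samples = length(record$t_s),
         n_out_of_range = record$n_out_of_range,
         n_gaps = record$n_gaps,
         longest_valid_run_s = as.integer(longest),
         required_duration_s = as.integer(required_duration_s),
         passed = longest >= required_duration_s),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> subject %s: %d samples, %d gap(s), %d out-of-range, longest valid run %d s (need %d s) -> %s\n",
              x$subject_id, x$n_samples, x$n_gaps, x$n_out_of_range,
              x$longest_valid_run_s, x$required_duration_s,
              if (x$passed) "PASS" else "FAIL"))
  invisible(x)
}

#' Serialise a QC report as a JSON line
#'
#' One-line JSON rendering used for run logs.
#'
#' @param report a `"qc_report"`.
#' @return A length-1 character JSON string.
#' @export
qc_json <- function(report) {
  stopifnot(inherits(report, "qc_report"))
  as.character(jsonlite::toJSON(unclass(report), auto_unbox = TRUE))
}

#' Extract a valid segment from a record
#'
#' Selects a contiguous, gap-free, in-range run of exactly `duration_s`
#' samples. Under `policy = "earliest"` (the patient convention: the earliest
#' available series of the first ICU day) the first qualifying run is used
#' and its first `duration_s` samples are returned; under `policy = "final"`
#' (the reference-exposure convention: the final minutes of a hypoxia level,
#' approximating a stable hypoxic state) the last qualifying run is used and
#' its last `duration_s` samples are returned. The result is always a
#' contiguous slice of the raw record.
#'
#' @param record an `"spo2_record"`.
#' @param duration_s segment length in seconds.
#' @param policy `"earliest"` or `"final"`.
#' @param group_label group label attached to the resulting segment.
#' @return An [oximetry_segment()].
#' @export
extract_segment <- function(record, duration_s,
                            policy = c("earliest", "final"),
                            group_label = "other") {
  stopifnot(inherits(record, "spo2_record"))
  policy <- match.arg(policy)
  if (!is_count(duration_s) || duration_s < 2)
    stop_spo2("duration_s must be a whole number of seconds >= 2",
              c("spo2_config_error"))
  runs <- valid_runs(record)
  runs <- runs[runs$length >= duration_s, , drop = FALSE]
  if (!nrow(runs)) {
    all_runs <- valid_runs(record)
    longest <- if (nrow(all_runs)) max(all_runs$length) else 0L
    stop_spo2(sprintf("no valid run of %d s (longest available: %d s)",
                      duration_s, longest),
              c("spo2_extraction_error", "spo2_data_error"),
              longest_valid_run_s = longest)
  }
  if (policy == "earliest") {
    r <- runs[which.min(runs$start), ]
    i0 <- r$start
  } else {
    r <- runs[which.max(runs$end), ]
    i0 <- r$end - duration_s + 1L
  }
  i1 <- i0 + duration_s - 1L
  oximetry_segment(record$spo2[i0:i1],
                   subject_id = record$subject_id,
                   group_label = group_label,
                   start_offset = record$t_s[i0] - record$t_s[1L])
}

#' Write a segment as canonical two-column CSV
#'
#' Writes `t_s,spo2` with timestamps reconstructed from the segment's start
#' offset, so that reading the file back reproduces the segment exactly.
#'
#' @param segment an [oximetry_segment()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_segment_csv <- function(segment, path) {
  stopifnot(inherits(segment, "oximetry_segment"))
  df <- data.frame(
    t_s = segment$start_offset + seq_along(segment$values) - 1L,
    spo2 = segment$values
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
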