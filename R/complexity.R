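# Sample entropy and multiscale entropy of SpO2 segments.
#
# SampEn(m, r): the negative natural log of the conditional probability that
# two template vectors of length m that are close (Chebyshev distance <= t)
# remain close when extended to length m+1. Self-matches are excluded and
# each unordered pair is counted once. Both the m- and (m+1)-length counts
# run over the same N - m template start positions, the standard convention,
# which guarantees A <= B and makes a constant series give exactly 0.

#' Entropy parameters
#'
#' Parameter bundle for [sample_entropy()] and [multiscale_entropy()].
#' Defaults are the standard SpO2-variability settings: embedding dimension
#' `m = 2`, tolerance `r = 0.2` interpreted relative to the standard
#' deviation of the (scale-1) series, and five coarse-graining scales.
#'
#' @param embed_dim template length `m` (>= 1).
#' @param tolerance_factor tolerance `r` (> 0). Under
#'   `tolerance_mode = "relative_sd"` the absolute tolerance is
#'   `r * sd(series)` (sample SD, denominator n-1); under `"absolute"` it is
#'   `r` percentage points directly. The relative reading is the canonical
#'   SampEn convention; the absolute switch matters for integer-percent
#'   signals, where the SD itself is small and discrete.
#' @param tolerance_mode `"relative_sd"` or `"absolute"`.
#' @param max_scale number of coarse-graining scales for multiscale entropy.
#' @return An object of class `"entropy_params"`.
#' @export
entropy_params <- function(embed_dim = 2L, tolerance_factor = 0.2,
                           tolerance_mode = c("relative_sd", "absolute"),
                           max_scale = 5L) {
  tolerance_mode <- match.arg(tolerance_mode)
  if (!is_count(embed_dim))
    stop_spo2("embed_dim must be a positive integer", "spo2_config_error")
  if (!is.numeric(tolerance_factor) || length(tolerance_factor) != 1L ||
      !is.finite(tolerance_factor) || tolerance_factor <= 0)
    stop_spo2("tolerance_factor must be a positive real", "spo2_config_error")
  if (!is_count(max_scale))
    stop_spo2("max_scale must be a positive integer", "spo2_config_error")
  structure(
    list(embed_dim = as.integer(embed_dim),
         tolerance_factor = as.numeric(tolerance_factor),
         tolerance_mode = tolerance_mode,
         max_scale = as.integer(max_scale)),
    class = "entropy_params"
  )
}

#' Coarse-grain a series
#'
#' Non-overlapping window averaging: output element `j` is the mean of input
#' window `[(j-1)*scale + 1, j*scale]`; the output has `floor(N / scale)`
#' elements and any trailing remainder samples are discarded. Scale 1 returns
#' the series unchanged.
#'
#' @param x numeric vector or [oximetry_segment()].
#' @param scale positive integer window width.
#' @return Numeric vector of window means.
#' @export
coarse_grain <- function(x, scale) {
  x <- seg_values(x)
  if (!is_count(scale))
    stop_spo2("scale must be a positive integer", "spo2_config_error")
  n <- length(x)
  if (scale > n)
    stop_spo2(sprintf("scale (%d) exceeds series length (%d)", scale, n),
              c("spo2_degenerate_error", "spo2_data_error"))
  if (scale == 1L) return(x)
  nwin <- n %/% scale
  colMeans(matrix(x[seq_len(nwin * scale)], nrow = scale))
}

# Absolute tolerance actually applied to a series under the given params.
# Under relative_sd this is r * sd of the *scale-1* series; multiscale
# analysis reuses the same absolute value at every scale.
abs_tolerance <- function(x, params) {
  if (params$tolerance_mode == "absolute") return(params$tolerance_factor)
  s <- stats::sd(x)          # denominator n - 1; 0 for a constant series
  params$tolerance_factor * s
}

# Template-pair match counts. B: unordered pairs of m-length templates with
# Chebyshev distance <= t; A: same for (m+1)-length templates; both over
# start positions 1..N-m. Vectorised over pairwise outer differences; memory
# is O((N-m)^2) logicals, fine for the 8-20 min 1 Hz segments this package
# targets.
sampen_counts <- function(x, m, t) {
  n <- length(x) - m
  sim <- matrix(TRUE, n, n)
  for (k in seq_len(m)) {
    xi <- x[(k):(n + k - 1L)]
    sim <- sim & (abs(outer(xi, xi, "-")) <= t)
  }
  B <- (sum(sim) - n) / 2
  xi <- x[(m + 1L):(n + m)]
  sim <- sim & (abs(outer(xi, xi, "-")) <= t)
  A <- (sum(sim) - n) / 2
  c(A = A, B = B)
}

#' Sample entropy of a series
#'
#' Computes SampEn(m, r) with Chebyshev template distance, self-matches
#' excluded and each pair counted once. When no m-length pair matches
#' (`B = 0`) or no (m+1)-length pair matches (`A = 0`) the entropy is
#' undefined and returned as `NA` with a reason code rather than an error or
#' a plug-in correction; downstream analysis excludes such subjects with a
#' logged warning.
#'
#' A constant series has SD 0, hence tolerance 0 under the relative mode, but
#' distance-0 matches still count, so SampEn is exactly 0 (-ln 1), not an
#' error.
#'
#' @param x numeric vector or [oximetry_segment()]; needs at least
#'   `embed_dim + 2` samples.
#' @param params an [entropy_params()] bundle.
#' @return An object of class `"sampen_result"`: `sampen` (or `NA`), match
#'   counts `A` and `B`, `tolerance_used`, and `reason` (`NA` when defined).
#' @export
sample_entropy <- function(x, params = entropy_params()) {
  x <- seg_values(x)
  stopifnot(inherits(params, "entropy_params"))
  m <- params$embed_dim
  if (length(x) < m + 2L)
    stop_spo2(sprintf("series too short for SampEn: need >= %d samples, got %d",
                      m + 2L, length(x)),
              c("spo2_degenerate_error", "spo2_data_error"))
  t <- abs_tolerance(x, params)
  cnt <- sampen_counts(x, m, t)
  res <- list(sampen = NA_real_, A = cnt[["A"]], B = cnt[["B"]],
              tolerance_used = t, reason = NA_character_)
  if (cnt[["B"]] == 0) {
    res$reason <- "no_m_matches"
  } else if (cnt[["A"]] == 0) {
    res$reason <- "no_m1_matches"
  } else {
    res$sampen <- -log(cnt[["A"]] / cnt[["B"]])
  }
  structure(res, class = "sampen_result")
}

#' @export
print.sampen_result <- function(x, ...) {
  if (is.na(x$sampen)) {
    cat(sprintf("<sampen_result> undefined (%s); A = %g, B = %g, t = %g\n",
                x$reason, x$A, x$B, x$tolerance_used))
  } else {
    cat(sprintf("<sampen_result> SampEn = %.4f (A = %g, B = %g, t = %g)\n",
                x$sampen, x$A, x$B, x$tolerance_used))
  }
  invisible(x)
}

#' Multiscale entropy profile
#'
#' Computes SampEn on coarse-grained versions of the series for scales
#' 1..`max_scale`, using ONE absolute tolerance fixed from the original
#' scale-1 series (the standard multiscale convention), and averages the
#' defined per-scale values into an overall complexity measure. Scales whose
#' coarse-grained series is too short, or that yield no template matches,
#' appear as undefined entries with a reason -- they do not raise errors as
#' long as scale 1 itself is computable.
#'
#' @param x numeric vector or [oximetry_segment()].
#' @param params an [entropy_params()] bundle.
#' @return An object of class `"entropy_profile"`: `sampen` (the scale-1
#'   value, the quantity used for parenclitic deviation), a `per_scale`
#'   data frame (`scale`, `sampen`, `n_eff`, `reason`), `mse_mean`, and
#'   `tolerance_used`.
#' @export
multiscale_entropy <- function(x, params = entropy_params()) {
  x <- seg_values(x)
  stopifnot(inherits(params, "entropy_params"))
  m <- params$embed_dim
  if (length(x) < m + 2L)
    stop_spo2(sprintf("series too short for SampEn: need >= %d samples, got %d",
                      m + 2L, length(x)),
              c("spo2_degenerate_error", "spo2_data_error"))
  t <- abs_tolerance(x, params)
  scales <- seq_len(params$max_scale)
  per <- lapply(scales, function(tau) {
    n_eff <- length(x) %/% tau
    if (n_eff < m + 2L)
      return(data.frame(scale = tau, sampen = NA_real_, n_eff = n_eff,
                        reason = "too_short", stringsAsFactors = FALSE))
    cg <- coarse_grain(x, tau)
    cnt <- sampen_counts(cg, m, t)
    if (cnt[["B"]] == 0)
      return(data.frame(scale = tau, sampen = NA_real_, n_eff = n_eff,
                        reason = "no_m_matches", stringsAsFactors = FALSE))
    if (cnt[["A"]] == 0)
      return(data.frame(scale = tau, sampen = NA_real_, n_eff = n_eff,
                        reason = "no_m1_matches", stringsAsFactors = FALSE))
    data.frame(scale = tau, sampen = -log(cnt[["A"]] / cnt[["B"]]),
               n_eff = n_eff, reason = NA_character_, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  defined <- per$sampen[!is.na(per$sampen)]
  structure(
    list(sampen = per$sampen[per$scale == 1L],
         per_scale = per,
         mse_mean = if (length(defined)) mean(defined) else NA_real_,
         tolerance_used = t,
         params = params),
    class = "entropy_profile"
  )
}

#' @export
print.entropy_profile <- function(x, ...) {
  cat(sprintf("<entropy_profile> scale-1 SampEn = %s, MSE mean over %d defined scale(s) = %s (t = %g)\n",
              format(x$sampen, digits = 4),
              sum(!is.na(x$per_scale$sampen)),
              format(x$mse_mean, digits = 4), x$tolerance_used))
  invisible(x)
}

#' Batch entropy features for a list of segments
#'
#' Computes mean SpO2 plus the full entropy profile for each segment and
#' returns one row per segment, wide per-scale columns included, in a form
#' that round-trips through CSV.
#'
#' @param segments a list of [oximetry_segment()] objects.
#' @param params an [entropy_params()] bundle.
#' @return A data frame with columns `subject_id`, `group`, `n_samples`,
#'   `mean_spo2`, `sampen`, `mse_mean`, `sampen_scale1` ...
#'   `sampen_scale<max_scale>`, `tolerance_used`.
#' @export
entropy_features <- function(segments, params = entropy_params()) {
  stopifnot(is.list(segments), length(segments) >= 1L)
  rows <- lapply(segments, function(seg) {
    stopifnot(inherits(seg, "oximetry_segment"))
    prof <- multiscale_entropy(seg, params)
    row <- data.frame(
      subject_id = seg$subject_id,
      group = seg$group_label,
      n_samples = length(seg$values),
      mean_spo2 = mean(seg$values),
      sampen = prof$sampen,
      mse_mean = prof$mse_mean,
      tolerance_used = prof$tolerance_used,
      stringsAsFactors = FALSE
    )
    wide <- as.data.frame(as.list(stats::setNames(
      prof$per_scale$sampen, paste0("sampen_scale", prof$per_scale$scale))))
    cbind(row, wide)
  })
  do.call(rbind, rows)
}
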