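# Synthetic data: graded-hypoxia reference populations, MIX-style SpO2
# signals with tunable irregularity, and ICU-style cohorts with planted
# deviation structure and survival outcomes.
#
# The signal generator is a MIX-style process: a slow, small-amplitude
# sinusoid around the target mean (the deterministic, low-entropy limit) in
# which each sample is independently replaced, with probability p, by
# uniform noise centred on the same mean. One parameter (p) then maps
# near-monotonically onto SampEn over a wide range, which makes entropy
# calibration a one-dimensional inversion. Amplitudes are capped so signals
# stay within the physiological band (and never leave [0, 100]).

# Evaluate code without disturbing the caller's RNG stream.
preserve_rng <- function(code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

#' Graded-hypoxia exposure protocol
#'
#' Describes the reference experiment the generator emulates: healthy
#' subjects exposed to stepwise-decreasing inspired oxygen, with the final
#' minutes of each exposure analysed. Defaults follow the standard chamber
#' protocol: FiO2 levels 21, 17, 14.5 and 12 percent, 12 subjects per level
#' except 11 at the most severe level, 8-min (480 s) analysis segments.
#'
#' @param fio2_levels strictly decreasing FiO2 percentages.
#' @param n_subjects subjects per level (recycled to the number of levels).
#' @param exposure_duration_s analysed segment length per level, in seconds.
#' @param seed integer seed controlling all randomness of the population.
#' @return An object of class `"hypoxia_protocol"`.
#' @export
hypoxia_protocol <- function(fio2_levels = c(21, 17, 14.5, 12),
                             n_subjects = c(12, 12, 12, 11),
                             exposure_duration_s = 480, seed = 1L) {
  if (length(fio2_levels) < 2L || any(diff(fio2_levels) >= 0))
    stop_spo2("fio2_levels must be strictly decreasing", "spo2_config_error")
  n_subjects <- rep_len(as.integer(n_subjects), length(fio2_levels))
  if (any(n_subjects < 1L))
    stop_spo2("n_subjects must be >= 1 per level", "spo2_config_error")
  if (!is_count(exposure_duration_s) || exposure_duration_s < 60)
    stop_spo2("exposure_duration_s must be >= 60 s", "spo2_config_error")
  structure(
    list(fio2_levels = as.numeric(fio2_levels), n_subjects = n_subjects,
         exposure_duration_s = as.integer(exposure_duration_s),
         seed = as.integer(seed)),
    class = "hypoxia_protocol"
  )
}

#' Generate a MIX-style synthetic SpO2 signal
#'
#' Baseline: a slow sinusoid of small amplitude around `target_mean`. With
#' probability `p`, each sample is independently replaced by uniform noise of
#' amplitude `noise_amp` centred on the target mean. `p = 0` gives a
#' deterministic quasi-periodic signal with SampEn near 0; `p = 1` gives
#' white noise. Amplitudes are automatically reduced near the saturation
#' ceiling so the realised mean stays within 0.5\% of the target, and values
#' are clipped to \[0, 100\]. With `quantize = TRUE` values are rounded to
#' integer percent (the typical bedside-monitor export dialect).
#'
#' @param target_mean target mean SpO2 in percent, in (50, 100].
#' @param p replacement probability in \[0, 1\] (the irregularity dial).
#' @param duration_s signal length in seconds (>= 30).
#' @param seed optional integer seed (bit-reproducible output given a seed).
#' @param quantize round to integer percent.
#' @param noise_amp half-width of the replacement noise, percent.
#' @param sine_amp baseline sinusoid amplitude, percent.
#' @param sine_period_s baseline sinusoid period, seconds.
#' @param subject_id,group_label metadata for the resulting segment.
#' @return An [oximetry_segment()].
#' @export
gen_spo2_signal <- function(target_mean, p, duration_s, seed = NULL,
                            quantize = FALSE, noise_amp = 3, sine_amp = 1.5,
                            sine_period_s = 240, subject_id = "synthetic",
                            group_label = "synthetic") {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop_spo2("p must lie in [0, 1]", "spo2_config_error")
  if (!is.numeric(target_mean) || length(target_mean) != 1L ||
      target_mean <= 50 || target_mean > 100)
    stop_spo2("target_mean must lie in (50, 100] percent", "spo2_config_error")
  if (!is_count(duration_s) || duration_s < 30)
    stop_spo2("duration_s must be >= 30 s",
              c("spo2_degenerate_error", "spo2_data_error"))
  if (!is.null(seed)) set.seed(as.integer(seed))

  # keep the signal inside [70, 100] and symmetric about the target so
  # clipping cannot bias the realised mean
  headroom <- max(0, min(noise_amp, 100 - target_mean, target_mean - 70))
  s_amp <- min(sine_amp, headroom)

  t <- seq_len(duration_s) - 1L
  phase <- stats::runif(1L, 0, 2 * pi)
  x <- target_mean + s_amp * sin(2 * pi * t / sine_period_s + phase)
  repl <- stats::runif(duration_s) < p
  if (any(repl))
    x[repl] <- stats::runif(sum(repl), target_mean - headroom,
                            target_mean + headroom)
  x <- pmin(100, pmax(0, x))
  if (quantize) x <- round(x)
  oximetry_segment(x, subject_id = subject_id, group_label = group_label,
                   start_offset = 0)
}

# Cache for calibration maps (keyed by everything that shapes the map).
.cal_cache <- new.env(parent = emptyenv())

#' Monte-Carlo calibration map from irregularity to expected SampEn
#'
#' Probes a fixed grid of replacement probabilities `p`, generating `n_rep`
#' signals per probe and averaging their SampEn, to obtain a monotone map
#' from `p` to expected entropy at the given duration and parameters. The
#' probe seeds are fixed internally, so the map is deterministic, cacheable
#' across calls, and independent of the caller's RNG stream. The grid is
#' denser at small `p`, where the entropy response is steepest.
#'
#' @param params an [entropy_params()] bundle.
#' @param duration_s signal duration the map is calibrated for.
#' @param quantize whether probe signals are integer-quantised.
#' @param target_mean probe signal mean; under the relative-SD tolerance the
#'   map is essentially mean-invariant, so one probe mean suffices.
#' @param n_rep Monte-Carlo replicates per probe.
#' @param p_grid probe grid over \[0, 1\].
#' @param map_seed base seed of the internal probe streams.
#' @return An object of class `"entropy_calibration"`: data frame `map`
#'   (`p`, `mean_sampen`, `mono_sampen`) plus the settings.
#' @export
entropy_calibration_map <- function(params = entropy_params(),
                                    duration_s = 1200, quantize = FALSE,
                                    target_mean = 95, n_rep = 20,
                                    p_grid = c(0, 0.01, 0.02, 0.035, 0.05,
                                               0.075, 0.1, 0.15, 0.2, 0.3,
                                               0.45, 0.6, 0.8, 1),
                                    map_seed = 760813L) {
  key <- paste(params$embed_dim, params$tolerance_factor,
               params$tolerance_mode, duration_s, quantize, target_mean,
               n_rep, paste(p_grid, collapse = ","), map_seed, sep = "|")
  if (!is.null(.cal_cache[[key]])) return(.cal_cache[[key]])
  map <- preserve_rng({
    means <- vapply(seq_along(p_grid), function(i) {
      vals <- vapply(seq_len(n_rep), function(r) {
        sig <- gen_spo2_signal(target_mean, p_grid[i], duration_s,
                               seed = map_seed + 1000L * i + r,
                               quantize = quantize)
        sample_entropy(sig, params)$sampen
      }, numeric(1))
      mean(vals, na.rm = TRUE)
    }, numeric(1))
    data.frame(p = p_grid, mean_sampen = means,
               mono_sampen = cummax(means))
  })
  obj <- structure(
    list(map = map, params = params, duration_s = duration_s,
         quantize = quantize, target_mean = target_mean, n_rep = n_rep),
    class = "entropy_calibration"
  )
  .cal_cache[[key]] <- obj
  obj
}

#' Invert the calibration map: entropy target to irregularity
#'
#' Monotone lookup of the replacement probability `p` whose expected SampEn
#' (under the calibration map's Monte-Carlo estimate) matches
#' `target_sampen`, by linear interpolation on the monotone map. Targets
#' outside the achievable range raise a range error reporting the achievable
#' interval.
#'
#' @param target_sampen desired expected SampEn.
#' @param map an [entropy_calibration_map()]; built (or fetched from cache)
#'   from the remaining arguments when `NULL`.
#' @param params,duration_s,quantize forwarded to
#'   [entropy_calibration_map()] when `map` is `NULL`.
#' @return The replacement probability `p` in \[0, 1\].
#' @export
calibrate_irregularity <- function(target_sampen, map = NULL,
                                   params = entropy_params(),
                                   duration_s = 1200, quantize = FALSE) {
  if (is.null(map))
    map <- entropy_calibration_map(params, duration_s, quantize)
  stopifnot(inherits(map, "entropy_calibration"))
  m <- map$map
  lo <- min(m$mono_sampen)
  hi <- max(m$mono_sampen)
  if (!is.finite(target_sampen) || target_sampen < lo - 1e-9 ||
      target_sampen > hi + 1e-9)
    stop_spo2(sprintf("target SampEn %.4g outside achievable range [%.4g, %.4g]",
                      target_sampen, lo, hi),
              c("spo2_range_error", "spo2_data_error"),
              achievable = c(lo, hi))
  target_sampen <- min(max(target_sampen, lo), hi)
  keep <- !duplicated(m$mono_sampen)   # flat stretches break interpolation
  stats::approx(m$mono_sampen[keep], m$p[keep], xout = target_sampen,
                rule = 2)$y
}

# Generate one signal whose *realised* SampEn matches the target: start from
# the calibration-map inversion, then refine p against the actual seeded
# realisation (deterministic given the seed) using the map's local slope.
# Entropy targets at the map floor (p = 0) stop refining once p pins at 0.
gen_signal_with_entropy <- function(target_mean, target_sampen, seed, map,
                                    params, duration_s, quantize,
                                    subject_id = "synthetic", tol = 0.004,
                                    max_iter = 8L) {
  m <- map$map
  keep <- !duplicated(m$mono_sampen)
  local_slope <- function(p) {
    i <- findInterval(p, m$p, all.inside = TRUE)
    max((m$mono_sampen[i + 1L] - m$mono_sampen[i]) / (m$p[i + 1L] - m$p[i]),
        0.05)
  }
  p <- calibrate_irregularity(target_sampen, map = map)
  sig <- NULL
  y <- NA_real_
  for (iter in seq_len(max_iter)) {
    sig <- gen_spo2_signal(target_mean, p, duration_s, seed = seed,
                           quantize = quantize, subject_id = subject_id,
                           group_label = "synthetic")
    y <- sample_entropy(sig, params)$sampen
    if (is.na(y)) { p <- min(1, p + 0.02); next }
    if (abs(y - target_sampen) <= tol) break
    p_new <- p - (y - target_sampen) / local_slope(p)
    p_new <- min(1, max(0, p_new))
    if (p_new == p) break   # pinned at the achievable boundary
    p <- p_new
  }
  list(signal = sig, sampen = y, p = p)
}

# Internal dose-response of the emulated chamber protocol: level mean SpO2 by
# FiO2 (interpolated for non-default levels) and an exactly linear entropy
# target so the emulated reference is linear by construction.
REF_DOSE <- data.frame(fio2 = c(12, 14.5, 17, 21),
                       mean_spo2 = c(84.5, 90.5, 94.5, 97.7))
REF_TRUE_SLOPE <- -0.0274
REF_TRUE_INTERCEPT <- 2.80

ref_target_mean <- function(fio2) {
  stats::approx(REF_DOSE$fio2, REF_DOSE$mean_spo2, xout = fio2, rule = 2)$y
}

ref_target_sampen <- function(mean_spo2) {
  REF_TRUE_INTERCEPT + REF_TRUE_SLOPE * mean_spo2
}

#' Generate a healthy graded-hypoxia reference population
#'
#' Emulates the reference experiment statistically: for each FiO2 level,
#' per-subject signals are generated whose target mean decreases with FiO2
#' (a saturating dose-response) and whose target entropy increases as the
#' mean falls, following an internal linear mean-entropy relationship. Each
#' subject's irregularity is calibrated via the entropy calibration map, and
#' the returned per-subject `(fio2, mean_spo2, sampen)` points are computed
#' from the generated signals through the complexity module -- so the table
#' reflects realised, not planted, values.
#'
#' @param protocol a [hypoxia_protocol()].
#' @param params an [entropy_params()] bundle.
#' @param quantize integer-quantise the generated signals.
#' @param mean_jitter_sd,sampen_jitter_sd between-subject SD of the target
#'   mean (percent) and target entropy at each level.
#' @return A list: `table` (per-subject points), `signals` (list of
#'   [oximetry_segment()]), `protocol`, and `true_line` (the generating
#'   slope/intercept).
#' @export
gen_reference_population <- function(protocol = hypoxia_protocol(),
                                     params = entropy_params(),
                                     quantize = FALSE,
                                     mean_jitter_sd = 0.5,
                                     sampen_jitter_sd = 0.015) {
  stopifnot(inherits(protocol, "hypoxia_protocol"))
  map <- entropy_calibration_map(params, protocol$exposure_duration_s,
                                 quantize)
  lo <- min(map$map$mono_sampen)
  hi <- max(map$map$mono_sampen)

  set.seed(protocol$seed)
  n_total <- sum(protocol$n_subjects)
  sig_seeds <- sample.int(2^30, n_total)

  rows <- list()
  signals <- list()
  k <- 0L
  for (li in seq_along(protocol$fio2_levels)) {
    fio2 <- protocol$fio2_levels[li]
    level_mean <- ref_target_mean(fio2)
    for (si in seq_len(protocol$n_subjects[li])) {
      k <- k + 1L
      subj_mean <- min(99, max(75, level_mean + stats::rnorm(1, 0, mean_jitter_sd)))
      subj_y <- ref_target_sampen(subj_mean) +
        stats::rnorm(1, 0, sampen_jitter_sd)
      subj_y <- min(max(subj_y, lo), hi)
      p <- calibrate_irregularity(subj_y, map = map)
      id <- sprintf("ref%02d_fio2_%g", si, fio2)
      sig <- gen_spo2_signal(subj_mean, p, protocol$exposure_duration_s,
                             seed = sig_seeds[k], quantize = quantize,
                             subject_id = id, group_label = "healthy")
      ent <- sample_entropy(sig, params)
      rows[[k]] <- data.frame(fio2 = fio2, subject_id = id,
                              mean_spo2 = mean(sig$values),
                              sampen = ent$sampen,
                              stringsAsFactors = FALSE)
      signals[[k]] <- sig
    }
  }
  list(table = do.call(rbind, rows), signals = signals, protocol = protocol,
       true_line = list(slope = REF_TRUE_SLOPE,
                        intercept = REF_TRUE_INTERCEPT))
}

#' Specification of a synthetic patient cohort
#'
#' Defaults emulate a sepsis-like ICU cohort: 164 subjects with a 130/34
#' survivor/non-survivor split, deviation strata centred at 0.0391 (SD
#' 0.0827) among survivors and 0.113 (SD 0.126) among non-survivors, a
#' 30-day horizon, and 20-min signals. Two outcome mechanisms are available:
#' if `beta` is `NULL`, survival status is stratified (fixed event count,
#' event times uniform over the horizon) and delta is drawn per stratum; if
#' `beta` is a named vector of log-hazards per SD, delta is drawn from the
#' first stratum's distribution for everyone and survival times are drawn
#' from an exponential hazard `baseline_rate * exp(sum(beta * z))` over
#' z-scored covariates, censored at the horizon.
#'
#' @param n number of subjects (>= 2).
#' @param seed integer seed.
#' @param delta_mean,delta_sd length-2 numeric: planted delta distribution
#'   for (survivor, non-survivor) strata; only the first entry is used in
#'   hazard mode.
#' @param n_events number of non-survivors in stratified mode; defaults to
#'   the same event fraction as the emulated cohort (34/164).
#' @param beta named log-hazard-per-SD vector (names among `delta`, `sofa`,
#'   `meld`, `mech_vent`, `mean_spo2`), or `NULL` for stratified mode.
#' @param baseline_rate baseline hazard, events/day (> 0).
#' @param horizon follow-up cap in days.
#' @param signal_duration_s signal length for `signal_level` mode.
#' @param mode `"feature_level"` (exact algebraic features) or
#'   `"signal_level"` (features recomputed from generated signals).
#' @param x_mean,x_sd mean-SpO2 distribution of the cohort.
#' @param quantize integer-quantise generated signals (signal mode).
#' @param mech_vent_prob mechanical-ventilation probability.
#' @return An object of class `"synthetic_cohort_spec"`.
#' @export
synthetic_cohort_spec <- function(n = 164, seed = 1L,
                                  delta_mean = c(0.0391, 0.113),
                                  delta_sd = c(0.0827, 0.126),
                                  n_events = NULL, beta = NULL,
                                  baseline_rate = 0.02, horizon = 30,
                                  signal_duration_s = 1200,
                                  mode = c("feature_level", "signal_level"),
                                  x_mean = 97, x_sd = 3, quantize = FALSE,
                                  mech_vent_prob = 0.4) {
  mode <- match.arg(mode)
  if (!is_count(n) || n < 2)
    stop_spo2("n must be >= 2", "spo2_config_error")
  if (!is.numeric(baseline_rate) || baseline_rate <= 0)
    stop_spo2("baseline_rate must be > 0", "spo2_config_error")
  if (!is.numeric(horizon) || horizon <= 0)
    stop_spo2("horizon must be > 0", "spo2_config_error")
  if (is.null(n_events))
    n_events <- max(1L, round(n * 34 / 164))   # paper-like event fraction
  if (is.null(beta) && (!is_count(n_events) || n_events >= n))
    stop_spo2("stratified mode needs 1 <= n_events < n", "spo2_config_error")
  if (!is.null(beta) && is.null(names(beta)))
    stop_spo2("beta must be a named vector", "spo2_config_error")
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         delta_mean = rep_len(delta_mean, 2L),
         delta_sd = rep_len(delta_sd, 2L),
         n_events = as.integer(n_events), beta = beta,
         baseline_rate = baseline_rate, horizon = horizon,
         signal_duration_s = as.integer(signal_duration_s), mode = mode,
         x_mean = x_mean, x_sd = x_sd, quantize = isTRUE(quantize),
         mech_vent_prob = mech_vent_prob),
    class = "synthetic_cohort_spec"
  )
}

#' Generate a synthetic patient cohort with planted deviation structure
#'
#' In `feature_level` mode, each subject's entropy is set algebraically from
#' the planted deviation,
#' `y = (slope * x + intercept) - delta * sqrt(slope^2 + 1)`, so
#' [batch_delta()] recovers the planted values exactly (a round-trip
#' identity). In `signal_level` mode a signal is additionally synthesised
#' per subject, with irregularity calibrated to the target entropy, and
#' `(mean_spo2, sampen, delta)` are recomputed from the signal; entropy
#' targets outside the calibration map's achievable range fall back to the
#' nearest achievable value, flagged per subject in a `delta_fallback`
#' column with the total in the `n_fallback` attribute.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @param line a [fit_reference()] reference line.
#' @param params an [entropy_params()] bundle.
#' @return A cohort data frame (`subject_id`, `group`, `time_days`, `event`,
#'   `mean_spo2`, `sampen`, `delta`, `sofa`, `meld`, `mech_vent`,
#'   `delta_planted`). In signal mode the generated segments are attached as
#'   the `signals` attribute.
#' @export
gen_patient_cohort <- function(spec, line, params = entropy_params()) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  if (!is.list(line) || !is.finite(line$slope) || !is.finite(line$intercept))
    stop_spo2("a fitted reference line is required", "spo2_config_error")

  map <- NULL
  if (spec$mode == "signal_level")
    map <- entropy_calibration_map(params, spec$signal_duration_s,
                                   spec$quantize)

  set.seed(spec$seed)
  n <- spec$n
  x <- stats::rnorm(n, spec$x_mean, spec$x_sd)
  x <- pmin(97.5, pmax(80, x))
  sofa <- pmax(0, round(stats::rnorm(n, 5, 3)))
  meld <- pmax(6, round(stats::rnorm(n, 15, 8)))
  mech_vent <- stats::rbinom(n, 1, spec$mech_vent_prob)

  if (is.null(spec$beta)) {
    # stratified outcomes: fixed event count, delta drawn per stratum
    event <- integer(n)
    event[sample.int(n, spec$n_events)] <- 1L
    delta <- ifelse(event == 1L,
                    stats::rnorm(n, spec$delta_mean[2], spec$delta_sd[2]),
                    stats::rnorm(n, spec$delta_mean[1], spec$delta_sd[1]))
    time <- ifelse(event == 1L,
                   stats::runif(n, 0.5, spec$horizon),
                   spec$horizon)
  } else {
    delta <- stats::rnorm(n, spec$delta_mean[1], spec$delta_sd[1])
    covs <- list(delta = delta, sofa = sofa, meld = meld,
                 mech_vent = mech_vent, mean_spo2 = x)
    unknown <- setdiff(names(spec$beta), names(covs))
    if (length(unknown))
      stop_spo2(sprintf("unknown covariate(s) in beta: %s",
                        paste(unknown, collapse = ", ")),
                "spo2_config_error")
    lp <- rep(0, n)
    for (nm in names(spec$beta)) {
      v <- covs[[nm]]
      z <- if (length(unique(v)) > 2L) zscore(v)$z else v
      lp <- lp + spec$beta[[nm]] * z
    }
    tt <- stats::rexp(n, rate = spec$baseline_rate * exp(lp))
    event <- as.integer(tt <= spec$horizon)
    time <- pmin(tt, spec$horizon)
  }

  slope <- line$slope
  y_target <- (slope * x + line$intercept) - delta * sqrt(slope^2 + 1)

  cohort <- data.frame(
    subject_id = sprintf("syn%04d", seq_len(n)),
    group = "synthetic",
    time_days = time, event = event,
    mean_spo2 = x, sampen = y_target,
    sofa = sofa, meld = meld, mech_vent = mech_vent,
    delta_planted = delta,
    stringsAsFactors = FALSE
  )

  n_fallback <- 0L
  signals <- NULL
  if (spec$mode == "signal_level") {
    lo <- min(map$map$mono_sampen)
    hi <- max(map$map$mono_sampen)
    sig_seeds <- sample.int(2^30, n)
    signals <- vector("list", n)
    fallback <- logical(n)
    for (i in seq_len(n)) {
      yt <- y_target[i]
      if (yt < lo || yt > hi) {
        yt <- min(max(yt, lo), hi)
        fallback[i] <- TRUE
        n_fallback <- n_fallback + 1L
      }
      res <- gen_signal_with_entropy(x[i], yt, sig_seeds[i], map, params,
                                     spec$signal_duration_s, spec$quantize,
                                     subject_id = cohort$subject_id[i])
      signals[[i]] <- res$signal
      cohort$mean_spo2[i] <- mean(res$signal$values)
      cohort$sampen[i] <- res$sampen
    }
    cohort$delta_fallback <- fallback
    if (n_fallback > 0)
      message(sprintf("gen_patient_cohort: %d subject(s) fell back to the nearest achievable entropy target",
                      n_fallback))
  }

  cohort$delta <- parenclitic_delta(cohort$mean_spo2, cohort$sampen,
                                    line)$delta
  keep <- c("subject_id", "group", "time_days", "event", "mean_spo2",
            "sampen", "delta", "sofa", "meld", "mech_vent", "delta_planted",
            intersect("delta_fallback", names(cohort)))
  cohort <- cohort[keep]
  attr(cohort, "n_fallback") <- n_fallback
  if (!is.null(signals)) attr(cohort, "signals") <- signals
  cohort
}
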