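test_that("generated signals honour mean, quantisation, bounds and determinism", {
  sig <- gen_spo2_signal(95, 0.3, 600, seed = 1, quantize = TRUE)
  expect_s3_class(sig, "oximetry_segment")
  expect_true(all(sig$values == floor(sig$values)))
  expect_true(all(sig$values >= 0 & sig$values <= 100))

  # realised mean within 0.5% of target for duration >= 480 s
  for (tm in c(85, 92, 97)) {
    s <- gen_spo2_signal(tm, 0.4, 480, seed = 2)
    expect_lt(abs(mean(s$values) - tm) / tm, 0.005)
  }

  # bit-reproducible given a seed
  a <- gen_spo2_signal(94, 0.2, 300, seed = 9)
  b <- gen_spo2_signal(94, 0.2, 300, seed = 9)
  expect_identical(a$values, b$values)
  c <- gen_spo2_signal(94, 0.2, 300, seed = 10)
  expect_false(identical(a$values, c$values))

  # p = 0: deterministic quasi-periodic baseline, SampEn near zero
  flat <- gen_spo2_signal(95, 0, 480, seed = 3)
  expect_lt(sample_entropy(flat)$sampen, 0.1)

  # generated signals pass QC at their own duration
  path <- tempfile(fileext = ".csv")
  write_segment_csv(sig, path)
  expect_true(qc_record(read_spo2_csv(path), 600)$passed)

  expect_error(gen_spo2_signal(95, 1.2, 300), class = "spo2_config_error")
  expect_error(gen_spo2_signal(45, 0.2, 300), class = "spo2_config_error")
  expect_error(gen_spo2_signal(95, 0.2, 10), class = "spo2_degenerate_error")
})

test_that("the calibration map is monotone and its inversion closes the loop", {
  map <- entropy_calibration_map(duration_s = 480)
  expect_true(all(diff(map$map$mono_sampen) >= 0))
  # the map spans from the deterministic floor well into noise territory
  expect_lt(min(map$map$mono_sampen), 0.1)
  expect_gt(max(map$map$mono_sampen), 1.5)

  # boundary: targeting the p = 0 entropy returns p ~ 0
  expect_lt(calibrate_irregularity(min(map$map$mono_sampen) + 1e-6,
                                   map = map), 0.01)

  # monotone in the target
  targets <- c(0.15, 0.3, 0.6, 1.2)
  ps <- vapply(targets, calibrate_irregularity, numeric(1), map = map)
  expect_true(all(diff(ps) > 0))

  # closed loop: fresh signals at the calibrated p average near the target
  target <- 0.4
  p <- calibrate_irregularity(target, map = map)
  got <- mean(vapply(1:40, function(s)
    sample_entropy(gen_spo2_signal(95, p, 480, seed = 4000 + s))$sampen,
    numeric(1)))
  expect_lt(abs(got - target) / target, 0.1)

  expect_error(calibrate_irregularity(50, map = map),
               class = "spo2_range_error")
})

test_that("the synthetic reference population reproduces the inverse relationship", {
  ref <- gen_reference_population(hypoxia_protocol(seed = 101))
  expect_identical(nrow(ref$table), 47L)    # 12+12+12+11
  expect_identical(sort(unique(ref$table$fio2)), c(12, 14.5, 17, 21))

  line <- fit_reference(ref$table)
  expect_lt(line$slope, 0)
  expect_gt(line$r_squared, 0.9)

  # level means decrease with hypoxia severity; entropy increases
  lm <- aggregate(cbind(mean_spo2, sampen) ~ fio2, ref$table, mean)
  expect_true(all(diff(lm$mean_spo2) > 0))  # fio2 ascending -> mean rising
  expect_true(all(diff(lm$sampen) < 0))

  # one subject per level gives exactly one row per level
  tiny <- gen_reference_population(
    hypoxia_protocol(n_subjects = 1, seed = 5))
  expect_identical(nrow(tiny$table), 4L)

  # reproducible given the protocol seed
  again <- gen_reference_population(hypoxia_protocol(seed = 101))
  expect_identical(ref$table, again$table)

  expect_error(hypoxia_protocol(fio2_levels = c(12, 17)),
               class = "spo2_config_error")
})

test_that("feature-level cohorts invert delta exactly and respect the outcome model", {
  line <- structure(list(slope = -0.027, intercept = 2.8, r_squared = 1,
                         n_points = 4L, fit_mode = "group_mean"),
                    class = "reference_line")

  co <- gen_patient_cohort(synthetic_cohort_spec(n = 164, seed = 11), line)
  expect_identical(nrow(co), 164L)
  expect_identical(sum(co$event), 34L)
  expect_lt(max(abs(co$delta - co$delta_planted)), 1e-9)
  expect_true(all(co$time_days > 0 & co$time_days <= 30))
  expect_true(all(co$time_days[co$event == 0] == 30))

  # recomputing via batch_delta recovers the planted values too
  bd <- batch_delta(co, line)
  expect_lt(max(abs(bd$delta - co$delta_planted)), 1e-9)

  # bit-reproducible
  again <- gen_patient_cohort(synthetic_cohort_spec(n = 164, seed = 11), line)
  expect_identical(co, again)

  # hazard mode: exponential times censored at the horizon
  hz <- gen_patient_cohort(
    synthetic_cohort_spec(n = 400, seed = 12, beta = c(delta = 0.6),
                          baseline_rate = 0.02), line)
  expect_true(all(hz$time_days > 0 & hz$time_days <= 30))
  expect_true(all(hz$event %in% 0:1))
  expect_gt(sum(hz$event), 20)
  # planted positive log-hazard: events should show larger delta on average
  expect_gt(mean(hz$delta[hz$event == 1]), mean(hz$delta[hz$event == 0]))

  expect_error(synthetic_cohort_spec(n = 1), class = "spo2_config_error")
  expect_error(synthetic_cohort_spec(beta = c(0.5)),
               class = "spo2_config_error")
  expect_error(gen_patient_cohort(
    synthetic_cohort_spec(n = 10, beta = c(nope = 1)), line),
    class = "spo2_config_error")
})
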