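test_that("reference fit recovers exact lines and satisfies OLS identities", {
  pts <- data.frame(fio2 = c(21, 17, 14.5),
                    mean_spo2 = c(100, 95, 90), sampen = c(0.10, 0.20, 0.30))
  line <- fit_reference(pts)
  expect_equal(line$slope, -0.02)
  expect_equal(line$intercept, 2.10)
  expect_equal(line$r_squared, 1)
  expect_identical(line$n_points, 3L)

  # noiseless y = a*x + b is recovered exactly for any a, b
  x <- c(84, 90, 94, 98)
  for (ab in list(c(-0.03, 3), c(0.5, -10), c(2, 0))) {
    noiseless <- data.frame(fio2 = 1:4, mean_spo2 = x,
                            sampen = ab[1] * x + ab[2])
    ln <- fit_reference(noiseless)
    expect_equal(ln$slope, ab[1])
    expect_equal(ln$intercept, ab[2])
    expect_equal(ln$r_squared, 1)
  }

  # OLS identities on noisy data: residuals sum to zero, uncorrelated with x
  set.seed(31)
  noisy <- data.frame(fio2 = seq_len(12),
                      mean_spo2 = runif(12, 84, 98))
  noisy$sampen <- 2.8 - 0.027 * noisy$mean_spo2 + rnorm(12, 0, 0.02)
  ln <- fit_reference(noisy, fit_mode = "per_subject")
  res <- noisy$sampen - (ln$intercept + ln$slope * noisy$mean_spo2)
  expect_lt(abs(sum(res)), 1e-10)
  expect_lt(abs(sum(res * (noisy$mean_spo2 - mean(noisy$mean_spo2)))), 1e-10)

  # equality with the closed-form normal-equation oracle
  want <- oracle_ols(noisy$mean_spo2, noisy$sampen)
  expect_equal(ln$slope, unname(want["slope"]), tolerance = 1e-12)
  expect_equal(ln$intercept, unname(want["intercept"]), tolerance = 1e-12)
})

test_that("group-mean fit averages within FiO2 levels before regressing", {
  pts <- data.frame(fio2 = rep(c(21, 17), each = 3),
                    mean_spo2 = c(97, 98, 99, 93, 94, 95),
                    sampen = c(0.1, 0.12, 0.14, 0.2, 0.22, 0.24))
  gm <- fit_reference(pts, fit_mode = "group_mean")
  # level means: (98, 0.12) and (94, 0.22)
  expect_identical(gm$n_points, 2L)
  expect_equal(gm$slope, (0.22 - 0.12) / (94 - 98))
  ps <- fit_reference(pts, fit_mode = "per_subject")
  expect_identical(ps$n_points, 6L)
})

test_that("degenerate reference inputs raise classed errors", {
  expect_error(fit_reference(data.frame(mean_spo2 = 1, sampen = 1),
                             fit_mode = "per_subject"),
               class = "spo2_degenerate_error")
  expect_error(fit_reference(data.frame(fio2 = 1:3, mean_spo2 = rep(95, 3),
                                        sampen = c(0.1, 0.2, 0.3))),
               class = "spo2_nonidentifiable_error")
  expect_error(fit_reference(data.frame(a = 1)), class = "spo2_schema_error")
})

test_that("delta has the documented geometry: sign, magnitude, linearity", {
  line <- list(slope = -1, intercept = 0)
  expect_equal(parenclitic_delta(0, -1, line)$delta, 1 / sqrt(2))

  # a point on the line has delta 0
  ln2 <- list(slope = -0.027, intercept = 2.8)
  x <- 93.7
  expect_equal(parenclitic_delta(x, ln2$slope * x + ln2$intercept, ln2)$delta, 0)

  # below the line (entropy deficit) positive, above negative
  expect_gt(parenclitic_delta(x, ln2$slope * x + ln2$intercept - 0.1, ln2)$delta, 0)
  expect_lt(parenclitic_delta(x, ln2$slope * x + ln2$intercept + 0.1, ln2)$delta, 0)

  # |delta| equals the projection-oracle point-to-line distance
  set.seed(41)
  for (i in 1:200) {
    m <- runif(1, -2, 2); b <- runif(1, -5, 5)
    x0 <- runif(1, 80, 100); y0 <- runif(1, -1, 2)
    d <- parenclitic_delta(x0, y0, list(slope = m, intercept = b))$delta
    expect_equal(abs(d), oracle_point_line_dist(x0, y0, m, b),
                 tolerance = 1e-12)
  }

  # linear in y with coefficient -1/sqrt(m^2+1), in x with m/sqrt(m^2+1)
  m <- -0.5; b <- 1.2; ln3 <- list(slope = m, intercept = b)
  d0 <- parenclitic_delta(90, 0.3, ln3)$delta
  expect_equal(parenclitic_delta(90, 0.3 + 2, ln3)$delta - d0,
               -2 / sqrt(m^2 + 1))
  expect_equal(parenclitic_delta(90 + 3, 0.3, ln3)$delta - d0,
               3 * m / sqrt(m^2 + 1))
})

test_that("deltas of fitted group-mean points sum to zero", {
  set.seed(43)
  pts <- data.frame(fio2 = 1:4, mean_spo2 = c(85, 90, 94, 98),
                    sampen = c(0.5, 0.33, 0.25, 0.1) + rnorm(4, 0, 0.02))
  line <- fit_reference(pts)
  d <- parenclitic_delta(pts$mean_spo2, pts$sampen, line)$delta
  expect_lt(abs(sum(d)), 1e-10)
})

test_that("batch delta flags undefined entropy rows and keeps the rest", {
  line <- list(slope = -0.02, intercept = 2.1)
  tbl <- data.frame(mean_spo2 = c(95, 96, 97),
                    sampen = c(0.2, NA, 0.16))
  out <- suppressMessages(batch_delta(tbl, line))
  expect_identical(sum(is.na(out$delta)), 1L)
  expect_identical(out$delta_flagged, c(FALSE, TRUE, FALSE))
  expect_identical(attr(out, "n_flagged"), 1L)
  # on-line points give all-zero deltas
  on <- data.frame(mean_spo2 = c(90, 95, 100),
                   sampen = 2.1 - 0.02 * c(90, 95, 100))
  expect_equal(batch_delta(on, line)$delta, rep(0, 3))
  expect_error(batch_delta(data.frame(a = 1), line),
               class = "spo2_schema_error")
})

test_that("the reference line serialises to JSON and back", {
  pts <- data.frame(fio2 = c(1, 2), mean_spo2 = c(90, 95),
                    sampen = c(0.3, 0.2))
  line <- fit_reference(pts)
  path <- tempfile(fileext = ".json")
  save_reference_line(line, path)
  back <- load_reference_line(path)
  expect_equal(back$slope, line$slope)
  expect_equal(back$intercept, line$intercept)
  expect_equal(back$r_squared, line$r_squared)
  expect_identical(back$fit_mode, line$fit_mode)
  expect_error(load_reference_line(tempfile()), class = "spo2_config_error")
})
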