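test_that("z-scoring standardises to mean 0 and sample SD 1", {
  z <- zscore(c(1, 2, 3))
  expect_equal(z$z, c(-1, 0, 1))
  expect_equal(z$center, 2)
  expect_equal(z$scale, 1)
  set.seed(51)
  x <- rnorm(40, 10, 7)
  z2 <- zscore(x)
  expect_equal(mean(z2$z), 0)
  expect_equal(sd(z2$z), 1)
  # idempotence on already-standardised input
  expect_equal(zscore(z2$z)$z, z2$z, tolerance = 1e-12)
  expect_error(zscore(rep(3, 5)), class = "spo2_nonidentifiable_error")
  expect_error(zscore(1), class = "spo2_degenerate_error")
})

test_that("pooled t-test matches the closed-form oracle and is antisymmetric", {
  same <- two_group_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  tt <- two_group_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$statistic, -3.674, tolerance = 1e-3)
  expect_equal(tt$df, 4)

  swap <- two_group_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swap$statistic, -tt$statistic)
  expect_equal(swap$p_value, tt$p_value)

  expect_error(two_group_t(1, c(1, 2)), class = "spo2_degenerate_error")
  # Welch switch reported
  expect_identical(two_group_t(c(1, 2, 3), c(4, 5, 9),
                               var_equal = FALSE)$method, "welch")
})

test_that("cox_fit maximises the same partial likelihood as the grid oracle", {
  fixtures <- list(
    data.frame(time_days = c(1, 2, 3, 4, 5, 6),
               event = c(1, 1, 1, 1, 1, 1),
               x = c(1, 0, 1, 0, 1, 0)),
    data.frame(time_days = c(2, 4, 5, 7, 9, 11, 13, 15),
               event = c(1, 0, 1, 1, 0, 1, 1, 0),
               x = c(0.5, -1.2, 2.1, 0.3, -0.7, 1.5, -0.2, 0.9))
  )
  for (d in fixtures) {
    want <- oracle_cox_beta(d$time_days, d$event, d$x)
    for (ties in c("efron", "breslow")) {
      fit <- cox_fit(d, "x", ties = ties)
      expect_equal(fit$coefficients$beta, want, tolerance = 1e-4)
      expect_true(fit$model$converged)
      expect_equal(fit$coefficients$hazard_ratio,
                   exp(fit$coefficients$beta))
      expect_equal(fit$coefficients$ci95_low,
                   exp(fit$coefficients$beta - 1.96 * fit$coefficients$se))
    }
  }
})

test_that("per-SD scaling relates standardized and raw coefficients", {
  set.seed(53)
  n <- 120
  d <- data.frame(x = rnorm(n, 5, 2.5))
  d$time_days <- pmin(rexp(n, 0.05 * exp(0.3 * (d$x - 5))), 30)
  d$event <- as.integer(d$time_days < 30)
  raw <- cox_fit(d, "x")
  std <- cox_fit(d, "x", standardize = TRUE)
  expect_true(std$coefficients$per_sd)
  expect_equal(std$coefficients$beta, raw$coefficients$beta * sd(d$x),
               tolerance = 1e-6)
  # binary covariates are never rescaled
  d$mv <- rbinom(n, 1, 0.4)
  both <- cox_fit(d, c("x", "mv"), standardize = TRUE)
  expect_identical(both$coefficients$per_sd, c(TRUE, FALSE))
})

test_that("degenerate covariate structures are rejected", {
  d <- data.frame(time_days = c(5, 7, 9, 12), event = c(1, 0, 1, 1),
                  x = c(1, 2, 3, 4))
  d$y <- d$x
  expect_error(cox_fit(d, c("x", "y")),
               class = "spo2_nonidentifiable_error")
  d$z <- 3
  expect_error(cox_fit(d, "z"), class = "spo2_nonidentifiable_error")
  d0 <- d
  d0$event <- 0
  expect_error(cox_fit(d0, "x"), class = "spo2_degenerate_error")
  expect_error(cox_fit(d, "missing"), class = "spo2_schema_error")
})

test_that("a covariate unrelated to survival yields null-consistent fits", {
  set.seed(57)
  p_vals <- replicate(60, {
    n <- 150
    d <- data.frame(time_days = pmin(rexp(n, 0.05), 30), x = rnorm(n))
    d$event <- as.integer(d$time_days < 30)
    f <- cox_fit(d, "x")$coefficients
    c(f$beta, f$p_value)
  })
  expect_lt(abs(mean(p_vals[1, ])), 0.05)          # betas centred on zero
  frac_sig <- mean(p_vals[2, ] < 0.05)
  expect_lt(frac_sig, 0.15)                        # ~5% type-I error
})

test_that("the proportional-hazards diagnostic flags planted non-proportionality", {
  set.seed(59)
  # null: proportional hazards hold
  n <- 300
  d <- data.frame(x = rnorm(n))
  d$time_days <- pmin(rexp(n, 0.05 * exp(0.5 * d$x)), 30)
  d$event <- as.integer(d$time_days < 30)
  fit <- cox_fit(d, "x")
  ph <- ph_check(fit)
  expect_identical(ph$term, "x")
  expect_true(is.finite(ph$rho) && abs(ph$rho) <= 1)

  # alternative: effect reverses over time -> strongly non-proportional
  flags <- replicate(10, {
    n <- 500
    x <- rnorm(n)
    # early hazard increases with x, late hazard decreases with x
    t1 <- rexp(n, 0.15 * exp(1.2 * x))
    t2 <- 5 + rexp(n, 0.15 * exp(-1.2 * x))
    tt <- ifelse(t1 <= 5, t1, t2)
    d <- data.frame(x = x, time_days = pmin(tt, 30))
    d$event <- as.integer(d$time_days < 30)
    ph_check(cox_fit(d, "x"))$flagged
  })
  expect_gte(mean(flags), 0.8)

  # too few events: undefined with a reason
  tiny <- data.frame(time_days = c(3, 6, 10, 20), event = c(1, 1, 0, 0),
                     x = c(2, 1, 4, 3))
  res <- ph_check(cox_fit(tiny, "x"))
  expect_match(res$reason, "fewer than 3 events")
})

test_that("rank-estimator AUC matches the exhaustive pairwise oracle", {
  # perfect separation
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1)
  # all tied scores
  expect_equal(roc_auc(rep(7, 10), rep(c(0, 1), 5))$auc, 0.5)
  # ties handled as half-concordant
  set.seed(61)
  for (i in 1:20) {
    sc <- sample(1:6, 25, replace = TRUE)
    y <- rbinom(25, 1, 0.4)
    if (sum(y) == 0 || sum(y) == 25) next
    expect_equal(roc_auc(sc, y)$auc, oracle_auc(sc, y == 1))
  }
  # invariance under strictly increasing transforms
  sc <- rnorm(50)
  y <- rbinom(50, 1, 0.5)
  expect_equal(roc_auc(exp(sc), y)$auc, roc_auc(sc, y)$auc)
  expect_equal(roc_auc(rank(sc), y)$auc, roc_auc(sc, y)$auc)
  # single-class input undefined with reason
  expect_identical(roc_auc(1:5, rep(1, 5))$reason, "single_class")
})

test_that("rank-estimator AUC agrees with an established ROC implementation", {
  set.seed(63)
  sc <- rnorm(80)
  y <- rbinom(80, 1, 0.35)
  got <- roc_auc(sc, y)
  want <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                         direction = "<")))
  expect_equal(got$auc, want, tolerance = 1e-12)
})

test_that("Bland-Altman limits and outside counts match a direct recount", {
  id <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(id$bias, 0)
  expect_equal(id$loa_low, 0)
  expect_equal(id$loa_high, 0)
  expect_identical(id$n_outside, 0L)

  # constant offset: zero-width limits at the bias
  a <- c(0.1, 0.2, 0.3, 0.4)
  off <- bland_altman(a, a + 0.5)
  expect_equal(off$bias, -0.5)
  expect_equal(off$sd_diff, 0)
  expect_equal(off$loa_low, off$loa_high)

  set.seed(65)
  x20 <- rnorm(164, 0.05, 0.1)
  x10 <- x20 + rnorm(164, 0, 0.03)
  ba <- bland_altman(x20, x10)
  d <- x20 - x10
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$loa_low, mean(d) - 1.96 * sd(d))
  expect_identical(ba$n_outside,
                   sum(d < mean(d) - 1.96 * sd(d) | d > mean(d) + 1.96 * sd(d)))
  expect_lte(ba$n_outside, ba$n_total)
  # ~5% of gaussian differences fall outside 1.96 SD limits
  expect_lt(ba$n_outside / ba$n_total, 0.12)

  expect_error(bland_altman(1:4, 1:5), class = "spo2_schema_error")
  expect_error(bland_altman(1:2, 1:2), class = "spo2_degenerate_error")
})

test_that("survivor table reproduces direct group summaries", {
  set.seed(67)
  cohort <- data.frame(
    group = rep(c("sepsis", "copd"), each = 40),
    event = rep(c(0, 1), 40),
    mean_spo2 = rnorm(80, 96, 2),
    sampen = rnorm(80, 0.12, 0.05),
    delta = rnorm(80, 0.05, 0.1)
  )
  tab <- survivor_table(cohort)
  expect_identical(nrow(tab), 6L)   # 2 groups x 3 features
  row <- tab[tab$group == "sepsis" & tab$feature == "delta", ]
  sub <- cohort[cohort$group == "sepsis", ]
  expect_equal(row$mean_survivor, mean(sub$delta[sub$event == 0]))
  expect_equal(row$sd_nonsurvivor, sd(sub$delta[sub$event == 1]))
  expect_equal(row$p_value,
               two_group_t(sub$delta[sub$event == 0],
                           sub$delta[sub$event == 1])$p_value)

  # equal delta distributions across arms: no significance in most seeds
  ps <- replicate(40, {
    co <- data.frame(group = "sepsis", event = rep(c(0, 1), 50),
                     delta = rnorm(100, 0.05, 0.1))
    survivor_table(co, features = "delta")$p_value
  })
  expect_gt(mean(ps > 0.05), 0.8)

  # an arm with < 2 members reports NA cells, not errors
  small <- data.frame(group = "alf", event = c(0, 0, 1),
                      delta = c(0.1, 0.2, 0.3))
  expect_true(is.na(survivor_table(small, features = "delta")$p_value))
})
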