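# Independent brute-force oracles. Each one re-derives a quantity by direct
# enumeration or closed form, sharing no code with the implementation paths
# it checks.

# SampEn match counts by explicit double loop over all template pairs: both
# the m- and (m+1)-length counts run over start positions 1..N-m, Chebyshev
# distance, each unordered pair once, full max over the extended template.
oracle_sampen_counts <- function(x, m, t) {
  n <- length(x) - m
  A <- 0L
  B <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)])) <= t) B <- B + 1L
      if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= t) A <- A + 1L
    }
  }
  c(A = A, B = B)
}

oracle_sampen <- function(x, m, t) {
  cnt <- oracle_sampen_counts(x, m, t)
  if (cnt[["B"]] == 0L || cnt[["A"]] == 0L) return(NA_real_)
  -log(cnt[["A"]] / cnt[["B"]])
}

# OLS slope/intercept by the closed-form normal equations.
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Euclidean point-to-line distance via the perpendicular-foot projection
# onto y = m*x + b (not the signed-distance formula).
oracle_point_line_dist <- function(x0, y0, m, b) {
  # foot of the perpendicular from (x0, y0)
  xf <- (x0 + m * (y0 - b)) / (1 + m^2)
  yf <- m * xf + b
  sqrt((x0 - xf)^2 + (y0 - yf)^2)
}

# Cox log partial likelihood for a single covariate with distinct event
# times, enumerated risk set by risk set; vectorised over a beta grid.
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- rep(0, length(beta))
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    for (k in seq_along(beta))
      ll[k] <- ll[k] + beta[k] * x[i] - log(sum(exp(beta[k] * x[risk])))
  }
  ll
}

# Grid-search maximiser of the partial likelihood: coarse pass over
# [-4, 4], then a fine 1e-5 grid around the coarse optimum.
oracle_cox_beta <- function(time, event, x) {
  coarse <- seq(-4, 4, by = 0.01)
  b0 <- coarse[which.max(oracle_cox_loglik(coarse, time, event, x))]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-5)
  fine[which.max(oracle_cox_loglik(fine, time, event, x))]
}

# AUC by exhaustive pairwise comparison: concordant pairs plus half ties.
oracle_auc <- function(scores, outcome) {
  pos <- scores[outcome]
  neg <- scores[!outcome]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Convenience: write a segment-style CSV fixture and return its path.
write_fixture_csv <- function(values, t_s = seq_along(values) - 1L,
                              header = TRUE, single_col = FALSE) {
  path <- tempfile(fileext = ".csv")
  if (single_col) {
    writeLines(as.character(values), path)
  } else {
    df <- data.frame(t_s = t_s, spo2 = values)
    utils::write.table(df, path, sep = ",", row.names = FALSE,
                       col.names = header, quote = FALSE)
  }
  path
}
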