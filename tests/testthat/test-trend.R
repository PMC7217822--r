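test_that("OLS matches collinear, constant and lm-oracle cases", {
  fit <- ols_fit(c(0, 1, 2), c(0, -1, -2))
  expect_equal(fit$slope, -1)
  expect_equal(fit$intercept, 0)
  expect_equal(ols_fit(0:5, rep(3, 6))$slope, 0)
  set.seed(8)
  t <- runif(8, 0, 5); y <- -5 - 0.4 * t + rnorm(8)
  fit <- ols_fit(t, y)
  lmfit <- summary(lm(y ~ t))
  expect_equal(fit$slope, unname(coef(lmfit)[2, 1]), tolerance = 1e-12)
  expect_equal(fit$intercept, unname(coef(lmfit)[1, 1]), tolerance = 1e-12)
  expect_equal(fit$slope_se, unname(coef(lmfit)[2, 2]), tolerance = 1e-12)
  expect_equal(fit$slope_p, unname(coef(lmfit)[2, 4]), tolerance = 1e-12)
  expect_error(ols_fit(rep(1, 4), rnorm(4)), "degenerate")
})

test_that("weighted fit matches lm and degenerates correctly", {
  set.seed(9)
  t <- runif(8, 0, 5); y <- -5 - 0.4 * t + rnorm(8); w <- runif(8, 0.1, 3)
  fit <- weighted_fit(t, y, w)
  lmfit <- summary(lm(y ~ t, weights = w))
  expect_equal(fit$slope, unname(coef(lmfit)[2, 1]), tolerance = 1e-12)
  expect_equal(fit$slope_se, unname(coef(lmfit)[2, 2]), tolerance = 1e-12)
  expect_equal(fit$slope_p, unname(coef(lmfit)[2, 4]), tolerance = 1e-12)
  # equal weights of any scale reproduce OLS; weights are scale-free
  f1 <- weighted_fit(t, y, rep(7.3, 8))
  f0 <- ols_fit(t, y)
  expect_equal(f1$slope, f0$slope, tolerance = 1e-12)
  expect_equal(f1$slope_p, f0$slope_p, tolerance = 1e-12)
  f2 <- weighted_fit(t, y, w * 1e6)
  expect_equal(f2$slope, fit$slope, tolerance = 1e-9)
  # a dominating weight pins the line to that point
  w2 <- c(1e6, rep(1, 7))
  fd <- weighted_fit(t, y, w2)
  expect_lt(abs(fd$intercept + fd$slope * t[1] - y[1]), 1e-3)
  expect_error(weighted_fit(c(1, 1, 2), c(0, 0, 1), c(1, 1, 0)), "degenerate")
  expect_error(weighted_fit(t, y, -w), "nonnegative")
})

test_that("reconstruction-error weights follow the reciprocal formula", {
  s <- random_series(5, seed = 50)
  rec <- s
  rec$td <- s$td + 2          # every exam differs by exactly 2 dB in mTD
  sch <- weight_scheme("vae_mtd", epsilon = 0.5)
  expect_equal(vae_weights(s, rec, sch), rep(0.5, 5))
  # perfect reconstruction: capped at 1/epsilon
  expect_equal(vae_weights(s, s, sch), rep(2, 5))
  # pointwise mode: per-point reciprocal, epsilon floor
  rec2 <- s
  rec2$td[, 1] <- s$td[, 1] + 4
  w <- vae_weights(s, rec2, weight_scheme("vae_pointwise", epsilon = 0.5))
  expect_equal(w[, 1], rep(0.25, 5))
  expect_equal(w[, 2], rep(2, 5))
  # doubling the reconstruction error halves the weights (above the floor)
  rec3 <- s; rec3$td <- s$td + 8
  w3 <- vae_weights(s, rec3, weight_scheme("vae_pointwise", epsilon = 0.5))
  expect_equal(w3[, 1], w[, 1] / 2)
  expect_equal(vae_weights(s, NULL, weight_scheme("unweighted")), rep(1, 5))
  expect_error(vae_weights(s, vf_truncate(s, 3), sch), "aligned")
})

test_that("mTD trend classifies progression and honours weighting modes", {
  s <- random_series(10, seed = 51)
  expect_equal(mtd_trend(s, weight_scheme("unweighted"))$slope,
               ols_fit(s$t, compute_mtd(s))$slope)
  # linear deterioration without noise: significant, exact slope
  td <- matrix(rep(-1 * (0:9), 52), 10)
  s2 <- vf_series("p", 0:9, td)
  fit <- mtd_trend(s2, weight_scheme("unweighted"))
  expect_equal(fit$slope, -1)
  expect_true(fit$significant)
  # minimal length: n = 3 gives a valid p
  s3 <- vf_truncate(random_series(5, seed = 52), 3)
  f3 <- mtd_trend(s3, weight_scheme("unweighted"))
  expect_equal(f3$n, 3)
  expect_true(f3$slope_p >= 0 && f3$slope_p <= 1)
})

test_that("future-mTD prediction extrapolates the fit", {
  td <- matrix(rep(-2 - 0.5 * (0:9), 52), 10)
  s <- vf_series("p", seq(0, 4.5, by = 0.5), td)
  # noise-free linear series: exact prediction from any truncation
  for (k in c(2, 3, 7))
    expect_equal(predict_future_mtd(s, k, 4.5), compute_mtd(vf_exam(s, 10)),
                 tolerance = 1e-9)
  # equal weights agree with unweighted
  rec <- s; rec$td <- s$td + 1
  expect_equal(predict_future_mtd(s, 5, 4.5, weight_scheme("vae_mtd"), rec),
               predict_future_mtd(s, 5, 4.5), tolerance = 1e-9)
})

test_that("pointwise PLR p-values match the t-test oracle", {
  s <- random_series(10, seed = 53)
  plr <- pointwise_plr(s)
  for (j in c(1, 17, 52)) {
    lmfit <- summary(lm(s$td[, j] ~ s$t))
    tt <- coef(lmfit)[2, 3]
    expect_equal(plr$p[j], pt(tt, 8), tolerance = 1e-10)
    expect_equal(plr$slope[j], unname(coef(lmfit)[2, 1]), tolerance = 1e-10)
  }
  # constant points give p = 0.5 under the symmetric null
  s0 <- vf_series("c", 0:4, matrix(-3, 5, 52))
  expect_equal(pointwise_plr(s0)$p, rep(0.5, 52))
  # a noise-free deteriorating point has p near 0
  td <- matrix(-3, 5, 52); td[, 9] <- -3 - 2 * (0:4)
  sdet <- vf_series("d", 0:4, td)
  expect_lt(pointwise_plr(sdet)$p[9], 1e-6)
  # two-sided option
  expect_equal(pointwise_plr(s, alternative = "two.sided")$p[1],
               summary(lm(s$td[, 1] ~ s$t))$coefficients[2, 4],
               tolerance = 1e-10)
})

test_that("binomial PLR uses exact tails, the median-of-four and the 0.025 rule", {
  # all-null p-vector: counts 0, tail probabilities 1, not significant
  b0 <- binomial_plr(rep(0.5, 52))
  expect_equal(b0$counts_below, rep(0L, 4))
  expect_equal(b0$binom_p, rep(1, 4))
  expect_false(b0$significant)
  # exact enumeration oracle at c = 0.05, k = 6
  p <- c(rep(0.01, 6), rep(0.5, 46))
  b <- binomial_plr(p)
  oracle <- sum(choose(52, 6:52) * 0.05^(6:52) * 0.95^(52 - 6:52))
  expect_equal(b$binom_p[2], oracle, tolerance = 1e-12)
  # strict inequality: p exactly at the cutoff does not count
  p2 <- c(rep(0.05, 6), rep(0.5, 46))
  expect_equal(binomial_plr(p2)$counts_below[2], 0L)
  # median of four = mean of the two middle values
  expect_equal(vfnoise:::N_POINTS, 52L)
  bp <- binomial_plr(c(rep(1e-4, 10), rep(0.9, 42)))
  expect_equal(bp$median_p, mean(sort(bp$binom_p)[2:3]))
  expect_error(binomial_plr(rep(0.5, 51)), "52")
  expect_error(binomial_plr(c(rep(0.5, 51), 1.2)), "\\[0, 1\\]")
})

test_that("binomial PLR is monotone in the per-point p-values", {
  set.seed(54)
  for (rep_i in 1:20) {
    p <- runif(52)
    b1 <- binomial_plr(p)
    p2 <- p
    j <- sample(52, 5)
    p2[j] <- p[j] * runif(5)   # lower some p-values
    b2 <- binomial_plr(p2)
    expect_lte(b2$median_p, b1$median_p + 1e-12)
  }
})

test_that("detection power grows with series length under progression", {
  gen <- suppressWarnings(generate_cohort(
    cohort_config(n_eyes = 60, slope_mean = -1.2, slope_sd = 0.2, seed = 61),
    noise_model()))
  det <- sapply(c(4, 10), function(k) {
    mean(vapply(gen$measured, function(s)
      binomial_plr_series(vf_truncate(s, k))$significant, logical(1)))
  })
  expect_gt(det[2], det[1])
})
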