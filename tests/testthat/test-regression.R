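test_that("linear flux equals the closed-form OLS slope oracle", {
  set.seed(11)
  sys <- case_system()
  for (rep in 1:5) {
    y <- 325 + 0.05 * case_times + rnorm(4, 0, 3)
    ser <- conc_series(case_times, y, sys)
    fit <- fit_linear(ser)
    slope <- sum((case_times - mean(case_times)) * (y - mean(y))) /
      sum((case_times - mean(case_times))^2)
    expect_equal(fit$flux, slope * 0.2 * conv_ref, tolerance = 1e-12)
    expect_true(fit$converged)
  }
  # constant concentrations give exactly zero flux
  ser0 <- conc_series(case_times, rep(325, 4), sys)
  expect_equal(fit_linear(ser0)$flux, 0)
})

test_that("linear slope uncertainty matches the textbook design factor", {
  # sd(slope) = sd_gc / sqrt(sum((t - tbar)^2)); for 0/12/24/36 min the
  # design sum is 2 592 000 s^2, so 3 ppb of noise gives 1.8634e-3 ppb/s
  expect_equal(sqrt(sum((case_times - mean(case_times))^2)), sqrt(2592000))
  sys <- case_system()
  f <- analytic_f_det_linear(sys, case_times, quantile = 0.975)
  expect_equal(f, qnorm(0.975) * (3 / sqrt(2592000)) * 0.2 * conv_ref,
               tolerance = 1e-12)
  expect_equal(f, 0.030, tolerance = 0.02)
})

test_that("robust fit equals OLS on clean data and resists an outlier", {
  sys <- case_system()
  # zero residual spread: all weights 1
  ser <- exact_series(1, 0, system = case_system(sd_gc = 0))
  expect_equal(fit_robust_linear(ser)$flux, fit_linear(ser)$flux,
               tolerance = 1e-10)
  # gross middle-point outlier on an otherwise exact line
  y <- 325 + 0.05 * case_times
  y[3] <- y[3] + 40
  sero <- conc_series(case_times, y, sys)
  f_ols <- fit_linear(sero)$flux
  f_rob <- fit_robust_linear(sero)$flux
  # consensus: OLS on the three clean points
  keep <- c(1, 2, 4)
  slope3 <- coef(lm(y[keep] ~ case_times[keep]))[[2]]
  f_cons <- slope3 * 0.2 * conv_ref
  expect_lt(abs(f_rob - f_cons), abs(f_ols - f_cons))
  # endpoints keep full weight at n = 4
  expect_equal(fit_robust_linear(sero)$diagnostics$weights[c(1, 4)], c(1, 1))
})

test_that("robust and OLS agree in expectation under symmetric noise", {
  set.seed(21)
  sys <- case_system()
  diffs <- replicate(150, {
    ser <- noisy_series(0.5, 0, sd_gc = 3)
    fit_robust_linear(ser)$flux - fit_linear(ser)$flux
  })
  # mean difference within 3 MC standard errors of zero
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)))
})

test_that("the kappa profile solves the conditional least squares exactly", {
  # noiseless model data: at the true kappa the profile recovers phi and
  # f0 with zero residual; elsewhere the SSE is positive
  ser <- exact_series(2, 1e-3)
  pr <- hmr_profile_sse(ser, 1e-3)
  expect_equal(pr$f0, 2, tolerance = 1e-10)
  expect_equal(pr$phi, 325 + (2 / conv_ref) / (1e-3 * 0.2), tolerance = 1e-10)
  expect_lt(pr$sse, 1e-15)
  expect_gt(hmr_profile_sse(ser, 5e-3)$sse, 1e-2)

  # against a generic-optimiser oracle over (phi, beta) at fixed kappa
  set.seed(31)
  sern <- noisy_series(1, 3e-4, sd_gc = 3)
  for (kappa in c(1e-5, 3e-4, 2e-3)) {
    pr <- hmr_profile_sse(sern, kappa)
    e <- exp(-kappa * sern$times)
    # independent route: normal equations of the two-column design
    X <- cbind(1, e)
    par <- solve(crossprod(X), crossprod(X, sern$concentrations))
    sse_ne <- sum((sern$concentrations - X %*% par)^2)
    expect_equal(pr$sse, sse_ne, tolerance = 1e-6)
    expect_equal(pr$phi, par[1], tolerance = 1e-6)
  }
})

test_that("fit_hmr inverts noiseless model data and refuses linear data", {
  ser <- exact_series(2, 1e-3)
  fit <- fit_hmr(ser)
  expect_true(fit$converged)
  expect_equal(fit$flux, 2, tolerance = 1e-4)
  expect_equal(fit$params$kappa, 1e-3, tolerance = 1e-4)
  expect_equal(fit$params$phi, 325 + (2 / conv_ref) / (1e-3 * 0.2),
               tolerance = 1e-4)
  # uptake flux, same identifiability
  fitu <- fit_hmr(exact_series(-1, 1e-3))
  expect_true(fitu$converged)
  expect_equal(fitu$flux, -1, tolerance = 1e-4)
  # exactly linear data has no interior curvature optimum
  flin <- fit_hmr(exact_series(1, 0))
  expect_false(flin$converged)
  expect_true(is.na(flin$flux))
})

test_that("fitted kappa stays inside the search bounds, SSE below the profile", {
  set.seed(41)
  for (rep in 1:30) {
    ser <- noisy_series(runif(1, 0, 2), 10^runif(1, -6, -2), sd_gc = 3)
    fit <- fit_hmr(ser)
    if (fit$converged) {
      expect_gt(fit$params$kappa, 1e-7)
      expect_lt(fit$params$kappa, 1)
      expect_lt(fit$sse, fit$diagnostics$sse_linear)
    }
  }
  # on strongly identified data the minimised SSE beats any probed kappa
  set.seed(42)
  ser <- noisy_series(2, 1e-3, sd_gc = 0.5)
  fit <- fit_hmr(ser)
  expect_true(fit$converged)
  probes <- 10^seq(-6.5, -0.5, length.out = 25)
  sse_probes <- vapply(probes, function(k) hmr_profile_sse(ser, k)$sse, 0)
  expect_lte(fit$sse, min(sse_probes) * (1 + 1e-9))
})

test_that("fit_hmr agrees with a dense global kappa-grid oracle on average", {
  set.seed(51)
  sys <- case_system()
  dense <- exp(seq(log(1e-7), log(1), length.out = 1e4))
  Emat <- exp(-outer(dense, case_times))
  me <- rowMeans(Emat)
  sxx <- rowSums((Emat - me)^2)
  n_rep <- 200
  f_pkg <- f_orc <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    ser <- noisy_series(1, 1e-4, sd_gc = 3)
    y <- ser$concentrations
    fit <- fit_hmr(ser)
    flin <- fit_linear(ser)$flux
    f_pkg[r] <- if (fit$converged) fit$flux else flin
    # vectorised closed-form profile over the dense grid, independent of
    # package internals
    sxy <- (Emat - me) %*% (y - mean(y))
    beta <- as.numeric(sxy) / sxx
    sse <- sum((y - mean(y))^2) - beta^2 * sxx
    j <- which.min(sse)
    f_orc[r] <- if (j > 1 && j < length(dense))
      -beta[j] * dense[j] * 0.2 * conv_ref else flin
  }
  expect_equal(median(f_pkg), median(f_orc), tolerance = 0.1)
})

test_that("AIC penalises parameters and rewards fit quality as it should", {
  ser <- exact_series(2, 1e-3)
  lin <- fit_linear(ser)
  hmr <- fit_hmr(ser)
  # curved noiseless data: HMR wins despite the extra parameter
  expect_lt(aic_of_fit(hmr), aic_of_fit(lin))
  # equal SSE: the smaller model wins by its penalty
  set.seed(61)
  sern <- noisy_series(0.5, 0, sd_gc = 3)
  linn <- fit_linear(sern)
  fake_hmr <- linn; fake_hmr$method <- "hmr"
  expect_equal(aic_of_fit(fake_hmr) - aic_of_fit(linn), 2)
  # halving the SSE at fixed n and k drops the AIC by n log 2
  half <- linn; half$sse <- linn$sse / 2
  expect_equal(aic_of_fit(linn) - aic_of_fit(half), 4 * log(2),
               tolerance = 1e-12)
  expect_error(aic_of_fit(linn, n = 0), "> 0")
})
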