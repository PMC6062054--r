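test_that("the kappa.max threshold follows its defining ratio", {
  # flux at the detection limit: threshold is exactly 1/t_meas
  expect_equal(kappa_max(0.028, 0.028, 2160), 1 / 2160)
  expect_equal(kappa_max(0.28, 0.028, 2160), 10 / 2160)
  # zero linear flux forbids any nonlinearity
  expect_equal(kappa_max(0, 0.028, 2160), 0)
  # uptake gets the same restriction magnitude
  expect_equal(kappa_max(-0.28, 0.028, 2160), kappa_max(0.28, 0.028, 2160))
  # monotone in its arguments
  expect_gt(kappa_max(0.5, 0.028, 2160), kappa_max(0.25, 0.028, 2160))
  expect_lt(kappa_max(0.28, 0.056, 2160), kappa_max(0.28, 0.028, 2160))
  expect_lt(kappa_max(0.28, 0.028, 4320), kappa_max(0.28, 0.028, 2160))
  expect_error(kappa_max(0.28, 0, 2160), "f_det")
  expect_error(kappa_max(0.28, 0.028, -1), "t_meas")
})

test_that("kappa.max accepts a clearly identified moderate curvature", {
  # noiseless f0 = 2, kappa = 1e-3: kappa_max = 2/(0.028*2160) ~ 0.033
  # (the linear estimate is attenuated but still large), well above the
  # fitted kappa, so the HMR flux is selected and recovers f0
  ser <- exact_series(2, 1e-3)
  d <- select_flux(ser, scheme_config("KAPPAMAX", f_det = 0.028))
  expect_equal(d$chosen, "hmr")
  expect_equal(d$reason, "hmr_ok")
  expect_equal(d$flux, 2, tolerance = 1e-4)
  expect_true(d$kappa_max_value > d$hmr_fit$params$kappa)
})

test_that("every nonlinear scheme falls back to linear when HMR fails", {
  ser <- exact_series(1, 0)   # exactly linear: no interior optimum
  f_lin <- fit_linear(ser)$flux
  for (sch in c("HMR", "AIC", "GFACTOR", "FIXEDKAPPA")) {
    d <- select_flux(ser, scheme_config(sch))
    expect_equal(d$chosen, "linear", info = sch)
    expect_equal(d$reason, "hmr_not_converged", info = sch)
    expect_equal(d$flux, f_lin, info = sch)
  }
  d <- select_flux(ser, scheme_config("KAPPAMAX", f_det = 0.028))
  expect_equal(d$reason, "hmr_not_converged")
  expect_equal(d$flux, f_lin)
})

test_that("the g-factor cap and fixed-kappa threshold reject amplified fits", {
  # strong saturation: the linear estimate is much smaller than f0, so
  # the nonlinear/linear ratio blows past the default g-factor of 4
  ser <- exact_series(2, 5e-3)
  hmr <- fit_hmr(ser)
  lin <- fit_linear(ser)
  expect_true(hmr$converged)
  expect_gt(abs(hmr$flux / lin$flux), 4)
  d <- select_flux(ser, scheme_config("GFACTOR"))
  expect_equal(d$reason, "g_factor_exceeded")
  expect_equal(d$flux, lin$flux)
  # a generous cap accepts the same fit
  d9 <- select_flux(ser, scheme_config("GFACTOR", g_max = 1e6))
  expect_equal(d9$flux, hmr$flux)
  # fixed threshold: kappa = 5e-3 s^-1 = 18 h^-1 sits below 20 h^-1 but
  # above 10 h^-1
  expect_equal(select_flux(ser, scheme_config("FIXEDKAPPA", kappa_fixed = 20))$chosen, "hmr")
  dfk <- select_flux(ser, scheme_config("FIXEDKAPPA", kappa_fixed = 10))
  expect_equal(dfk$reason, "kappa_exceeds_fixed")
  expect_equal(dfk$flux, lin$flux)
})

test_that("kappa.max degenerates to LR and to HMR in its f_det limits", {
  set.seed(71)
  series <- replicate(25, noisy_series(runif(1, 0, 2), 10^runif(1, -5, -2.5)),
                      simplify = FALSE)
  for (ser in series) {
    d_inf <- select_flux(ser, scheme_config("KAPPAMAX", f_det = 1e9))
    expect_equal(d_inf$flux, fit_linear(ser)$flux)
    d_hmr <- select_flux(ser, scheme_config("HMR"))
    d_0 <- select_flux(ser, scheme_config("KAPPAMAX", f_det = 1e-12))
    if (!is.null(d_0$hmr_fit) && d_0$hmr_fit$converged &&
        abs(d_0$linear_fit$flux) > 0)
      expect_equal(d_0$flux, d_hmr$flux)
    # the selected flux is always one of the two base estimates
    expect_true(d_hmr$flux %in% c(d_hmr$linear_fit$flux,
                                  if (d_hmr$hmr_fit$converged) d_hmr$hmr_fit$flux))
    # kappa.max never moves further from LR than HMR does when both
    # accept or both reject the same fit
    km <- select_flux(ser, scheme_config("KAPPAMAX", f_det = 0.09))
    if (km$chosen == "hmr" || d_hmr$chosen == "linear")
      expect_lte(abs(km$flux - km$linear_fit$flux),
                 abs(d_hmr$flux - d_hmr$linear_fit$flux) + 1e-12)
  }
})

test_that("batch selection summarises a campaign per scheme", {
  # all-linear batch: the deviation ratio is exactly 1
  series <- lapply(c(0.3, 0.6, 1.2), exact_series, kappa = 0)
  b <- batch_select(series, list(scheme_config("LR"), scheme_config("HMR")))
  expect_equal(nrow(b$decisions), 6L)
  expect_equal(b$summary$deviation_from_lr, c(1, 1))
  expect_equal(b$summary$n_hmr, c(0L, 0L))
  # a singleton batch reproduces the single decision
  ser <- exact_series(2, 1e-3)
  b1 <- batch_select(list(ser), scheme_config("KAPPAMAX", f_det = 0.028))
  d1 <- select_flux(ser, scheme_config("KAPPAMAX", f_det = 0.028))
  expect_equal(b1$decisions$flux, d1$flux)
  expect_equal(b1$decisions$reason, d1$reason)
  expect_equal(b1$summary$mean_flux, d1$flux)
  expect_error(batch_select(list(), scheme_config("LR")), "empty")
})

test_that("AIC accepts nonlinearity more freely than kappa.max on small fluxes", {
  set.seed(81)
  series <- replicate(100, noisy_series(runif(1, 0.05, 0.3), 2e-3, sd_gc = 3),
                      simplify = FALSE)
  b <- batch_select(series, list(scheme_config("AIC"),
                                 scheme_config("KAPPAMAX", f_det = 0.09)))
  n_aic <- b$summary$n_hmr[b$summary$scheme == "AIC"]
  n_km <- b$summary$n_hmr[b$summary$scheme == "KAPPAMAX"]
  expect_gte(n_aic, n_km)
})

test_that("scheme configuration is validated", {
  expect_error(scheme_config("KAPPAMAX"), "f_det")
  expect_error(scheme_config("KAPPAMAX", f_det = -1), "f_det")
  expect_error(scheme_config("GFACTOR", g_max = 1), "g_max")
  expect_error(scheme_config("FIXEDKAPPA", kappa_fixed = 0), "kappa_fixed")
  expect_error(scheme_config("NOSUCH"), "arg")
})
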