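# Base flux estimators: ordinary linear, Huber robust linear, and the
# HMR nonlinear fit via a profiled partial-linear least-squares
# algorithm.

# internal constructor for fit records
.flux_fit <- function(method, flux = NA_real_, params = NULL, sse = NA_real_,
                      aic = NA_real_, se_flux = NA_real_, converged = FALSE,
                      n = NA_integer_, diagnostics = list()) {
  structure(
    list(method = method, flux = flux, params = params, sse = sse,
         aic = aic, se_flux = se_flux, converged = converged, n = n,
         diagnostics = diagnostics),
    class = "flux_fit")
}

#' @export
print.flux_fit <- function(x, ...) {
  cat(sprintf("<flux_fit:%s> ", x$method))
  if (x$converged)
    cat(sprintf("flux = %.4g +/- %.3g nmol s^-1 m^-2, sse = %.4g ppb^2, aic = %.4g\n",
                x$flux, x$se_flux, x$sse, x$aic))
  else
    cat("not converged\n")
  if (inherits(x$params, "hmr_parameters"))
    cat(sprintf("  phi = %.5g ppb, kappa = %.4g s^-1\n", x$params$phi, x$params$kappa))
  invisible(x)
}

# Akaike information criterion from a residual sum of squares under a
# Gaussian error model: n log(sse/n) + 2k with k counting the error
# variance as one parameter.  An SSE floor of (1e-6 ppb)^2 * n keeps the
# criterion finite on noiseless fixtures.
.aic_from_sse <- function(sse, n, k) {
  if (!isTRUE(n > 0)) stop("'n' must be > 0")
  if (n < k - 1L) stop("'n' must be at least the number of model parameters")
  sse <- max(sse, 1e-12 * n)
  n * log(sse / n) + 2 * k
}

# parameter count (including the error variance) per fit method
.aic_k <- function(method) {
  switch(method, linear = 3L, robust_linear = 3L, hmr = 4L,
         stop("unknown fit method '", method, "'"))
}

#' AIC of a flux fit
#'
#' Gaussian-likelihood Akaike information criterion
#' `n log(sse / n) + 2k`, with `k` the number of model parameters plus
#' one for the error variance: 3 for the linear fits, 4 for HMR.  Used
#' by the AIC decision scheme to compare the linear and HMR fit of one
#' closure.
#'
#' @param fit a `flux_fit` with an `sse`.
#' @param n number of samples the fit used; defaults to the count stored
#'   in the fit.
#' @return the AIC, dimensionless.
#' @export
aic_of_fit <- function(fit, n = fit$n) {
  stopifnot(inherits(fit, "flux_fit"))
  if (!is.finite(fit$sse)) stop("fit has no residual sum of squares")
  .aic_from_sse(fit$sse, n, .aic_k(fit$method))
}

# slope/intercept least squares with flux conversion shared by the two
# linear estimators
.linear_from_coef <- function(series, coef, resid, method, se_slope = NA_real_,
                              diagnostics = list()) {
  h <- effective_height(series$system)
  cv <- .conv_factor(series$system)
  sse <- sum(resid^2)
  n <- length(series$times)
  .flux_fit(method,
            flux = unname(coef[2L]) * h * cv,
            params = c(intercept = unname(coef[1L]), slope = unname(coef[2L])),
            sse = sse,
            aic = .aic_from_sse(sse, n, .aic_k(method)),
            se_flux = se_slope * h * cv,
            converged = TRUE, n = n, diagnostics = diagnostics)
}

#' Ordinary linear regression flux
#'
#' Least-squares slope of concentration on time, scaled to a flux by the
#' effective chamber height and the ppb to nmol m^-3 conversion:
#' `f_lin = slope * h * p / (R T)`.
#'
#' @param series a [conc_series()].
#' @return a `flux_fit` with method `"linear"`; always converged.
#' @export
fit_linear <- function(series) {
  stopifnot(inherits(series, "conc_series"))
  t <- series$times; y <- series$concentrations
  if (length(unique(t)) < 3L) stop("need at least 3 distinct sample times")
  fit <- stats::lm.fit(cbind(1, t), y)
  n <- length(t)
  sse <- sum(fit$residuals^2)
  sxx <- sum((t - mean(t))^2)
  if (sxx <= 0) stop("degenerate design: all sample times identical")
  # residual variance with 2 regression df
  se_slope <- sqrt(sse / (n - 2L) / sxx)
  .linear_from_coef(series, fit$coefficients, fit$residuals, "linear", se_slope)
}

#' Robust linear regression flux (Huber M-estimator)
#'
#' Iteratively reweighted least squares with the Huber psi function
#' (tuning constant 1.345, scale re-estimated each iteration from the
#' median absolute residual).  With the minimum of 4 samples the first
#' and last time point are never down-weighted, so single outlying
#' middle samples cannot drag the slope through leverage at the ends.
#' If the IRLS does not settle within 100 iterations the ordinary
#' least-squares fit is returned with a `fallback` diagnostic.
#'
#' @param series a [conc_series()].
#' @return a `flux_fit` with method `"robust_linear"`.
#' @export
fit_robust_linear <- function(series) {
  stopifnot(inherits(series, "conc_series"))
  t <- series$times; y <- series$concentrations
  if (length(unique(t)) < 3L) stop("need at least 3 distinct sample times")
  n <- length(t)
  X <- cbind(1, t)
  cc <- 1.345
  coef <- stats::lm.fit(X, y)$coefficients
  converged_irls <- FALSE
  w <- rep(1, n)
  for (iter in seq_len(100L)) {
    r <- y - X %*% coef
    s <- stats::median(abs(r)) / 0.6745
    if (s < 1e-10) { w <- rep(1, n); converged_irls <- TRUE; break }
    w <- pmin(1, cc * s / abs(as.numeric(r)))
    if (n == 4L) w[c(1L, n)] <- 1  # endpoints keep full weight at minimal n
    fitw <- stats::lm.wfit(X, y, w)
    delta <- max(abs(fitw$coefficients - coef)) / max(1, max(abs(coef)))
    coef <- fitw$coefficients
    if (delta < 1e-6) { converged_irls <- TRUE; break }
  }
  diagnostics <- list(weights = as.numeric(w), irls_converged = converged_irls)
  if (!converged_irls) {
    warning("Huber IRLS did not converge within 100 iterations; ",
            "returning the ordinary least-squares fit")
    lin <- fit_linear(series)
    lin$method <- "robust_linear"
    lin$diagnostics <- c(lin$diagnostics, list(fallback = "irls_not_converged"))
    lin$aic <- .aic_from_sse(lin$sse, n, .aic_k("robust_linear"))
    return(lin)
  }
  r <- as.numeric(y - X %*% coef)
  sxx_w <- sum(w * (t - stats::weighted.mean(t, w))^2)
  se_slope <- sqrt(sum(w * r^2) / max(1L, n - 2L) / sxx_w)
  .linear_from_coef(series, coef, r, "robust_linear", se_slope, diagnostics)
}

#' Conditional least squares of the HMR model at fixed kappa
#'
#' For fixed `kappa` the HMR curve is linear in `(phi, beta)` with
#' `beta = f0 / (-kappa h)` (f0 in ppb m s^-1), so the conditional
#' least-squares solution is exact.  This profile is the inner step of
#' [fit_hmr()]'s partial-linear algorithm.
#'
#' When `exp(-kappa t)` underflows at every `t > 0` the regressor
#' degenerates to an indicator of the first sample (the "two-level"
#' fit); the result is returned with `degenerate = TRUE`.
#'
#' @param series a [conc_series()].
#' @param kappa nonlinearity parameter, s^-1; > 0.
#' @return list with `phi` (ppb), `f0` (nmol s^-1 m^-2), `beta` (ppb),
#'   `sse` (ppb^2) and `degenerate`.
#' @export
hmr_profile_sse <- function(series, kappa) {
  stopifnot(inherits(series, "conc_series"))
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) || kappa <= 0)
    stop("'kappa' must be a single finite number > 0")
  t <- series$times; y <- series$concentrations
  e <- exp(-kappa * t)
  me <- mean(e); my <- mean(y)
  sxx <- sum((e - me)^2)
  h <- effective_height(series$system)
  cv <- .conv_factor(series$system)
  if (sxx < .Machine$double.xmin) {
    # all regressor values identical (full underflow): flat fit
    return(list(phi = my, f0 = 0, beta = 0,
                sse = sum((y - my)^2), degenerate = TRUE))
  }
  beta <- sum((e - me) * (y - my)) / sxx
  phi <- my - beta * me
  res <- y - phi - beta * e
  # beta = f0u / (-kappa h)  =>  f0u = -beta kappa h  (ppb m/s)
  list(phi = phi, f0 = -beta * kappa * h * cv, beta = beta,
       sse = sum(res^2), degenerate = all(e[t > 0] == 0))
}

#' Fit the HMR model by profiled partial-linear least squares
#'
#' Minimises the conditional SSE of [hmr_profile_sse()] over `kappa`.
#' The profile is scanned on a log-spaced grid, then descended from a
#' mild-curvature starting value `kappa0 = log(1.5) / t_range` to the
#' nearest strict interior local minimum, which is refined by 1-D
#' minimisation on log kappa (relative tolerance ~1e-6).  The fit counts
#' as converged only when a strict interior optimum exists: the refined
#' kappa lies strictly inside `kappa_bounds` and its SSE is below both
#' boundary asymptotes of the profile, the linear fit (kappa -> 0) and
#' the degenerate two-level fit (kappa -> Inf).  Series whose profile
#' decreases monotonically into either boundary have no nonlinearity
#' optimum, and callers are expected to fall back to [fit_linear()] --
#' that fallback is part of every decision scheme, not of this fit.
#'
#' @param series a [conc_series()] with at least 4 samples.
#' @param kappa_bounds search interval for kappa, s^-1.
#' @param n_scan number of log-spaced scan points.
#' @return a `flux_fit` with method `"hmr"`; on convergence `params` is
#'   an [hmr_parameters()] and `flux` the fitted `f0`.  `se_flux` is the
#'   conditional (fixed-kappa) standard error.  Diagnostics record the
#'   linear and two-level boundary SSEs and the non-convergence reason
#'   if any.
#' @export
fit_hmr <- function(series, kappa_bounds = c(1e-7, 1), n_scan = 101L) {
  stopifnot(inherits(series, "conc_series"))
  if (!is.numeric(kappa_bounds) || length(kappa_bounds) != 2L ||
      any(kappa_bounds <= 0) || kappa_bounds[1L] >= kappa_bounds[2L])
    stop("'kappa_bounds' must be two increasing positive numbers")
  t <- series$times; y <- series$concentrations
  n <- length(t)
  klo <- kappa_bounds[1L]; khi <- kappa_bounds[2L]
  kgrid <- exp(seq(log(klo), log(khi), length.out = n_scan))

  lin <- stats::lm.fit(cbind(1, t), y)
  sse_lin <- sum(lin$residuals^2)
  # kappa -> Inf asymptote: first point isolated, remaining at their mean
  sse_inf <- sum((y[-1L] - mean(y[-1L]))^2)

  sse <- vapply(kgrid, function(k) hmr_profile_sse(series, k)$sse, numeric(1L))

  fail <- function(reason) {
    .flux_fit("hmr", converged = FALSE, n = n,
              diagnostics = list(reason = reason, sse_linear = sse_lin,
                                 sse_two_level = sse_inf))
  }

  # descend from the mild-curvature start to the nearest local minimum
  k0 <- log(1.5) / .t_meas(series)
  j <- which.min(abs(log(kgrid) - log(k0)))
  repeat {
    if (j > 1L && sse[j - 1L] < sse[j]) j <- j - 1L
    else if (j < n_scan && sse[j + 1L] < sse[j]) j <- j + 1L
    else break
  }
  if (j == 1L || j == n_scan)
    return(fail("kappa_at_bound"))
  if (!(sse[j] < sse[j - 1L] && sse[j] < sse[j + 1L]))
    return(fail("no_interior_optimum"))   # plateau, not a strict minimum

  obj <- function(lk) hmr_profile_sse(series, exp(lk))$sse
  opt <- stats::optimize(obj, interval = log(c(kgrid[j - 1L], kgrid[j + 1L])),
                         tol = 1e-7)
  kappa <- exp(opt$minimum)
  if (kappa <= klo * (1 + 1e-3) || kappa >= khi * (1 - 1e-3))
    return(fail("kappa_at_bound"))
  if (!is.finite(opt$objective) || opt$objective >= sse_lin ||
      opt$objective >= sse_inf)
    return(fail("no_interior_optimum"))

  prof <- hmr_profile_sse(series, kappa)
  h <- effective_height(series$system)
  cv <- .conv_factor(series$system)
  # conditional standard error of beta at fixed kappa, propagated to f0
  e <- exp(-kappa * t)
  sxx <- sum((e - mean(e))^2)
  se_beta <- sqrt(prof$sse / max(1L, n - 3L) / sxx)
  .flux_fit("hmr",
            flux = prof$f0,
            params = hmr_parameters(prof$phi, prof$f0, kappa),
            sse = prof$sse,
            aic = .aic_from_sse(prof$sse, n, .aic_k("hmr")),
            se_flux = se_beta * kappa * h * cv,
            converged = TRUE, n = n,
            diagnostics = list(sse_linear = sse_lin, sse_two_level = sse_inf))
}
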