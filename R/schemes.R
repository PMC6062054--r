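# Decision schemes: turn the base fits of one closure into a final flux.
#
# Every scheme picks either the linear or the HMR estimate; the kappa.max
# scheme bounds the fitted nonlinearity parameter by
# kappa_max = |f_lin| / (f_det * t_meas), so less nonlinearity is allowed
# for small fluxes and imprecise instruments.

.SCHEMES <- c("LR", "RLM", "HMR", "AIC", "GFACTOR", "KAPPAMAX", "FIXEDKAPPA")

#' Configure a flux calculation scheme
#'
#' @param scheme one of `"LR"` (ordinary linear), `"RLM"` (Huber robust
#'   linear), `"HMR"` (nonlinear with linear fallback), `"AIC"` (lower
#'   AIC of linear vs HMR), `"GFACTOR"` (HMR capped at `g_max` times the
#'   linear estimate), `"KAPPAMAX"` (HMR restricted by the dynamic kappa
#'   threshold) or `"FIXEDKAPPA"` (HMR restricted by a fixed kappa
#'   threshold in 1/h, the published "RF2017" variant).
#' @param g_max maximum allowed ratio of nonlinear to linear flux
#'   magnitude for `GFACTOR`; default 4.
#' @param f_det minimal detectable flux, nmol s^-1 m^-2; required for
#'   `KAPPAMAX` (see [simulate_f_det()]).
#' @param kappa_fixed fixed kappa threshold for `FIXEDKAPPA`, 1/h;
#'   default 20.
#' @param t_meas optional override of the measurement time used in the
#'   kappa.max threshold, s; by default the time difference between the
#'   first and last sample of each series.
#' @return an object of class `scheme_config`.
#' @export
scheme_config <- function(scheme = c("LR", "RLM", "HMR", "AIC", "GFACTOR",
                                     "KAPPAMAX", "FIXEDKAPPA"),
                          g_max = 4, f_det = NULL, kappa_fixed = 20,
                          t_meas = NULL) {
  scheme <- match.arg(scheme)
  if (!is.numeric(g_max) || length(g_max) != 1L || g_max <= 1)
    stop("'g_max' must be a single number > 1")
  if (scheme == "KAPPAMAX") {
    if (is.null(f_det) || !is.numeric(f_det) || length(f_det) != 1L ||
        !is.finite(f_det) || f_det <= 0)
      stop("scheme 'KAPPAMAX' needs a single positive 'f_det' ",
           "(simulate one with simulate_f_det())")
  }
  if (scheme == "FIXEDKAPPA" &&
      (!is.numeric(kappa_fixed) || length(kappa_fixed) != 1L || kappa_fixed <= 0))
    stop("scheme 'FIXEDKAPPA' needs a positive 'kappa_fixed' (1/h)")
  if (!is.null(t_meas) && (!is.numeric(t_meas) || length(t_meas) != 1L || t_meas <= 0))
    stop("'t_meas' override must be a single positive number (s)")
  structure(list(scheme = scheme, g_max = g_max, f_det = f_det,
                 kappa_fixed = kappa_fixed, t_meas = t_meas),
            class = "scheme_config")
}

#' @export
print.scheme_config <- function(x, ...) {
  extra <- switch(x$scheme,
    GFACTOR = sprintf(", g_max = %g", x$g_max),
    KAPPAMAX = sprintf(", f_det = %g nmol s^-1 m^-2", x$f_det),
    FIXEDKAPPA = sprintf(", kappa_fixed = %g h^-1", x$kappa_fixed),
    "")
  cat(sprintf("<scheme_config> %s%s%s\n", x$scheme, extra,
              if (is.null(x$t_meas)) "" else sprintf(", t_meas = %g s", x$t_meas)))
  invisible(x)
}

#' Dynamic upper bound on the HMR nonlinearity parameter
#'
#' `kappa_max = |f_lin| / (f_det * t_meas)`: the largest nonlinearity
#' the kappa.max scheme accepts, proportional to the linear flux
#' estimate and inversely proportional to the minimal detectable flux
#' and the deployment time.  The flux ratio is dimensionless; dividing
#' by the measurement time gives kappa its 1/time dimension.  The
#' absolute value extends the rule symmetrically to uptake fluxes.
#'
#' @param f_lin linear flux estimate, nmol s^-1 m^-2 (sign ignored).
#' @param f_det minimal detectable flux, nmol s^-1 m^-2; > 0.
#' @param t_meas measurement time (first to last sample), s; > 0.
#' @return the kappa threshold, s^-1.
#' @examples
#' kappa_max(0.28, 0.028, 2160)  # 10 / 2160 ~ 4.6e-3 s^-1
#' @export
kappa_max <- function(f_lin, f_det, t_meas) {
  if (!is.numeric(f_lin) || anyNA(f_lin)) stop("'f_lin' must be numeric")
  if (!isTRUE(all(f_det > 0))) stop("'f_det' must be > 0")
  if (!isTRUE(all(t_meas > 0))) stop("'t_meas' must be > 0")
  abs(f_lin) / (f_det * t_meas)
}

# Decision core shared by select_flux() and the simulation framework:
# takes precomputed fits so that one simulated series can be judged by
# many schemes (paired comparison).
.decide <- function(config, lin, hmr, rob = NULL, t_meas = NULL) {
  use_lin <- function(reason, kmax = NA_real_) {
    list(flux = lin$flux, chosen = "linear", reason = reason,
         kappa_max_value = kmax)
  }
  use_hmr <- function(reason, kmax = NA_real_) {
    list(flux = hmr$flux, chosen = "hmr", reason = reason,
         kappa_max_value = kmax)
  }
  switch(config$scheme,
    LR = list(flux = lin$flux, chosen = "linear", reason = "scheme_linear",
              kappa_max_value = NA_real_),
    RLM = list(flux = rob$flux, chosen = "robust_linear",
               reason = "scheme_robust", kappa_max_value = NA_real_),
    HMR = if (hmr$converged) use_hmr("hmr_ok") else use_lin("hmr_not_converged"),
    AIC = {
      if (!hmr$converged) use_lin("hmr_not_converged")
      else if (hmr$aic < lin$aic) use_hmr("aic_prefers_hmr")
      else use_lin("aic_prefers_linear")
    },
    GFACTOR = {
      if (!hmr$converged) use_lin("hmr_not_converged")
      else if (abs(hmr$flux) > config$g_max * abs(lin$flux))
        use_lin("g_factor_exceeded")
      else use_hmr("hmr_ok")
    },
    KAPPAMAX = {
      tm <- if (!is.null(config$t_meas)) config$t_meas else t_meas
      kmax <- kappa_max(lin$flux, config$f_det, tm)
      if (!hmr$converged) use_lin("hmr_not_converged", kmax)
      else if (hmr$params$kappa > kmax) use_lin("kappa_exceeds_max", kmax)
      else use_hmr("hmr_ok", kmax)
    },
    FIXEDKAPPA = {
      kfix <- config$kappa_fixed / 3600   # h^-1 -> s^-1
      if (!hmr$converged) use_lin("hmr_not_converged", kfix)
      else if (hmr$params$kappa > kfix) use_lin("kappa_exceeds_fixed", kfix)
      else use_hmr("hmr_ok", kfix)
    },
    stop("unknown scheme '", config$scheme, "'"))
}

#' Select the flux of one closure under a decision scheme
#'
#' Fits the base models the scheme needs (linear always, robust linear
#' for `RLM`, HMR for the nonlinear schemes) and applies the scheme's
#' decision rule.  Whenever the HMR fit does not converge, every
#' nonlinear scheme falls back to the linear estimate -- the fallback is
#' part of the scheme.
#'
#' @param series a [conc_series()].
#' @param config a [scheme_config()].
#' @return an object of class `flux_decision` with elements `flux`,
#'   `chosen` (tag of the fit used), `reason` (machine-readable rule
#'   code), the underlying `linear_fit`, `hmr_fit` (and `robust_fit` for
#'   RLM), and `kappa_max_value` (the threshold applied, where
#'   applicable, s^-1).
#' @export
select_flux <- function(series, config) {
  stopifnot(inherits(series, "conc_series"), inherits(config, "scheme_config"))
  lin <- fit_linear(series)
  rob <- if (config$scheme == "RLM") fit_robust_linear(series) else NULL
  hmr <- if (config$scheme %in% c("HMR", "AIC", "GFACTOR", "KAPPAMAX", "FIXEDKAPPA"))
    fit_hmr(series) else NULL
  d <- .decide(config, lin, hmr, rob, t_meas = .t_meas(series))
  structure(
    list(flux = d$flux, chosen = d$chosen, reason = d$reason,
         scheme = config$scheme, linear_fit = lin, hmr_fit = hmr,
         robust_fit = rob, kappa_max_value = d$kappa_max_value,
         id = series$id),
    class = "flux_decision")
}

#' @export
print.flux_decision <- function(x, ...) {
  cat(sprintf("<flux_decision:%s> flux = %.4g nmol s^-1 m^-2 (%s; %s)\n",
              x$scheme, x$flux, x$chosen, x$reason))
  invisible(x)
}

# geometric mean on a positive-shift convention: fluxes at or below zero
# are made positive by shifting with |min| + eps, and the shift is
# removed afterwards
.geometric_mean <- function(x, eps = 1e-6) {
  shift <- if (any(x <= 0)) abs(min(x)) + eps else 0
  exp(mean(log(x + shift))) - shift
}

#' Apply decision schemes to a batch of closures
#'
#' Fits every closure once and judges the shared fits under each
#' requested scheme, mirroring how a measurement campaign's dataset is
#' processed.  The summary reports, per scheme, the number of HMR fluxes
#' selected, the arithmetic and (shift-convention) geometric mean flux,
#' and the deviation ratio mean(scheme) / mean(LR).
#'
#' @param series_list a non-empty list of [conc_series()].
#' @param configs a single [scheme_config()] or a list of them.
#' @return a list of class `batch_decisions`: `decisions`, a long
#'   data.frame with one row per closure and scheme (columns `id`,
#'   `scheme`, `flux`, `chosen`, `reason`, `f_lin`, `f_hmr`, `kappa`,
#'   `kappa_max`), and `summary`, one row per scheme.
#' @export
batch_select <- function(series_list, configs) {
  if (inherits(configs, "scheme_config")) configs <- list(configs)
  if (!length(series_list)) stop("'series_list' must not be empty")
  if (!all(vapply(series_list, inherits, TRUE, "conc_series")))
    stop("'series_list' must contain conc_series objects")
  if (!all(vapply(configs, inherits, TRUE, "scheme_config")))
    stop("'configs' must contain scheme_config objects")

  need_rob <- any(vapply(configs, function(cf) cf$scheme == "RLM", TRUE))
  need_hmr <- any(vapply(configs, function(cf)
    cf$scheme %in% c("HMR", "AIC", "GFACTOR", "KAPPAMAX", "FIXEDKAPPA"), TRUE))

  n <- length(series_list)
  ids <- vapply(seq_along(series_list), function(i) {
    id <- series_list[[i]]$id
    if (is.null(id)) sprintf("closure_%04d", i) else as.character(id)
  }, character(1L))

  lin_fits <- lapply(series_list, fit_linear)
  rob_fits <- if (need_rob) lapply(series_list, fit_robust_linear)
  hmr_fits <- if (need_hmr) lapply(series_list, fit_hmr)
  tms <- vapply(series_list, .t_meas, numeric(1L))

  rows <- vector("list", length(configs))
  for (ci in seq_along(configs)) {
    cf <- configs[[ci]]
    dec <- lapply(seq_len(n), function(i)
      .decide(cf, lin_fits[[i]],
              if (need_hmr) hmr_fits[[i]],
              if (need_rob) rob_fits[[i]], tms[i]))
    rows[[ci]] <- data.frame(
      id = ids,
      scheme = cf$scheme,
      flux = vapply(dec, `[[`, numeric(1L), "flux"),
      chosen = vapply(dec, `[[`, character(1L), "chosen"),
      reason = vapply(dec, `[[`, character(1L), "reason"),
      f_lin = vapply(lin_fits, `[[`, numeric(1L), "flux"),
      f_hmr = if (need_hmr) vapply(hmr_fits, function(f)
        if (f$converged) f$flux else NA_real_, numeric(1L)) else NA_real_,
      kappa = if (need_hmr) vapply(hmr_fits, function(f)
        if (f$converged) f$params$kappa else NA_real_, numeric(1L)) else NA_real_,
      kappa_max = vapply(dec, `[[`, numeric(1L), "kappa_max_value"),
      stringsAsFactors = FALSE)
  }
  decisions <- do.call(rbind, rows)
  mean_lr <- mean(vapply(lin_fits, `[[`, numeric(1L), "flux"))

  summary <- do.call(rbind, lapply(rows, function(df) {
    data.frame(scheme = df$scheme[1L],
               n = n,
               n_hmr = sum(df$chosen == "hmr"),
               mean_flux = mean(df$flux),
               geom_mean_flux = .geometric_mean(df$flux),
               deviation_from_lr = mean(df$flux) / mean_lr,
               stringsAsFactors = FALSE)
  }))
  structure(list(decisions = decisions, summary = summary),
            class = "batch_decisions")
}

#' @export
print.batch_decisions <- function(x, ...) {
  cat(sprintf("<batch_decisions> %d closures x %d scheme(s)\n",
              x$summary$n[1L], nrow(x$summary)))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
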