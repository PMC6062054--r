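# Minimal detectable flux: the flux magnitude a chamber system can
# distinguish from zero given its instrument noise, estimated as an
# upper quantile of flux estimates over simulated zero-flux closures.

#' Simulate the minimal detectable flux of a chamber system
#'
#' Generates `n_sim` zero-flux closures (constant ambient concentration
#' plus i.i.d. Gaussian noise of the system's `sd_gc` at the given
#' sample times), estimates each flux under the requested scheme, and
#' returns the empirical `quantile` of the estimated fluxes.  For the
#' nonlinear schemes the linear fallback applies on non-convergence, as
#' in real processing.
#'
#' The noise matrix is drawn in a single call before any fitting, so two
#' runs with the same `seed` and `times` see identical concentrations
#' regardless of scheme -- detection limits of different schemes can be
#' compared on paired simulations.
#'
#' The `KAPPAMAX` scheme is rejected: its threshold consumes an `f_det`,
#' so its detection limit must be computed by passing a
#' `scheme_config("KAPPAMAX", f_det = ...)` built from another scheme's
#' result (conventionally the HMR-based one).
#'
#' @param system a [chamber_system()] with `sd_gc > 0`.
#' @param times sample times, s (at least 4).
#' @param scheme a scheme tag or a [scheme_config()]; default `"HMR"`,
#'   the population the kappa.max rule is defined on.  `"KAPPAMAX"` as a
#'   bare tag is a configuration error; a full `scheme_config` with its
#'   own `f_det` is accepted.
#' @param n_sim number of simulated closures; >= 100.
#' @param quantile probability of the empirical quantile, in (0, 1).
#' @param seed RNG seed; mandatory for reproducibility.
#' @param population `"fallback"` takes the quantile over all `n_sim`
#'   fluxes (linear fallback included); `"hmr_only"` restricts to
#'   closures where the HMR fit converged (only meaningful for the HMR
#'   scheme).
#' @param absolute take the quantile of |flux| instead of signed fluxes.
#' @return an object of class `f_det_result` with fields `f_det`,
#'   `quantile`, `n_sim`, `sd_gc`, `scheme`, `seed`, and the simulated
#'   `fluxes`.
#' @examples
#' sys <- chamber_system(0.014, 0.07, sd_gc = 3)
#' simulate_f_det(sys, times = c(0, 720, 1440, 2160), scheme = "LR",
#'                n_sim = 200, seed = 1)
#' @export
simulate_f_det <- function(system, times, scheme = "HMR", n_sim = 1000L,
                           quantile = 0.975, seed,
                           population = c("fallback", "hmr_only"),
                           absolute = FALSE) {
  stopifnot(inherits(system, "chamber_system"))
  population <- match.arg(population)
  if (missing(seed)) stop("'seed' is required for a reproducible simulation")
  if (!is.numeric(times) || length(times) < 4L || any(diff(times) <= 0))
    stop("'times' must be at least 4 strictly increasing sample times (s)")
  if (!isTRUE(n_sim >= 100)) stop("'n_sim' must be at least 100")
  if (!is.numeric(quantile) || length(quantile) != 1L ||
      quantile <= 0 || quantile >= 1)
    stop("'quantile' must lie strictly between 0 and 1")
  if (is.character(scheme)) {
    if (identical(scheme, "KAPPAMAX"))
      stop("the detection limit of 'KAPPAMAX' depends on an f_det input; ",
           "pass scheme_config('KAPPAMAX', f_det = ...) built from ",
           "another scheme's simulated f_det")
    config <- scheme_config(scheme)
  } else {
    stopifnot(inherits(scheme, "scheme_config"))
    config <- scheme
  }

  m <- length(times)
  set.seed(seed)
  noise <- matrix(stats::rnorm(n_sim * m, 0, system$sd_gc), n_sim, m)

  need_hmr <- config$scheme %in% c("HMR", "AIC", "GFACTOR", "KAPPAMAX", "FIXEDKAPPA")
  fluxes <- numeric(n_sim)
  conv <- logical(n_sim)
  tm <- diff(range(times))
  for (i in seq_len(n_sim)) {
    ser <- conc_series(times, system$c0_ambient + noise[i, ], system)
    lin <- fit_linear(ser)
    rob <- if (config$scheme == "RLM") fit_robust_linear(ser)
    hmr <- if (need_hmr) fit_hmr(ser)
    d <- .decide(config, lin, hmr, rob, tm)
    fluxes[i] <- d$flux
    conv[i] <- need_hmr && hmr$converged
  }
  pop <- if (population == "hmr_only") fluxes[conv] else fluxes
  if (!length(pop)) stop("no HMR fit converged; 'hmr_only' population is empty")
  val <- if (absolute) abs(pop) else pop
  structure(
    list(f_det = unname(stats::quantile(val, quantile, type = 7)),
         quantile = quantile, n_sim = n_sim, sd_gc = system$sd_gc,
         scheme = config$scheme, seed = seed, population = population,
         absolute = absolute, fluxes = fluxes, hmr_converged = conv),
    class = "f_det_result")
}

#' @export
print.f_det_result <- function(x, ...) {
  cat(sprintf(
    "<f_det_result> %s: f_det = %.4g nmol s^-1 m^-2 (q%.3g of %d zero fluxes, sd_gc = %g ppb)\n",
    x$scheme, x$f_det, x$quantile, x$n_sim, x$sd_gc))
  invisible(x)
}

#' Closed-form detection limit of the linear scheme
#'
#' For ordinary least squares on Gaussian noise the zero-flux estimate
#' is exactly normal with standard deviation
#' `sd_gc / sqrt(sum((t - tbar)^2))` in slope units, so the detection
#' limit is the normal quantile of that distribution scaled to flux
#' units.  Serves as the independent oracle for [simulate_f_det()] with
#' `scheme = "LR"`.
#'
#' @param system a [chamber_system()].
#' @param times sample times, s; at least 3 distinct values.
#' @param quantile probability, in (0, 1).
#' @param sd_gc noise standard deviation, ppb; defaults to the system's.
#' @return detection limit, nmol s^-1 m^-2.
#' @export
analytic_f_det_linear <- function(system, times, quantile = 0.975,
                                  sd_gc = system$sd_gc) {
  stopifnot(inherits(system, "chamber_system"))
  if (length(unique(times)) < 3L)
    stop("degenerate design: need at least 3 distinct sample times")
  if (!is.numeric(quantile) || quantile <= 0 || quantile >= 1)
    stop("'quantile' must lie strictly between 0 and 1")
  sxx <- sum((times - mean(times))^2)
  stats::qnorm(quantile) * sd_gc / sqrt(sxx) *
    effective_height(system) * .conv_factor(system)
}
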