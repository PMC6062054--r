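# Monte-Carlo simulation framework: generate noisy HMR series over a
# (f0 x kappa) grid, evaluate every scheme on the same simulated series,
# and map median / IQ90 / bias / MSE per cell.  This is the machinery
# behind the heatmap figures and the sensitivity sweeps.

#' Specify a simulation grid
#'
#' Defaults mirror a typical manual-chamber N2O study: 25 flux levels
#' spanning 0-5 nmol s^-1 m^-2 (0 plus a log-spaced sequence from 0.01),
#' 25 log-spaced kappa values from 1e-6 to 1e-2 s^-1, and 50 Monte-Carlo
#' replicates per cell.
#'
#' @param system a [chamber_system()].
#' @param times sample times, s.
#' @param f0_values true flux grid, nmol s^-1 m^-2; sorted, may include 0.
#' @param kappa_values true kappa grid, s^-1; sorted, all > 0.
#' @param n_mc replicates per cell; >= 2.
#' @param seed master seed; per-cell substreams are derived from it by
#'   counter, so results do not depend on evaluation order.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(system, times, f0_values = NULL, kappa_values = NULL,
                      n_mc = 50L, seed = 1L) {
  stopifnot(inherits(system, "chamber_system"))
  if (is.null(f0_values))
    f0_values <- c(0, exp(seq(log(0.01), log(5), length.out = 24L)))
  if (is.null(kappa_values))
    kappa_values <- exp(seq(log(1e-6), log(1e-2), length.out = 25L))
  if (!length(f0_values) || is.unsorted(f0_values, strictly = TRUE))
    stop("'f0_values' must be non-empty and strictly increasing")
  if (!length(kappa_values) || any(kappa_values <= 0) ||
      is.unsorted(kappa_values, strictly = TRUE))
    stop("'kappa_values' must be strictly increasing and > 0")
  if (!isTRUE(n_mc >= 2)) stop("'n_mc' must be at least 2")
  if (!is.numeric(times) || length(times) < 4L || any(diff(times) <= 0))
    stop("'times' must be at least 4 strictly increasing sample times (s)")
  structure(list(system = system, times = as.numeric(times),
                 f0_values = as.numeric(f0_values),
                 kappa_values = as.numeric(kappa_values),
                 n_mc = as.integer(n_mc), seed = as.integer(seed)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells (f0 %g-%g, kappa %g-%g), n_mc = %d, seed = %d\n",
              length(x$f0_values), length(x$kappa_values),
              min(x$f0_values), max(x$f0_values),
              min(x$kappa_values), max(x$kappa_values), x$n_mc, x$seed))
  invisible(x)
}

# noiseless concentration curve anchored at C(0) = c0_ambient;
# kappa = 0 (or below numerical resolution) is the straight-line limit
.true_conc <- function(f0, kappa, system, times) {
  h <- effective_height(system)
  f0u <- f0 / .conv_factor(system)   # ppb m s^-1
  c0 <- system$c0_ambient
  if (kappa <= 0)
    c0 + f0u * times / h
  else
    c0 + f0u / (kappa * h) * (1 - exp(-kappa * times))
}

#' Simulate one chamber closure from the HMR model
#'
#' Concentrations follow the HMR curve anchored so that the
#' concentration at closure equals the system's ambient baseline, plus
#' i.i.d. Gaussian noise with the system's `sd_gc`.  `kappa = 0` is
#' handled as the linear limit.
#'
#' @param f0 true initial flux, nmol s^-1 m^-2.
#' @param kappa true nonlinearity parameter, s^-1; >= 0.
#' @param system a [chamber_system()].
#' @param times sample times, s.
#' @param seed optional seed; when `NULL` the current RNG stream is
#'   used (callers that simulate many series seed once outside).
#' @return a [conc_series()].
#' @export
simulate_series <- function(f0, kappa, system, times, seed = NULL) {
  stopifnot(inherits(system, "chamber_system"))
  if (!isTRUE(kappa >= 0)) stop("'kappa' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  mu <- .true_conc(f0, kappa, system, times)
  conc_series(times, mu + stats::rnorm(length(times), 0, system$sd_gc), system)
}

# per-cell metric block
.cell_metrics <- function(est, chosen_hmr, f0_true) {
  qs <- stats::quantile(est, c(0.05, 0.95), type = 7, names = FALSE)
  m <- mean(est)
  bias <- m - f0_true
  variance <- mean((est - m)^2)
  data.frame(median_flux = stats::median(est), mean_flux = m,
             iq90 = qs[2L] - qs[1L], bias = bias, variance = variance,
             mse = bias^2 + variance, hmr_frac = mean(chosen_hmr))
}

#' Run the simulation grid for a set of schemes
#'
#' For every `(f0, kappa)` cell, `n_mc` noisy series are simulated once
#' and every scheme judges the same series (paired design: base fits are
#' computed once per series and shared).  Per cell and scheme the result
#' records the median and mean estimate, the IQ90 (95th minus 5th
#' percentile), bias (mean minus true f0), the population variance, the
#' MSE (`bias^2 + variance`, exactly), and the fraction of replicates in
#' which the HMR estimate was selected.
#'
#' @param spec a [grid_spec()].
#' @param schemes a [scheme_config()] or list of them.  A `KAPPAMAX`
#'   config must already carry its `f_det`.
#' @param keep_estimates retain the raw per-replicate estimates.
#' @return an object of class `sim_grid_result` with `spec`, `schemes`,
#'   `metrics` (long data.frame: `scheme`, `f0_true`, `kappa_true`,
#'   `n_mc`, metric columns) and optionally `estimates`.
#' @export
run_grid <- function(spec, schemes, keep_estimates = FALSE) {
  stopifnot(inherits(spec, "grid_spec"))
  if (inherits(schemes, "scheme_config")) schemes <- list(schemes)
  if (!length(schemes) || !all(vapply(schemes, inherits, TRUE, "scheme_config")))
    stop("'schemes' must be scheme_config objects")
  for (cf in schemes)
    if (cf$scheme == "KAPPAMAX" && is.null(cf$f_det))
      stop("KAPPAMAX scheme requires a precomputed f_det")

  need_rob <- any(vapply(schemes, function(cf) cf$scheme == "RLM", TRUE))
  need_hmr <- any(vapply(schemes, function(cf)
    cf$scheme %in% c("HMR", "AIC", "GFACTOR", "KAPPAMAX", "FIXEDKAPPA"), TRUE))
  tm <- diff(range(spec$times))
  nf <- length(spec$f0_values); nk <- length(spec$kappa_values)
  ns <- length(schemes)

  blocks <- vector("list", nf * nk * ns)
  est_rows <- if (keep_estimates) vector("list", nf * nk) else NULL
  bi <- 0L
  for (i in seq_len(nf)) for (j in seq_len(nk)) {
    ci <- (i - 1L) * nk + j
    cell_seed <- (spec$seed + 104729 * ci) %% 2147483647L
    if (cell_seed == 0L) cell_seed <- 1L
    set.seed(cell_seed)
    f0 <- spec$f0_values[i]; kap <- spec$kappa_values[j]
    est <- matrix(NA_real_, spec$n_mc, ns)
    hmr_sel <- matrix(FALSE, spec$n_mc, ns)
    for (r in seq_len(spec$n_mc)) {
      ser <- simulate_series(f0, kap, spec$system, spec$times)
      lin <- fit_linear(ser)
      rob <- if (need_rob) fit_robust_linear(ser)
      hmr <- if (need_hmr) fit_hmr(ser)
      for (s in seq_len(ns)) {
        d <- .decide(schemes[[s]], lin, hmr, rob, tm)
        est[r, s] <- d$flux
        hmr_sel[r, s] <- d$chosen == "hmr"
      }
    }
    for (s in seq_len(ns)) {
      bi <- bi + 1L
      blocks[[bi]] <- cbind(
        data.frame(scheme = schemes[[s]]$scheme, f0_true = f0,
                   kappa_true = kap, n_mc = spec$n_mc,
                   stringsAsFactors = FALSE),
        .cell_metrics(est[, s], hmr_sel[, s], f0))
    }
    if (keep_estimates)
      est_rows[[ci]] <- data.frame(
        scheme = rep(vapply(schemes, `[[`, character(1L), "scheme"),
                     each = spec$n_mc),
        f0_true = f0, kappa_true = kap,
        replicate = rep(seq_len(spec$n_mc), ns),
        flux = as.numeric(est), stringsAsFactors = FALSE)
  }
  structure(list(spec = spec, schemes = schemes,
                 metrics = do.call(rbind, blocks),
                 estimates = if (keep_estimates) do.call(rbind, est_rows)),
            class = "sim_grid_result")
}

#' @export
print.sim_grid_result <- function(x, ...) {
  cat(sprintf("<sim_grid_result> %d x %d cells, n_mc = %d, schemes: %s\n",
              length(x$spec$f0_values), length(x$spec$kappa_values),
              x$spec$n_mc,
              paste(vapply(x$schemes, `[[`, character(1L), "scheme"),
                    collapse = ", ")))
  invisible(x)
}

#' Sensitivity sweep over instrument precision or deployment time
#'
#' Re-runs the grid for each value of `sd_gc` (ppb) or `t_max` (minutes;
#' the four sample times are rescaled to 0, t/3, 2t/3, t).  For every
#' `KAPPAMAX` scheme the minimal detectable flux is re-simulated for the
#' swept conditions before the grid runs, because f_det itself depends
#' on the noise level and the sampling times.
#'
#' @param spec base [grid_spec()].
#' @param parameter `"sd_gc"` or `"t_max"`.
#' @param values values to sweep (ppb, or minutes for `t_max`).
#' @param schemes as in [run_grid()].
#' @param f_det_scheme,f_det_n,f_det_quantile how to re-simulate the
#'   f_det feeding KAPPAMAX.
#' @return a named list of `sim_grid_result`, one per value, each with
#'   attribute `swept_value`.
#' @export
sweep_parameter <- function(spec, parameter = c("sd_gc", "t_max"), values,
                            schemes, f_det_scheme = "HMR", f_det_n = 1000L,
                            f_det_quantile = 0.975) {
  stopifnot(inherits(spec, "grid_spec"))
  parameter <- match.arg(parameter)
  if (!length(values)) stop("'values' must be non-empty")
  if (inherits(schemes, "scheme_config")) schemes <- list(schemes)
  out <- vector("list", length(values))
  names(out) <- as.character(values)
  for (vi in seq_along(values)) {
    v <- values[vi]
    spec_v <- spec
    if (parameter == "sd_gc") {
      if (v < 0) stop("'sd_gc' values must be >= 0")
      spec_v$system$sd_gc <- v
    } else {
      if (v <= 0) stop("'t_max' values must be > 0 (minutes)")
      spec_v$times <- c(0, 1, 2, 3) / 3 * v * 60
    }
    schemes_v <- lapply(schemes, function(cf) {
      if (cf$scheme == "KAPPAMAX") {
        fd <- simulate_f_det(spec_v$system, spec_v$times, f_det_scheme,
                             n_sim = f_det_n, quantile = f_det_quantile,
                             seed = (spec$seed + 999983L) %% 2147483647L)
        cf$f_det <- fd$f_det
      }
      cf
    })
    res <- run_grid(spec_v, schemes_v)
    attr(res, "swept_value") <- v
    attr(res, "swept_parameter") <- parameter
    out[[vi]] <- res
  }
  out
}

# bin edges on the grid axes: geometric midpoints between positive
# neighbours, arithmetic midpoint where a neighbour is zero; open-ended
# outer bins so out-of-range values land in the extreme bins
.bin_edges <- function(values) {
  v1 <- values[-length(values)]; v2 <- values[-1L]
  mids <- ifelse(v1 > 0, sqrt(v1 * v2), (v1 + v2) / 2)
  c(-Inf, mids, Inf)
}

#' Project a measured (or fixture) dataset onto a simulation grid
#'
#' Bins every decision by its estimated flux and fitted kappa into the
#' grid's cells: fluxes beyond the flux range are counted in the extreme
#' flux bin, and closures whose kappa could not be fitted are counted in
#' the largest-kappa row (those fluxes come from linear regression).
#' The per-cell simulated metrics, weighted by the bin counts, estimate
#' the uncertainty (IQ90), bias and MSE the scheme imposes on the
#' dataset at hand.
#'
#' @param decisions a [batch_select()] result, or a data.frame with
#'   columns `flux` and `kappa` (NA kappa = not fitted).  If the batch
#'   holds several schemes, the rows matching `scheme` are used.
#' @param grid a [run_grid()] result containing `scheme`.
#' @param scheme scheme tag to project; defaults to the single scheme of
#'   the grid.
#' @return list of class `projection` with `histogram` (one row per
#'   grid cell: `f0_bin`, `kappa_bin`, `count`), `weighted` (count-
#'   weighted mean `iq90`, `bias`, `mse`), `scheme` and `n`.
#' @export
project_dataset <- function(decisions, grid, scheme = NULL) {
  stopifnot(inherits(grid, "sim_grid_result"))
  tags <- vapply(grid$schemes, `[[`, character(1L), "scheme")
  if (is.null(scheme)) {
    if (length(tags) != 1L)
      stop("grid holds several schemes; say which one to project")
    scheme <- tags
  }
  if (!scheme %in% tags) stop("grid has no metrics for scheme '", scheme, "'")
  if (inherits(decisions, "batch_decisions")) {
    df <- decisions$decisions
    if (scheme %in% df$scheme) df <- df[df$scheme == scheme, ]
  } else df <- decisions
  if (!is.data.frame(df) || !all(c("flux", "kappa") %in% names(df)))
    stop("'decisions' must provide columns 'flux' and 'kappa'")
  if (!nrow(df)) stop("empty decision list")

  fv <- grid$spec$f0_values; kv <- grid$spec$kappa_values
  fb <- findInterval(df$flux, .bin_edges(fv))
  kb <- findInterval(df$kappa, .bin_edges(kv))
  kb[is.na(df$kappa)] <- length(kv)   # unfitted kappa -> largest-kappa row

  counts <- table(factor(fb, levels = seq_along(fv)),
                  factor(kb, levels = seq_along(kv)))
  hist <- data.frame(
    f0_bin = rep(fv, times = length(kv)),
    kappa_bin = rep(kv, each = length(fv)),
    count = as.integer(counts))

  met <- grid$metrics[grid$metrics$scheme == scheme, ]
  key <- paste(signif(met$f0_true, 12), signif(met$kappa_true, 12))
  idx <- match(paste(signif(hist$f0_bin, 12), signif(hist$kappa_bin, 12)), key)
  w <- hist$count
  weighted <- list(
    iq90 = stats::weighted.mean(met$iq90[idx], w),
    bias = stats::weighted.mean(met$bias[idx], w),
    mse  = stats::weighted.mean(met$mse[idx], w))
  structure(list(histogram = hist, weighted = weighted,
                 scheme = scheme, n = nrow(df)),
            class = "projection")
}

#' @export
print.projection <- function(x, ...) {
  cat(sprintf("<projection> %d fluxes on the %s grid\n", x$n, x$scheme))
  cat(sprintf("  weighted IQ90 = %.4g, bias = %.4g, MSE = %.4g (flux units)\n",
              x$weighted$iq90, x$weighted$bias, x$weighted$mse))
  invisible(x)
}
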