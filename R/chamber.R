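#' Describe a static chamber measurement system
#'
#' Bundles the chamber geometry, the ambient conditions used for unit
#' conversion, and the analytical precision of the concentration
#' measurements.  Every downstream computation (flux fits, detection
#' limits, simulations) takes one of these objects.
#'
#' The effective chamber height is the headspace volume divided by the
#' covered soil area; pass `height` only to override that quotient (for
#' example when the deployed chamber sits on an extension ring).
#'
#' @param volume chamber headspace volume, m^3.
#' @param area covered soil area, m^2.
#' @param height optional explicit effective height, m. Defaults to
#'   `volume / area`.
#' @param temperature air temperature used for the ppb to nmol m^-3
#'   conversion, K.
#' @param pressure air pressure for the same conversion, Pa.
#' @param sd_gc precision of the concentration measurement (standard
#'   deviation of repeated ambient standards), ppb.
#' @param c0_ambient ambient baseline concentration at closure, ppb.
#' @return an object of class `chamber_system`.
#' @examples
#' # the case-study manual chamber (N2O, gas chromatograph at 3 ppb)
#' sys <- chamber_system(volume = 0.014, area = 0.07, sd_gc = 3)
#' effective_height(sys)  # 0.2 m
#' @export
chamber_system <- function(volume, area, height = NULL,
                           temperature = 293.15, pressure = 101325,
                           sd_gc = 3, c0_ambient = 325) {
  stopifnot(is.numeric(volume), length(volume) == 1L, is.finite(volume),
            is.numeric(area), length(area) == 1L, is.finite(area))
  if (volume <= 0) stop("'volume' must be > 0 m^3")
  if (area <= 0) stop("'area' must be > 0 m^2")
  if (!is.null(height) && (!is.numeric(height) || length(height) != 1L || height <= 0))
    stop("'height' override must be a single positive number (m)")
  if (!isTRUE(temperature > 0)) stop("'temperature' must be > 0 K")
  if (!isTRUE(pressure > 0)) stop("'pressure' must be > 0 Pa")
  if (!is.numeric(sd_gc) || length(sd_gc) != 1L || !is.finite(sd_gc) || sd_gc < 0)
    stop("'sd_gc' must be a single finite number >= 0 (ppb)")
  structure(
    list(volume = volume, area = area, height = height,
         temperature = temperature, pressure = pressure,
         sd_gc = sd_gc, c0_ambient = c0_ambient),
    class = "chamber_system")
}

#' Effective chamber height
#'
#' Returns the explicit `height` override when the system carries one,
#' otherwise `volume / area`.
#'
#' @param system a [chamber_system()].
#' @return height, m.
#' @export
effective_height <- function(system) {
  stopifnot(inherits(system, "chamber_system"))
  if (!is.null(system$height)) system$height else system$volume / system$area
}

#' @export
print.chamber_system <- function(x, ...) {
  cat("<chamber_system>\n")
  cat(sprintf("  volume: %g m^3, area: %g m^2, effective height: %g m%s\n",
              x$volume, x$area, effective_height(x),
              if (is.null(x$height)) " (V/A)" else " (override)"))
  cat(sprintf("  T: %g K, p: %g Pa, sd_gc: %g ppb, ambient: %g ppb\n",
              x$temperature, x$pressure, x$sd_gc, x$c0_ambient))
  invisible(x)
}

#' One chamber closure's concentration time series
#'
#' @param times sample times since closure, s; strictly increasing,
#'   first time >= 0.  At least 4 samples are required, the minimum for
#'   a nonlinear fit.
#' @param concentrations trace gas mole fractions, ppb; same length as
#'   `times`.
#' @param system the [chamber_system()] the closure was measured with.
#' @param id optional closure identifier used in messages and outputs.
#' @return an object of class `conc_series`.
#' @export
conc_series <- function(times, concentrations, system, id = NULL) {
  stopifnot(inherits(system, "chamber_system"))
  lbl <- if (is.null(id)) "" else sprintf(" (closure '%s')", id)
  if (!is.numeric(times) || !is.numeric(concentrations))
    stop("'times' and 'concentrations' must be numeric", lbl)
  if (length(times) != length(concentrations))
    stop(sprintf("'times' and 'concentrations' must have equal length%s", lbl))
  if (length(times) < 4L)
    stop(sprintf("at least 4 samples are required%s", lbl))
  if (anyNA(times) || anyNA(concentrations) ||
      any(!is.finite(times)) || any(!is.finite(concentrations)))
    stop(sprintf("non-finite values in series%s", lbl))
  if (times[1L] < 0) stop(sprintf("first sample time must be >= 0%s", lbl))
  if (any(diff(times) <= 0))
    stop(sprintf("sample times must be strictly increasing%s", lbl))
  structure(
    list(times = as.numeric(times),
         concentrations = as.numeric(concentrations),
         system = system, id = id),
    class = "conc_series")
}

#' @export
print.conc_series <- function(x, ...) {
  cat(sprintf("<conc_series%s> %d samples over %g s\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              length(x$times), diff(range(x$times))))
  print(data.frame(time_s = x$times, conc_ppb = x$concentrations),
        row.names = FALSE)
  invisible(x)
}

# deployment duration: last minus first sample time
.t_meas <- function(series) {
  diff(range(series$times))
}
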