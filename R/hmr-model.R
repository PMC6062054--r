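# Forward Hutchinson-Mosier (HMR) concentration model.
#
# In the Pedersen parameterization the headspace concentration during a
# closure is
#
#     C(t) = phi + f0 * exp(-kappa t) / (-kappa h)
#
# where phi is the constant source concentration the chamber converges
# to, f0 the initial flux at closure (the flux undisturbed by the
# chamber's feedback on the diffusion gradient), kappa > 0 the
# nonlinearity shape parameter (1/s) and h the effective chamber height.
# The instantaneous flux implied at time t is f0 * exp(-kappa t); as
# kappa -> 0 the curve degenerates to a straight line of slope f0 / h.

#' HMR model parameters
#'
#' @param phi asymptotic source concentration, ppb.
#' @param f0 initial flux at closure, nmol s^-1 m^-2. May be negative
#'   (uptake).
#' @param kappa nonlinearity shape parameter, s^-1; must be > 0.
#' @return an object of class `hmr_parameters`.
#' @export
hmr_parameters <- function(phi, f0, kappa) {
  stopifnot(is.numeric(phi), is.numeric(f0), is.numeric(kappa),
            length(phi) == 1L, length(f0) == 1L, length(kappa) == 1L)
  if (!is.finite(kappa) || kappa <= 0)
    stop("'kappa' must be a finite number > 0 (s^-1)")
  structure(list(phi = phi, f0 = f0, kappa = kappa), class = "hmr_parameters")
}

#' @export
print.hmr_parameters <- function(x, ...) {
  cat(sprintf("<hmr_parameters> phi = %g ppb, f0 = %g nmol s^-1 m^-2, kappa = %g s^-1\n",
              x$phi, x$f0, x$kappa))
  invisible(x)
}

#' Evaluate the HMR concentration curve
#'
#' Computes `C(t) = phi + f0 * exp(-kappa t) / (-kappa h)` with `f0`
#' converted from flux units (nmol s^-1 m^-2) to ppb m s^-1 using the
#' system's temperature and pressure.  The curve is monotone
#' non-decreasing for `f0 > 0` and converges to `phi` as `t` grows.
#'
#' @param t time since closure, s; may be a vector.
#' @param params an [hmr_parameters()] object (kappa > 0).
#' @param system a [chamber_system()] providing the effective height and
#'   the unit-conversion conditions.
#' @return concentration(s), ppb.
#' @examples
#' sys <- chamber_system(0.014, 0.07)
#' p <- hmr_parameters(phi = 455, f0 = 1, kappa = 1e-3)
#' hmr_concentration(c(0, 720, 1440, 2160), p, sys)
#' @export
hmr_concentration <- function(t, params, system) {
  stopifnot(inherits(params, "hmr_parameters"), inherits(system, "chamber_system"))
  if (!is.numeric(t) || anyNA(t) || any(t < 0))
    stop("'t' must be numeric and >= 0 (s)")
  if (params$kappa <= 0) stop("'kappa' must be > 0")
  h <- effective_height(system)
  f0u <- params$f0 / .conv_factor(system)   # ppb m s^-1
  params$phi + f0u * exp(-params$kappa * t) / (-params$kappa * h)
}
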