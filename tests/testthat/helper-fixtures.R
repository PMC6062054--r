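# Shared fixtures: the case-study manual chamber system and series
# builders.  Everything is generated in code; no files.

case_system <- function(sd_gc = 3, ...) {
  chamber_system(volume = 0.014, area = 0.07, sd_gc = sd_gc, ...)
}

case_times <- c(0, 720, 1440, 2160)   # 0/12/24/36 min

# nmol m^-3 per ppb at the default conversion conditions, written out
# independently of the package's converter
conv_ref <- 101325 / (8.314462618 * 293.15)

# noiseless HMR series (kappa >= 0; 0 = linear limit), built from first
# principles rather than through simulate_series
exact_series <- function(f0, kappa, system = case_system(sd_gc = 0),
                         times = case_times) {
  h <- system$volume / system$area
  f0u <- f0 / conv_ref
  mu <- if (kappa <= 0) system$c0_ambient + f0u * times / h
        else system$c0_ambient + f0u / (kappa * h) * (1 - exp(-kappa * times))
  conc_series(times, mu, system)
}

noisy_series <- function(f0, kappa, sd_gc = 3, system = case_system(sd_gc = sd_gc),
                         times = case_times) {
  s <- exact_series(f0, kappa, chamber_system(system$volume, system$area,
                                              sd_gc = 0), times)
  conc_series(times, s$concentrations + rnorm(length(times), 0, sd_gc),
              system)
}

# independent profile SSE for a fixed kappa: plain closed-form simple
# regression of concentration on exp(-kappa t), no package code involved
oracle_profile_sse <- function(times, conc, kappa) {
  e <- exp(-kappa * times)
  fit <- stats::lm.fit(cbind(1, e), conc)
  sum(fit$residuals^2)
}
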