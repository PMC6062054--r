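# Reading and writing chamber flux tables, and a synthetic fixture
# generator emulating a multi-year field campaign.  Chamber data has no
# community standard file format; plain delimited text with declared
# columns is used throughout.

#' Read a chamber closure table
#'
#' Expects a delimited text file with one row per gas sample and columns
#' `closure` (identifier), `time` and `concentration` (ppb).  Lines
#' starting with `#` are ignored.  Times are converted to seconds since
#' each closure's first sample.
#'
#' @param path file path.
#' @param system a [chamber_system()] describing the setup the table was
#'   measured with.
#' @param time_unit unit of the `time` column: `"min"` (default) or
#'   `"s"`.
#' @param sep field separator; comma by default, use `"\t"` for TSV.
#' @return a named list of [conc_series()], one per closure, in order of
#'   first appearance.
#' @export
read_chamber_table <- function(path, system, time_unit = c("min", "s"),
                               sep = ",") {
  stopifnot(inherits(system, "chamber_system"))
  time_unit <- match.arg(time_unit)
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("closure", "time", "concentration")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(df$time) || !is.numeric(df$concentration))
    stop("'time' and 'concentration' must be numeric")
  fac <- factor(df$closure, levels = unique(df$closure))
  out <- lapply(split(df, fac), function(d) {
    tt <- d$time * if (time_unit == "min") 60 else 1
    if (anyDuplicated(tt))
      stop("duplicate sample time in closure '", d$closure[1L], "'")
    o <- order(tt)
    tryCatch(
      conc_series(tt[o] - tt[o][1L], d$concentration[o], system,
                  id = as.character(d$closure[1L])),
      error = function(e)
        stop("closure '", d$closure[1L], "': ", conditionMessage(e),
             call. = FALSE))
  })
  names(out) <- levels(fac)
  out
}

#' Write chamber closures back to a delimited table
#'
#' Inverse of [read_chamber_table()]; a round trip preserves every
#' numeric value to full double precision.
#'
#' @param series_list list of [conc_series()].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_chamber_table <- function(series_list, path, sep = ",") {
  if (!length(series_list)) stop("empty payload")
  rows <- lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    id <- if (is.null(s$id)) sprintf("closure_%04d", i) else s$id
    data.frame(closure = id, time = s$times / 60,
               concentration = s$concentrations, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# chamber closure table: time in minutes since closure, concentration in ppb", con)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write flux decisions or grid metrics to a delimited file
#'
#' Long-format output with a `#` header naming the units; readable back
#' with `read.csv(..., comment.char = "#")`.
#'
#' @param x a [batch_select()] result, a [run_grid()] result, or a
#'   plain data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  if (inherits(x, "batch_decisions")) {
    header <- "# flux decisions: flux/f_lin/f_hmr in nmol s^-1 m^-2, kappa/kappa_max in s^-1"
    df <- x$decisions
  } else if (inherits(x, "sim_grid_result")) {
    header <- "# simulation grid metrics: fluxes/bias/iq90 in nmol s^-1 m^-2, mse in (nmol s^-1 m^-2)^2, kappa in s^-1"
    df <- x$metrics
  } else if (is.data.frame(x)) {
    header <- "# kappamax results table"
    df <- x
  } else stop("don't know how to write an object of class ",
              paste(class(x), collapse = "/"))
  if (!nrow(df)) stop("empty payload")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate a synthetic fixture dataset emulating a field campaign
#'
#' Draws per-closure true parameters -- fluxes from a clipped log-normal
#' with a point mass of exact zeros, kappa log-uniform -- simulates
#' noisy concentration series through the HMR model, and returns the
#' series together with the ground-truth table needed for
#' parameter-recovery tests.  The defaults emulate the scale of a
#' multi-year manual-chamber N2O campaign (thousands of closures, most
#' fluxes a few tenths of nmol s^-1 m^-2, occasional large emissions).
#'
#' This is synthetic data: draws are independent across closures, noise
#' is Gaussian and homoscedastic, and the true curvature always follows
#' the HMR form, none of which field data guarantees.
#'
#' @param n_fluxes number of closures; >= 1.
#' @param system a [chamber_system()].
#' @param times sample times, s.
#' @param seed RNG seed (required; the result is a pure function of it).
#' @param flux_meanlog,flux_sdlog log-normal parameters of the positive
#'   flux distribution, nmol s^-1 m^-2.
#' @param flux_range positive fluxes are clipped into this range.
#' @param zero_frac fraction of exact zero-flux closures.
#' @param kappa_range log-uniform range of the true kappa, s^-1.
#' @return list with `series` (named list of [conc_series()]) and
#'   `truth` (data.frame `id`, `f0_true`, `kappa_true`).
#' @export
generate_fixture_dataset <- function(n_fluxes, system,
                                     times = c(0, 720, 1440, 2160), seed,
                                     flux_meanlog = log(0.15),
                                     flux_sdlog = 1.2,
                                     flux_range = c(0.01, 5),
                                     zero_frac = 0.1,
                                     kappa_range = c(1e-6, 1e-2)) {
  stopifnot(inherits(system, "chamber_system"))
  if (missing(seed)) stop("'seed' is required for a reproducible fixture")
  if (!isTRUE(n_fluxes >= 1)) stop("'n_fluxes' must be >= 1")
  if (!is.numeric(flux_range) || length(flux_range) != 2L ||
      any(flux_range <= 0) || diff(flux_range) <= 0)
    stop("'flux_range' must be two increasing positive numbers")
  if (!is.numeric(kappa_range) || length(kappa_range) != 2L ||
      any(kappa_range <= 0) || diff(kappa_range) <= 0)
    stop("'kappa_range' must be two increasing positive numbers")
  if (!is.numeric(zero_frac) || zero_frac < 0 || zero_frac >= 1)
    stop("'zero_frac' must be in [0, 1)")
  set.seed(seed)
  n <- as.integer(n_fluxes)
  f0 <- pmin(pmax(stats::rlnorm(n, flux_meanlog, flux_sdlog),
                  flux_range[1L]), flux_range[2L])
  f0[stats::runif(n) < zero_frac] <- 0
  kap <- exp(stats::runif(n, log(kappa_range[1L]), log(kappa_range[2L])))
  ids <- sprintf("closure_%05d", seq_len(n))
  series <- vector("list", n)
  for (i in seq_len(n)) {
    series[[i]] <- simulate_series(f0[i], kap[i], system, times)
    series[[i]]$id <- ids[i]
  }
  names(series) <- ids
  list(series = series,
       truth = data.frame(id = ids, f0_true = f0, kappa_true = kap,
                          stringsAsFactors = FALSE))
}
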