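#' Configuration for the synthetic time-series generator
#'
#' Describes a data-generating process mimicking an environmental
#' time-series study: a temperature-like exposure (seasonal cycle plus
#' autocorrelated noise) drives an overdispersed daily count outcome through
#' a known exposure-lag-response surface on the log scale, on top of a
#' seasonal baseline. Because the true surface is known, fitted models can
#' be checked against exact ground truth via [true_contrast()].
#'
#' The surface `f(x, l)` gives the log-rate contribution of an exposure `x`
#' experienced `l` days earlier, stored as a contrast: `f(reference, l) = 0`
#' for all lags. Presets (see [make_surface()]) cover the qualitative shapes
#' seen in temperature-mortality work: none, linear with decaying lag
#' structure, U-shaped with decaying lag structure, and U-shaped with an
#' immediate heat arm and a delayed cold arm.
#'
#' Defaults are sized like a mid-latitude city series: mean exposure 12
#' (degrees C) with seasonal amplitude 8 and day-to-day sd 3 at lag-1
#' autocorrelation 0.7; baseline around 50 events/day with a mild seasonal
#' cycle; dispersion 1.5 (counts overdispersed, variance = 1.5 x mean);
#' maximum lag 30 days.
#'
#' @param n_days series length (must exceed `max_lag`).
#' @param surface a function `f(x, l)` vectorized in `x`, or the name of a
#'   preset for [make_surface()]: `"null"`, `"linear_decay"`,
#'   `"ushape_decay"`, `"ushape_delayed_cold"`.
#' @param reference exposure value at which the surface is zero at all lags.
#' @param exposure list: `ar` (lag-1 autocorrelation of the noise, in
#'   (-1, 1)), `seasonal_amplitude`, `mean`, `sd` (marginal sd of the noise).
#' @param baseline list: `intercept` (log scale), `seasonal_amplitude` (log
#'   scale), `trend` (log-scale slope per day).
#' @param dispersion variance-to-mean ratio of the counts, >= 1. 1 gives
#'   Poisson counts; above 1, negative binomial with variance
#'   `dispersion * mu`.
#' @param max_lag maximum lag `L` of the surface.
#' @param seed integer seed; every stochastic draw is determined by it.
#' @return an object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_days = 400, surface = "ushape_decay", seed = 7)
#' dat <- simulate_series(cfg)
#' head(dat)
#' @export
sim_config <- function(n_days = 1826,
                       surface = "null",
                       reference = 20,
                       exposure = list(),
                       baseline = list(),
                       dispersion = 1.5,
                       max_lag = 30,
                       seed = 1L) {
  exposure <- utils::modifyList(
    list(ar = 0.7, seasonal_amplitude = 8, mean = 12, sd = 3), exposure)
  baseline <- utils::modifyList(
    list(intercept = log(50), seasonal_amplitude = 0.15, trend = 0), baseline)
  if (abs(exposure$ar) >= 1)
    stop("AR(1) coefficient must lie strictly inside (-1, 1)")
  if (dispersion < 1) stop("dispersion must be >= 1")
  n_days <- as.integer(n_days)
  max_lag <- as.integer(max_lag)
  if (n_days <= max_lag) stop("n_days must exceed max_lag")
  f <- if (is.character(surface)) make_surface(surface, reference) else surface
  if (!is.function(f)) stop("surface must be a function f(x, l) or a preset name")
  at_ref <- vapply(0:max_lag, function(l) max(abs(f(reference, l))),
                   numeric(1))
  if (max(at_ref) > 1e-12)
    stop("surface must be a contrast: f(reference, l) = 0 for all lags")
  structure(list(n_days = n_days, surface = f, reference = reference,
                 exposure = exposure, baseline = baseline,
                 dispersion = dispersion, max_lag = max_lag,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Preset exposure-lag-response surfaces
#'
#' Named true surfaces for the generator, all stored as contrasts against
#' `reference` (zero there at every lag):
#' \describe{
#'   \item{`null`}{no exposure effect.}
#'   \item{`linear_decay`}{log-linear in exposure, effect decaying
#'     exponentially over lags: `slope * (x - ref) * exp(-l / tau)`.}
#'   \item{`ushape_decay`}{quadratic (U-shaped) in exposure around the
#'     reference, decaying exponentially over lags:
#'     `height * ((x - ref) / 10)^2 * exp(-l / tau)`.}
#'   \item{`ushape_delayed_cold`}{U-shaped with asymmetric lag structure:
#'     the heat arm (`x > ref`) acts immediately and decays fast, the cold
#'     arm (`x < ref`) peaks around lag 2-3 and persists longer.}
#' }
#'
#' @param name preset name.
#' @param reference exposure of zero effect.
#' @param slope,height,tau shape parameters on the log-rate scale.
#' @return a function `f(x, l)`, vectorized in `x`.
#' @export
make_surface <- function(name = c("null", "linear_decay", "ushape_decay",
                                  "ushape_delayed_cold"),
                         reference = 20, slope = 0.003, height = 0.08,
                         tau = 3) {
  name <- match.arg(name)
  force(reference); force(slope); force(height); force(tau)
  switch(name,
    null = function(x, l) rep(0, length(x)),
    linear_decay = function(x, l)
      slope * (x - reference) * exp(-l / tau),
    ushape_decay = function(x, l)
      height * ((x - reference) / 10)^2 * exp(-l / tau),
    ushape_delayed_cold = function(x, l) {
      heat <- height * (pmax(x - reference, 0) / 10)^2 * exp(-l / 2)
      cold <- 0.6 * height * (pmax(reference - x, 0) / 10)^2 *
        ((l + 1) / 3) * exp(-l / 4)
      heat + cold
    })
}

#' Simulate the exposure series
#'
#' Generates `x_t = mean + A * cos(2 pi t / 365.25) + e_t` where `e_t` is a
#' stationary AR(1) process with lag-1 autocorrelation `ar` and marginal
#' standard deviation `sd`. Fully determined by `config$seed`.
#'
#' @param config a [sim_config()].
#' @return numeric vector of length `config$n_days`.
#' @export
simulate_exposure <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$exposure
  set.seed(config$seed)
  n <- config$n_days
  t <- seq_len(n)
  seasonal <- p$seasonal_amplitude * cos(2 * pi * t / 365.25)
  rho <- p$ar
  e <- numeric(n)
  e[1] <- stats::rnorm(1, 0, p$sd)
  if (n > 1) {
    innov <- stats::rnorm(n - 1, 0, p$sd * sqrt(1 - rho^2))
    for (i in 2:n) e[i] <- rho * e[i - 1] + innov[i - 1]
  }
  p$mean + seasonal + e
}

#' Simulate daily counts from the true surface
#'
#' The log mean on day `t` adds the baseline (intercept, seasonal cycle,
#' linear trend) and the accumulated surface contributions of the exposure
#' history, `sum_l f(x_{t-l}, l)`. For the first `max_lag` days the history
#' is incomplete; counts are still emitted using the available lags but the
#' days are flagged as burn-in, and should be excluded from fitting.
#' Counts are Poisson when `dispersion = 1`, otherwise negative binomial
#' parameterized so that `Var(Y) = dispersion * mu`.
#'
#' Draws are determined by `config$seed` (offset from the exposure stream so
#' that the pair of series is jointly reproducible).
#'
#' @param config a [sim_config()].
#' @param exposure exposure series of length `config$n_days`, typically from
#'   [simulate_exposure()].
#' @return integer vector of counts with attribute `burnin` (logical
#'   vector) and `mu` (the true means).
#' @export
simulate_counts <- function(config, exposure) {
  stopifnot(inherits(config, "sim_config"))
  if (length(exposure) != config$n_days)
    stop("exposure length must equal n_days")
  n <- config$n_days
  L <- config$max_lag
  b <- config$baseline
  t <- seq_len(n)
  eta <- b$intercept + b$seasonal_amplitude * cos(2 * pi * t / 365.25) +
    b$trend * t
  Q <- build_lag_matrix(exposure, L)
  contrib <- matrix(0, n, L + 1L)
  for (l in 0:L) {
    xl <- Q[, l + 1L]
    ok <- !is.na(xl)
    contrib[ok, l + 1L] <- config$surface(xl[ok], l)
  }
  eta <- eta + rowSums(contrib)
  if (max(eta) > 20)
    stop("simulated log-mean exceeds 20 (mean > 4.8e8); ",
         "rescale the surface or baseline")
  mu <- exp(eta)
  set.seed(config$seed + 1L)
  y <- if (config$dispersion == 1) {
    stats::rpois(n, mu)
  } else {
    stats::rnbinom(n, mu = mu, size = mu / (config$dispersion - 1))
  }
  structure(y, burnin = t <= L, mu = mu)
}

#' Simulate a full analysis-ready series
#'
#' Convenience wrapper: exposure plus counts as a data frame in the standard
#' input layout (`date`, `count`, `exposure`, `burnin`), with consecutive
#' calendar dates starting at `start`.
#'
#' @param config a [sim_config()].
#' @param start first date of the series.
#' @return a `data.frame`.
#' @export
simulate_series <- function(config, start = as.Date("2000-01-01")) {
  x <- simulate_exposure(config)
  y <- simulate_counts(config, x)
  data.frame(date = start + seq_len(config$n_days) - 1L,
             count = as.integer(y), exposure = x,
             burnin = attr(y, "burnin"))
}

#' True lag-specific and overall contrasts of the simulated surface
#'
#' Ground truth for recovery tests: the vector
#' `f(x_p, l) - f(reference, l)` over lags `0..max_lag` and its sum, exactly
#' what [predict_grid()] estimates at exposure `x_p`.
#'
#' @param config a [sim_config()].
#' @param x_p exposure value of interest.
#' @param reference contrast reference; defaults to the config reference.
#' @return list with `lag`, `contrast` (length `max_lag + 1`) and `overall`.
#' @export
true_contrast <- function(config, x_p, reference = config$reference) {
  stopifnot(inherits(config, "sim_config"))
  lags <- 0:config$max_lag
  v <- vapply(lags, function(l)
    config$surface(x_p, l) - config$surface(reference, l), numeric(1))
  list(lag = lags, contrast = v, overall = sum(v))
}

#' Write a simulated series and its true surface to disk
#'
#' Emits the standard input CSV (`date`, `count`, `exposure`) and, when
#' `truth_path` is given, a JSON file with the true contrast surface
#' evaluated on a grid of exposures, for oracle comparisons downstream.
#'
#' @param config a [sim_config()].
#' @param csv_path path for the series CSV.
#' @param truth_path optional path for the truth JSON.
#' @param exposures exposure grid for the truth surface; default 25 values
#'   across the simulated range.
#' @return the data frame, invisibly.
#' @export
write_series <- function(config, csv_path, truth_path = NULL,
                         exposures = NULL) {
  dat <- simulate_series(config)
  utils::write.csv(dat[, c("date", "count", "exposure")], csv_path,
                   row.names = FALSE)
  if (!is.null(truth_path)) {
    if (is.null(exposures))
      exposures <- seq(min(dat$exposure), max(dat$exposure), length.out = 25)
    truth <- lapply(exposures, function(x) {
      tc <- true_contrast(config, x)
      list(exposure = x, contrast = tc$contrast, overall = tc$overall)
    })
    jsonlite::write_json(
      list(reference = config$reference, max_lag = config$max_lag,
           dispersion = config$dispersion, seed = config$seed,
           grid = truth),
      truth_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(dat)
}
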