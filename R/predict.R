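#' Prediction grid of lag-specific and overall effects
#'
#' Builds the grid of predicted effects over (exposure value, lag) implied by
#' a fitted cross-basis, together with standard errors, and the overall
#' effects obtained by summing the contributions at each lag. All effects
#' are expressed on the linear-predictor scale as contrasts against a
#' reference exposure: the effect at `(x_p, l)` is
#' \deqn{a(x_p, l)^{\mathsf T}\,\hat\eta, \qquad
#'   a(x_p, l) = (z(x_p) - z(x_{ref})) \otimes c(l),}
#' where `z()` is the predictor-space basis transform, `c(l)` the row of the
#' lag-basis matrix at lag `l`, and \eqn{\hat\eta} the cross-basis
#' coefficients; its standard error is
#' \eqn{\sqrt{a^{\mathsf T} V(\hat\eta)\, a}}. The overall effect at `x_p`
#' uses the lag-summed contrast \eqn{a_{tot}(x_p) = \sum_l a(x_p, l)}, whose
#' variance accounts for all covariances among coefficients. At each lag the
#' transformed exposure is simply repeated: the grid describes the effect
#' profile of an exposure held at `x_p`, not a temporal exposure sequence.
#'
#' The reference contrast makes effects interpretable as (log) relative
#' risks versus the reference. For bases through the origin (linear,
#' threshold) `reference = NULL` requests uncentered effects, i.e. contrasts
#' against a zero basis row.
#'
#' @param fit a [extract_fit()] or [read_fit_interchange()] result.
#' @param cb the `crossbasis` used in the fit (a skeleton rebuilt with
#'   [crossbasis_from_recipe()] works too).
#' @param exposures predictor values for the grid rows; default is 50
#'   equally spaced values spanning the observed exposure range. Values
#'   outside the range are allowed with a warning (natural splines
#'   extrapolate linearly).
#' @param reference exposure value all effects are contrasted against, or
#'   `NULL` for uncentered effects (origin-based bases only).
#' @return An object of class `prediction_grid`: list with `exposures`,
#'   `lags` (`0:L`), matrices `E` and `E_sd` (`m x (L+1)`), vectors `e_tot`
#'   and `e_tot_sd`, `reference`, `link`, and the cross-basis `recipe`.
#' @export
predict_grid <- function(fit, cb, exposures = NULL, reference) {
  stopifnot(inherits(fit, "fitted_crossbasis"), inherits(cb, "crossbasis"))
  if (!identical(unname(fit$column_order), unname(attr(cb, "column_order"))))
    stop("column order of the fit does not match the cross-basis")
  var_spec <- attr(cb, "var_spec")
  lag_spec <- attr(cb, "lag_spec")
  L <- attr(cb, "L")
  rng <- attr(cb, "exposure_range")
  if (is.null(exposures))
    exposures <- seq(rng[1], rng[2], length.out = 50)
  exposures <- sort(unique(as.numeric(exposures)))
  if (any(exposures < rng[1] | exposures > rng[2]))
    warning("some prediction exposures lie outside the observed range [",
            signif(rng[1], 4), ", ", signif(rng[2], 4),
            "]; spline effects there are linear extrapolations")
  if (missing(reference))
    stop("a reference exposure must be supplied (or NULL for uncentered ",
         "effects with origin-based bases)")
  centred <- !is.null(reference)
  if (!centred && !var_spec$kind %in% c("linear", "threshold"))
    stop("uncentered effects are only meaningful for bases through the ",
         "origin (linear, threshold); supply a reference exposure")

  Zp <- unclass(evaluate_basis(var_spec, exposures, warn_range = FALSE))
  zref <- if (centred)
    unclass(evaluate_basis(var_spec, reference, warn_range = FALSE))[1L, ]
  else rep(0, ncol(Zp))
  Zc <- sweep(Zp, 2L, zref)
  C <- unclass(evaluate_basis(lag_spec, 0:L, warn_range = FALSE))
  v_x <- ncol(Zc); v_l <- ncol(C)
  eta <- unname(fit$eta_hat)
  V <- fit$vcov
  check_psd(V)
  m <- length(exposures)

  # E[i, l] = Zc[i,] %*% H %*% C[l,], with eta laid out predictor-major
  H <- matrix(eta, nrow = v_x, ncol = v_l, byrow = TRUE)
  E <- Zc %*% H %*% t(C)
  # per-cell contrast rows a(x_i, l) = kron(Zc[i,], C[l,]) share structure
  # across lags: build the m x (v_x*v_l) block lag by lag
  Zrep <- Zc[, rep(seq_len(v_x), each = v_l), drop = FALSE]
  E_sd <- matrix(NA_real_, m, L + 1L)
  for (l in seq_len(L + 1L)) {
    A <- Zrep * matrix(rep(C[l, ], times = v_x), m, v_x * v_l, byrow = TRUE)
    E_sd[, l] <- sqrt(pmax(rowSums((A %*% V) * A), 0))
  }
  ctot <- colSums(C)
  A_tot <- Zrep * matrix(rep(ctot, times = v_x), m, v_x * v_l, byrow = TRUE)
  e_tot <- drop(A_tot %*% eta)
  e_tot_sd <- sqrt(pmax(rowSums((A_tot %*% V) * A_tot), 0))

  dimnames(E) <- dimnames(E_sd) <-
    list(format(exposures, trim = TRUE), paste0("lag", 0:L))
  structure(list(exposures = exposures, lags = 0:L, E = E, E_sd = E_sd,
                 e_tot = e_tot, e_tot_sd = e_tot_sd,
                 reference = if (centred) reference else NULL,
                 link = fit$link, recipe = crossbasis_recipe(cb)),
            class = "prediction_grid")
}

check_psd <- function(V, tol = 1e-8) {
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev)))
    stop("variance-covariance matrix is not positive semidefinite ",
         "(min eigenvalue ", signif(min(ev), 3), "); the fit is degenerate")
  invisible(V)
}

#' Relative-risk table from a prediction grid
#'
#' Exponentiates a log-link prediction grid into relative risks with normal
#' confidence intervals: `RR = exp(effect)`,
#' `CI = exp(effect -/+ z * sd)` with `z` the standard normal quantile for
#' the requested coverage. Rows are keyed by exposure and lag, with the
#' lag-summed effects under the pseudo-lag `"overall"`.
#'
#' @param grid a [predict_grid()] result with `link = "log"`.
#' @param level confidence level (default 0.95).
#' @return a `data.frame` with columns `exposure`, `lag`, `effect`, `sd`,
#'   `rr`, `rr_low`, `rr_high`.
#' @export
to_risk_scale <- function(grid, level = 0.95) {
  stopifnot(inherits(grid, "prediction_grid"))
  if (!identical(grid$link, "log"))
    stop("relative risks require a log link; report effects on the ",
         "identity scale instead")
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- length(grid$exposures)
  lag_rows <- data.frame(
    exposure = rep(grid$exposures, times = length(grid$lags)),
    lag = as.character(rep(grid$lags, each = m)),
    effect = as.vector(grid$E),
    sd = as.vector(grid$E_sd))
  tot_rows <- data.frame(exposure = grid$exposures, lag = "overall",
                         effect = grid$e_tot, sd = grid$e_tot_sd)
  out <- rbind(lag_rows, tot_rows)
  out$rr <- exp(out$effect)
  out$rr_low <- exp(out$effect - z * out$sd)
  out$rr_high <- exp(out$effect + z * out$sd)
  attr(out, "level") <- level
  attr(out, "reference") <- grid$reference
  out
}

#' Slice a prediction grid
#'
#' Extracts the effect curve along one dimension: by exposure at a fixed lag
#' (`lag = l`), or by lag at a fixed exposure (`exposure = x`). The value
#' must be on the grid; no interpolation is performed.
#'
#' @param grid a [predict_grid()] result.
#' @param lag,exposure exactly one of the two must be supplied.
#' @return a `data.frame` with the axis (`exposure` or `lag`), `effect`
#'   and `sd`.
#' @export
slice_grid <- function(grid, lag = NULL, exposure = NULL) {
  stopifnot(inherits(grid, "prediction_grid"))
  if (is.null(lag) == is.null(exposure))
    stop("supply exactly one of 'lag' or 'exposure'")
  if (!is.null(lag)) {
    i <- which(grid$lags == lag)
    if (length(i) != 1L)
      stop("lag ", lag, " is not on the grid (0..", max(grid$lags), ")")
    data.frame(exposure = grid$exposures,
               effect = grid$E[, i], sd = grid$E_sd[, i])
  } else {
    i <- which(abs(grid$exposures - exposure) < 1e-12)
    if (length(i) != 1L)
      stop("exposure ", exposure, " is not on the grid; ",
           "add it to 'exposures' when calling predict_grid()")
    data.frame(lag = grid$lags,
               effect = grid$E[i, ], sd = grid$E_sd[i, ])
  }
}

#' Export a prediction grid
#'
#' Writes the grid in long format (`exposure, lag, effect, sd, rr, rr_low,
#' rr_high`, with `lag = "overall"` rows for the lag-summed effects) to a
#' CSV file, and the metadata needed to reproduce it (reference, confidence
#' level, the full cross-basis recipe) to a JSON sidecar.
#'
#' @param grid a [predict_grid()] result.
#' @param csv_path path of the CSV to write.
#' @param meta_path path of the JSON sidecar; default replaces the CSV
#'   extension with `_meta.json`.
#' @param level confidence level for the RR columns (log link only; on
#'   other links the RR columns are omitted).
#' @return the CSV path, invisibly.
#' @export
write_grid <- function(grid, csv_path,
                       meta_path = sub("\\.csv$", "_meta.json", csv_path),
                       level = 0.95) {
  stopifnot(inherits(grid, "prediction_grid"))
  tab <- if (identical(grid$link, "log")) {
    to_risk_scale(grid, level)
  } else {
    m <- length(grid$exposures)
    rbind(data.frame(exposure = rep(grid$exposures, times = length(grid$lags)),
                     lag = as.character(rep(grid$lags, each = m)),
                     effect = as.vector(grid$E), sd = as.vector(grid$E_sd)),
          data.frame(exposure = grid$exposures, lag = "overall",
                     effect = grid$e_tot, sd = grid$e_tot_sd))
  }
  utils::write.csv(tab, csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(reference = grid$reference, level = level, link = grid$link,
         recipe = grid$recipe),
    meta_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(csv_path)
}

#' @export
print.prediction_grid <- function(x, ...) {
  cat("<prediction_grid> ", length(x$exposures), " exposures x ",
      length(x$lags), " lags", sep = "")
  if (!is.null(x$reference)) cat(", reference ", x$reference, sep = "")
  cat(" (", x$link, " link)\n", sep = "")
  i <- order(abs(x$e_tot), decreasing = TRUE)[1L]
  cat("  largest overall effect ", signif(x$e_tot[i], 4), " at exposure ",
      signif(x$exposures[i], 4), "\n", sep = "")
  invisible(x)
}
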