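#' Matrix of lagged exposures
#'
#' Expands an ordered exposure series `x` of length `n` into the
#' `n x (L + 1)` matrix of lagged occurrences: entry `(t, l)` holds
#' `x[t - l]`, the exposure `l` days before day `t`. The first column is the
#' series itself (lag 0). Entries reaching before the start of the series
#' are missing: the first `L` rows have incomplete lag histories and are
#' dropped by downstream model fitting rather than filled from assumed
#' pre-sample exposures.
#'
#' @param x numeric exposure series, ordered in time with no gaps (a regular
#'   daily series).
#' @param L maximum lag, `0 <= L < length(x)`.
#' @return A matrix of class `lag_matrix` with columns `lag0 ... lagL` and
#'   attributes `L` and `lags` (`0:L`).
#' @examples
#' build_lag_matrix(c(1, 2, 3, 4), L = 2)
#' @export
build_lag_matrix <- function(x, L) {
  x <- as.numeric(x)
  n <- length(x)
  L <- as.integer(L)
  if (L < 0L) stop("L must be non-negative")
  if (L >= n) stop("maximum lag L must be smaller than the series length ",
                   "(no row would have a complete lag history)")
  Q <- vapply(0:L, function(l) c(rep(NA_real_, l), x[seq_len(n - l)]),
              numeric(n))
  Q <- matrix(Q, nrow = n)
  colnames(Q) <- paste0("lag", 0:L)
  structure(Q, L = L, lags = 0:L, class = c("lag_matrix", class(Q)))
}

#' Build a cross-basis design matrix
#'
#' Combines a basis for the predictor space (applied to the exposure values)
#' with a basis for the lag space (applied to the lag vector `0:L`) into the
#' bi-dimensional cross-basis: the set of `v_x * v_l` functions describing
#' simultaneously the shape of the exposure-response relationship and its
#' distribution over lags. Column `(j, k)` of the returned matrix `W` holds,
#' for each day `t`,
#' \deqn{w_{t,(j,k)} = \sum_{l=0}^{L} z_{t-l,\,j}\; c_{l,k},}
#' the lag-weighted sum of the `j`-th predictor-basis variable evaluated on
#' the exposure history, with weights given by the `k`-th lag-basis variable.
#' The construction is symmetric: applying the predictor basis to the lagged
#' exposures, or lagging the predictor-basis columns, gives the same matrix.
#'
#' `W` is a plain numeric matrix and can be included directly in the design
#' of any regression model (e.g. `glm(count ~ cb + ..., family =
#' quasipoisson())`). The returned object carries the fully materialized
#' basis specs, maximum lag, exposure range and column order needed to
#' rebuild the transforms at prediction time; see [crossbasis_recipe()].
#'
#' Special cases: a `linear` predictor basis with an `identity` lag basis
#' reproduces the unconstrained distributed lag model (`W` equals the lag
#' matrix `Q`); with a `constant` lag basis it gives the lag-sum model, i.e.
#' `(L + 1)` times the moving average of the past `L + 1` days (the sum is
#' exposed unscaled; a coefficient fitted to the moving average equals
#' `L + 1` times the coefficient fitted to the sum).
#'
#' @param x numeric exposure series (regular, time-ordered).
#' @param var_spec [basis_spec()] for the predictor space.
#' @param lag_spec [basis_spec()] for the lag space. Data-driven spline knots
#'   here default to the log-lag placement of [make_lag_knots()] with
#'   boundary knots at 0 and `L`.
#' @param L maximum lag.
#' @return An `n x (v_x * v_l)` matrix of class `crossbasis` with columns
#'   named `v<j>.l<k>` in predictor-basis-major order (column index
#'   `(j - 1) * v_l + k`), and attributes `var_spec`, `lag_spec`, `L`,
#'   `exposure_range`, `column_order`. The first `L` rows are missing.
#' @examples
#' x <- 10 + 5 * sin(seq_len(200) / 20)
#' cb <- build_crossbasis(x,
#'   var_spec = basis_spec("natural_cubic_spline", df = 4),
#'   lag_spec = basis_spec("natural_cubic_spline", df = 3, intercept = TRUE),
#'   L = 7)
#' dim(cb)
#' @export
build_crossbasis <- function(x, var_spec, lag_spec, L) {
  stopifnot(inherits(var_spec, "basis_spec"), inherits(lag_spec, "basis_spec"))
  x <- as.numeric(x)
  if (all(!is.finite(x))) stop("exposure series is entirely missing")
  L <- as.integer(L)
  if (identical(var_spec$kind, "identity"))
    stop("identity bases are valid only for the lag space")
  lag_spec <- default_lag_spec(lag_spec, L)
  Z <- evaluate_basis(var_spec, x)
  var_spec <- attr(Z, "spec")
  C <- evaluate_basis(lag_spec, 0:L, warn_range = FALSE)
  lag_spec <- attr(C, "spec")
  if (nrow(C) != L + 1L)
    stop("lag basis must evaluate to one row per lag 0..L")
  v_x <- ncol(Z)
  v_l <- ncol(C)
  n <- length(x)
  W <- matrix(NA_real_, nrow = n, ncol = v_x * v_l)
  for (j in seq_len(v_x)) {
    Qj <- build_lag_matrix(Z[, j], L)
    W[, (j - 1L) * v_l + seq_len(v_l)] <- unclass(Qj) %*% unclass(C)
  }
  column_order <- paste0("v", rep(seq_len(v_x), each = v_l),
                         ".l", rep(seq_len(v_l), times = v_x))
  colnames(W) <- column_order
  structure(W,
            var_spec = var_spec, lag_spec = lag_spec, L = L,
            exposure_range = range(x[is.finite(x)]),
            column_order = column_order,
            class = c("crossbasis", class(W)))
}

# Lag-space conventions: spline knots on the log lag scale, boundary at the
# ends of the lag vector.
default_lag_spec <- function(lag_spec, L) {
  if (lag_spec$kind == "natural_cubic_spline") {
    if (is.null(lag_spec$boundary)) lag_spec$boundary <- c(0, L)
    if (is.null(lag_spec$knots)) {
      nk <- lag_spec$df - 1L - as.integer(lag_spec$intercept)
      if (nk > 0L) lag_spec$knots <- make_lag_knots(L, nk)
    }
  }
  lag_spec
}

#' Recipe to rebuild a cross-basis transform
#'
#' Returns the fully materialized description of a cross-basis — both basis
#' specs (with the actual knots used), the maximum lag, the observed exposure
#' range and the column order — as a plain list that serializes to JSON.
#' Embedding this recipe in output files lets the prediction step reconstruct
#' the transforms exactly without access to the original data.
#'
#' @param cb a [build_crossbasis()] object, or a recipe list for
#'   `crossbasis_from_recipe()`.
#' @return `crossbasis_recipe()`: a named list; `crossbasis_from_recipe()`:
#'   a skeleton `crossbasis` (attributes only, no rows) usable by
#'   [predict_grid()].
#' @export
crossbasis_recipe <- function(cb) {
  stopifnot(inherits(cb, "crossbasis"))
  list(var_spec = basis_spec_to_list(attr(cb, "var_spec")),
       lag_spec = basis_spec_to_list(attr(cb, "lag_spec")),
       L = attr(cb, "L"),
       exposure_range = attr(cb, "exposure_range"),
       column_order = attr(cb, "column_order"))
}

#' @rdname crossbasis_recipe
#' @param recipe a list as returned by `crossbasis_recipe()`.
#' @export
crossbasis_from_recipe <- function(recipe) {
  skel <- matrix(numeric(0), nrow = 0,
                 ncol = length(recipe$column_order),
                 dimnames = list(NULL, unlist(recipe$column_order)))
  structure(skel,
            var_spec = basis_spec_from_list(recipe$var_spec),
            lag_spec = basis_spec_from_list(recipe$lag_spec),
            L = as.integer(recipe$L),
            exposure_range = as.numeric(unlist(recipe$exposure_range)),
            column_order = unlist(recipe$column_order),
            class = c("crossbasis", "matrix", "array"))
}

#' @export
print.crossbasis <- function(x, ...) {
  cat("<crossbasis> ", nrow(x), " x ", ncol(x),
      " (max lag ", attr(x, "L"), ")\n", sep = "")
  cat("predictor basis: ")
  print(attr(x, "var_spec"))
  cat("lag basis:       ")
  print(attr(x, "lag_spec"))
  invisible(x)
}
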