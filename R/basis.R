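#' Declare a one-dimensional basis
#'
#' A `basis_spec` is a declarative description of a set of basis functions
#' used to represent the shape of a relationship, either in the space of the
#' predictor (applied to exposure values) or in the lag space (applied to the
#' integer lag vector `0:L`). The spec is evaluated into a numeric matrix by
#' [evaluate_basis()].
#'
#' Supported kinds:
#' \describe{
#'   \item{`linear`}{a single untransformed column.}
#'   \item{`polynomial`}{monomials `x, x^2, ..., x^degree`.}
#'   \item{`natural_cubic_spline`}{cubic regression spline constrained to be
#'     linear beyond the boundary knots, built from a B-spline representation
#'     (via [splines::ns()]). The dimension convention is
#'     `#internal_knots + 1` without intercept, plus 1 with intercept, so a
#'     request for `df` degrees of freedom places `df - 1 - intercept`
#'     internal knots.}
#'   \item{`threshold`}{hockey-stick terms: one column `(x - k)+` per knot
#'     `k`, i.e. `x - k` above the knot and 0 below.}
#'   \item{`strata`}{interval indicators cut at the knots. With
#'     `intercept = TRUE` all `#knots + 1` intervals get an indicator (rows
#'     sum to one); otherwise the lowest interval is dropped as reference.}
#'   \item{`constant`}{a single column of ones.}
#'   \item{`identity`}{one indicator column per distinct integer input value;
#'     intended for the lag space, where it yields the unconstrained
#'     distributed lag model.}
#' }
#'
#' Knots for splines and strata may be given explicitly, or derived from the
#' data at evaluation time when only `df` is supplied: `placement = "even"`
#' spaces them equally across the observed range, `placement = "quantiles"`
#' puts them at equally spaced quantiles. Lag-space splines instead default
#' to knots equally spaced on the log lag scale (see [make_lag_knots()]),
#' giving more resolution at short lags where effects change fastest.
#'
#' @param kind character, one of the kinds listed above.
#' @param df requested dimension (degrees of freedom) of the basis; for
#'   splines this determines the number of internal knots when `knots` is not
#'   given. Ignored when the dimension is implied by `degree` or `knots`.
#' @param degree polynomial degree (`kind = "polynomial"` only).
#' @param knots numeric vector of strictly increasing knots, in predictor
#'   units (`natural_cubic_spline`, `threshold`, `strata`).
#' @param boundary length-2 numeric, boundary knots for splines; defaults to
#'   the observed input range at evaluation time.
#' @param intercept logical; include a constant column. Only meaningful for
#'   `polynomial`, `natural_cubic_spline` and `strata`.
#' @param placement `"even"` or `"quantiles"`: how data-driven spline/strata
#'   knots are placed when `knots` is not supplied.
#' @return An object of class `basis_spec`.
#' @seealso [evaluate_basis()], [basis_dimension()], [build_crossbasis()]
#' @examples
#' basis_spec("natural_cubic_spline", df = 5)
#' basis_spec("threshold", knots = c(15, 25))
#' @export
basis_spec <- function(kind = c("linear", "polynomial", "natural_cubic_spline",
                                "threshold", "strata", "constant", "identity"),
                       df = NULL, degree = NULL, knots = NULL,
                       boundary = NULL, intercept = FALSE,
                       placement = c("even", "quantiles")) {
  kind <- match.arg(kind)
  placement <- match.arg(placement)
  if (!is.logical(intercept) || length(intercept) != 1L || is.na(intercept))
    stop("'intercept' must be TRUE or FALSE")
  if (intercept && !kind %in% c("polynomial", "natural_cubic_spline", "strata"))
    stop("'intercept' is only supported for polynomial, natural_cubic_spline ",
         "and strata bases; for other kinds add a constant basis instead")
  if (!is.null(knots)) {
    knots <- as.numeric(knots)
    if (anyNA(knots) || any(!is.finite(knots)))
      stop("knots must be finite")
    if (is.unsorted(knots, strictly = TRUE))
      stop("knots must be strictly increasing")
  }
  if (kind == "polynomial") {
    if (is.null(degree)) degree <- if (!is.null(df)) df - intercept else 2L
    degree <- as.integer(degree)
    if (degree < 1L) stop("polynomial degree must be a positive integer")
  } else if (!is.null(degree)) {
    stop("'degree' applies to polynomial bases only")
  }
  if (kind %in% c("threshold", "strata") && is.null(knots) && is.null(df))
    stop(kind, " basis requires 'knots' or 'df'")
  if (kind == "natural_cubic_spline") {
    if (is.null(knots) && is.null(df))
      stop("natural_cubic_spline basis requires 'df' or 'knots'")
    if (!is.null(df) && df < 1L + intercept)
      stop("natural_cubic_spline df too small for the requested intercept")
    if (!is.null(boundary)) {
      boundary <- as.numeric(boundary)
      if (length(boundary) != 2L || boundary[1] >= boundary[2])
        stop("'boundary' must be two increasing values")
      if (!is.null(knots) && (any(knots <= boundary[1]) || any(knots >= boundary[2])))
        stop("internal knots must lie strictly inside the boundary knots")
    }
  } else if (!is.null(boundary)) {
    stop("'boundary' applies to natural_cubic_spline bases only")
  }
  spec <- structure(
    list(kind = kind, df = if (!is.null(df)) as.integer(df),
         degree = if (kind == "polynomial") degree,
         knots = knots, boundary = boundary,
         intercept = intercept, placement = placement),
    class = "basis_spec"
  )
  spec
}

#' Dimension of a basis
#'
#' Number of columns the basis produces when evaluated: `linear` and
#' `constant` give 1; `polynomial` gives `degree` (+1 with intercept);
#' `threshold` one per knot; `strata` one per interval beyond the first
#' (all intervals with intercept); `natural_cubic_spline` gives
#' `#internal_knots + 1` (+1 with intercept); `identity` one per distinct
#' integer value, so `n_values` must be supplied (for a lag vector `0:L`
#' this is `L + 1`).
#'
#' @param spec a [basis_spec()].
#' @param n_values number of distinct input values; required for `identity`
#'   and for data-driven specs declared through `df` alone.
#' @return a positive integer.
#' @export
basis_dimension <- function(spec, n_values = NULL) {
  stopifnot(inherits(spec, "basis_spec"))
  switch(spec$kind,
    linear = 1L,
    constant = 1L,
    polynomial = spec$degree + as.integer(spec$intercept),
    threshold = if (!is.null(spec$knots)) length(spec$knots) else spec$df,
    strata = if (!is.null(spec$knots))
        length(spec$knots) + as.integer(spec$intercept)
      else spec$df,
    natural_cubic_spline = if (!is.null(spec$knots))
        length(spec$knots) + 1L + as.integer(spec$intercept)
      else spec$df,
    identity = {
      if (is.null(n_values))
        stop("identity basis dimension depends on the input values; ",
             "supply n_values")
      as.integer(n_values)
    },
    stop("unknown basis kind: ", spec$kind)
  )
}

# Fill in data-driven pieces (knots, boundary) so the spec becomes fully
# reproducible: evaluating the materialized spec on new data gives the same
# transform. Called by evaluate_basis() and build_crossbasis().
materialize_spec <- function(spec, values) {
  obs <- values[is.finite(values)]
  if (length(obs) == 0L) stop("no finite input values to evaluate basis on")
  rng <- range(obs)
  if (spec$kind == "natural_cubic_spline") {
    if (is.null(spec$boundary)) spec$boundary <- rng
    if (is.null(spec$knots)) {
      nk <- spec$df - 1L - as.integer(spec$intercept)
      spec$knots <- place_knots(obs, nk, spec$placement, spec$boundary)
    }
  }
  if (spec$kind %in% c("threshold", "strata") && is.null(spec$knots)) {
    nk <- spec$df - if (spec$kind == "strata") as.integer(spec$intercept) else 0L
    spec$knots <- place_knots(obs, nk, spec$placement, rng)
  }
  if (spec$kind == "identity") {
    iv <- unique(sort(obs))
    if (max(abs(iv - round(iv))) > 1e-8)
      stop("identity basis requires integer input values")
    spec$values <- as.integer(round(iv))
  }
  spec$df <- basis_dimension(spec, n_values = length(spec$values))
  spec
}

place_knots <- function(obs, nk, placement, bounds) {
  if (nk < 0L) stop("negative number of knots implied; increase df")
  if (nk == 0L) return(NULL)
  k <- if (placement == "quantiles") {
    unname(stats::quantile(obs, probs = seq_len(nk) / (nk + 1)))
  } else {
    seq(bounds[1], bounds[2], length.out = nk + 2L)[seq_len(nk) + 1L]
  }
  if (is.unsorted(k, strictly = TRUE))
    stop("derived knots are not strictly increasing; ",
         "too many df for the spread of the data")
  k
}

#' Evaluate a basis on a vector of values
#'
#' Applies the basis functions described by `spec` to `values`, returning one
#' row per input value. Missing inputs propagate to missing rows rather than
#' erroring, matching the incomplete lag histories at the start of a series.
#' Knots and boundary knots left unspecified are derived from the observed
#' values and recorded in the returned spec, so the same transform can be
#' reproduced exactly at prediction time.
#'
#' @param spec a [basis_spec()].
#' @param values numeric vector.
#' @param warn_range warn when values fall outside explicitly supplied spline
#'   boundary knots (natural splines extrapolate linearly there).
#' @return A numeric matrix of class `basis_matrix` with `basis_dimension()`
#'   columns, carrying attributes `spec` (the materialized spec) and
#'   `input_range`.
#' @examples
#' evaluate_basis(basis_spec("threshold", knots = 3), c(2, 5))
#' @export
evaluate_basis <- function(spec, values, warn_range = TRUE) {
  stopifnot(inherits(spec, "basis_spec"))
  values <- as.numeric(values)
  spec <- materialize_spec(spec, values)
  ok <- is.finite(values)
  x <- values[ok]
  if (!is.null(spec$knots) && warn_range &&
      (min(spec$knots) < min(x) || max(spec$knots) > max(x)))
    warning("some knots lie outside the range of the supplied values")
  m <- switch(spec$kind,
    linear = matrix(x, ncol = 1L),
    constant = matrix(1, nrow = length(x), ncol = 1L),
    polynomial = {
      p <- outer(x, seq_len(spec$degree), `^`)
      if (spec$intercept) cbind(1, p) else p
    },
    threshold = vapply(spec$knots, function(k) pmax(x - k, 0),
                       numeric(length(x))),
    strata = {
      breaks <- c(-Inf, spec$knots, Inf)
      g <- cut(x, breaks = breaks, right = FALSE, labels = FALSE)
      ind <- outer(g, seq_along(breaks[-1L]), `==`) * 1
      if (spec$intercept) ind else ind[, -1L, drop = FALSE]
    },
    natural_cubic_spline = {
      if (warn_range && (any(x < spec$boundary[1]) || any(x > spec$boundary[2])))
        warning("values beyond the spline boundary knots; ",
                "natural splines extrapolate linearly there")
      unclass(splines::ns(x, knots = spec$knots,
                          Boundary.knots = spec$boundary,
                          intercept = spec$intercept))
    },
    identity = {
      if (max(abs(x - round(x))) > 1e-8)
        stop("identity basis requires integer input values")
      outer(as.integer(round(x)), spec$values, `==`) * 1
    },
    stop("unknown basis kind: ", spec$kind)
  )
  m <- matrix(as.numeric(m), nrow = length(x))
  out <- matrix(NA_real_, nrow = length(values), ncol = ncol(m))
  out[ok, ] <- m
  if (ncol(out) != basis_dimension(spec, length(spec$values)))
    stop("internal error: basis dimension mismatch")  # nocov
  colnames(out) <- paste0("b", seq_len(ncol(out)))
  structure(out, spec = spec,
            input_range = range(values[ok]),
            class = c("basis_matrix", class(out)))
}

#' Lag knots equally spaced on the log scale
#'
#' Places `n_knots` internal knots for a lag-space spline at equal intervals
#' on the logarithmic scale of lags, the customary choice when more
#' flexibility is wanted at short lags. The log transform acts on lags
#' >= 1, and lag 0 always falls inside the first interval.
#'
#' @param L maximum lag (>= 1).
#' @param n_knots number of internal knots, `1 <= n_knots < L`.
#' @return strictly increasing knots inside `(0, L)`.
#' @examples
#' make_lag_knots(30, 3)
#' @export
make_lag_knots <- function(L, n_knots) {
  L <- as.integer(L)
  n_knots <- as.integer(n_knots)
  if (L < 1L) stop("L must be at least 1")
  if (n_knots < 1L) stop("n_knots must be at least 1")
  if (n_knots >= L) stop("n_knots must be smaller than the maximum lag L")
  exp(seq(log(1), log(L), length.out = n_knots + 2L))[seq_len(n_knots) + 1L]
}

#' @export
print.basis_spec <- function(x, ...) {
  cat("<basis_spec>", x$kind)
  if (!is.null(x$degree)) cat(", degree", x$degree)
  if (!is.null(x$df)) cat(", df", x$df)
  if (x$intercept) cat(", with intercept")
  cat("\n")
  if (!is.null(x$knots))
    cat("  knots:", paste(signif(x$knots, 4), collapse = ", "), "\n")
  if (!is.null(x$boundary))
    cat("  boundary:", paste(signif(x$boundary, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize / restore a basis spec
#'
#' A `basis_spec` round-trips through a plain named list (and hence JSON),
#' so that the bases of a fitted model can be stored alongside coefficients
#' and rebuilt exactly for prediction.
#'
#' @param spec a [basis_spec()].
#' @param config a named list as produced by `basis_spec_to_list()`.
#' @return `basis_spec_to_list()` a named list; `basis_spec_from_list()` a
#'   `basis_spec`.
#' @export
basis_spec_to_list <- function(spec) {
  stopifnot(inherits(spec, "basis_spec"))
  out <- spec[!vapply(spec, is.null, logical(1))]
  class(out) <- NULL
  out
}

#' @rdname basis_spec_to_list
#' @export
basis_spec_from_list <- function(config) {
  spec <- basis_spec(kind = config$kind, df = config$df,
                     degree = config$degree, knots = config$knots,
                     boundary = config$boundary,
                     intercept = isTRUE(config$intercept),
                     placement = if (!is.null(config$placement))
                       config$placement else "even")
  if (!is.null(config$values)) spec$values <- as.integer(config$values)
  if (!is.null(config$df)) spec$df <- as.integer(config$df)
  spec
}
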