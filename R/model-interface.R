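#' Extract the fitted cross-basis from a regression model
#'
#' The cross-basis matrix enters an ordinary (typically quasi-Poisson) GLM
#' alongside confounder terms; estimation raises no special problems. This
#' function pulls out of the fitted model exactly the pieces the prediction
#' machinery needs: the coefficient sub-vector for the cross-basis columns
#' (in cross-basis column order, regardless of how the model ordered them),
#' the matching block of the variance-covariance matrix, the estimated
#' dispersion, the log-likelihood, and the model size.
#'
#' For quasi-likelihood families no likelihood is defined; following the
#' convention of the overdispersion-adjusted information criteria literature,
#' the Poisson log-likelihood evaluated at the fitted means is used and
#' recorded as such.
#'
#' @param model a fitted [stats::glm()] (or `lm`) whose design contains the
#'   columns of `cb` under recoverable names (e.g. fitted as
#'   `glm(y ~ cb + z)`).
#' @param cb the [build_crossbasis()] object used in the fit.
#' @return An object of class `fitted_crossbasis`: a list with elements
#'   `eta_hat` (named coefficient vector, length `v_x * v_l`), `vcov`,
#'   `dispersion`, `loglik`, `n_obs`, `n_params` (all mean-model parameters,
#'   confounders included), `link`, and `column_order`.
#' @examples
#' cfg <- sim_config(n_days = 400, max_lag = 7, seed = 42)
#' dat <- simulate_series(cfg)
#' cb <- build_crossbasis(dat$exposure,
#'   basis_spec("polynomial", degree = 2),
#'   basis_spec("natural_cubic_spline", df = 3, intercept = TRUE), L = 7)
#' fit <- stats::glm(dat$count ~ cb, family = stats::quasipoisson())
#' extract_fit(fit, cb)
#' @export
extract_fit <- function(model, cb) {
  stopifnot(inherits(cb, "crossbasis"))
  beta <- stats::coef(model)
  V <- stats::vcov(model)
  idx <- locate_crossbasis_coefs(model, names(beta),
                                 attr(cb, "column_order"))
  eta <- beta[idx]
  if (anyNA(eta))
    stop("cross-basis coefficients are NA (rank-deficient fit); ",
         "reduce the basis dimensions")
  names(eta) <- attr(cb, "column_order")
  Vb <- V[idx, idx, drop = FALSE]
  dimnames(Vb) <- list(names(eta), names(eta))
  fam <- tryCatch(stats::family(model), error = function(e) NULL)
  sm <- summary(model)
  dispersion <- if (!is.null(sm$dispersion)) sm$dispersion else 1
  if (!is.null(fam) && fam$family %in% c("poisson", "quasipoisson")) {
    mu <- stats::fitted(model)
    y <- model$y
    ll <- sum(stats::dpois(y, mu, log = TRUE))
    link <- "log"
  } else {
    ll <- as.numeric(stats::logLik(model))
    lk <- if (!is.null(fam)) fam$link else "identity"
    link <- if (lk == "log") "log" else if (lk == "identity") "identity"
           else "other"
  }
  new_fitted_crossbasis(
    eta_hat = eta, vcov = Vb, dispersion = dispersion, loglik = ll,
    n_obs = stats::nobs(model), n_params = sum(!is.na(beta)),
    link = link, column_order = attr(cb, "column_order"))
}

# Locate the cross-basis coefficients in the fitted model. Preferred route:
# find the model-frame term holding the cross-basis (matched by its column
# names) and reconstruct the coefficient names R gives matrix terms
# ("<term><colname>", or just "<term>" for a single column). Falls back to
# suffix matching when no model frame is available.
locate_crossbasis_coefs <- function(model, coef_names, column_order) {
  label <- tryCatch({
    mf <- stats::model.frame(model)
    hits <- names(mf)[vapply(mf, function(v)
      is.matrix(v) && identical(colnames(v), column_order), logical(1))]
    if (length(hits) == 1L) hits else NULL
  }, error = function(e) NULL)
  if (!is.null(label)) {
    cand <- if (length(column_order) == 1L) label
            else paste0(label, column_order)
    if (all(cand %in% coef_names)) return(match(cand, coef_names))
  }
  match_crossbasis_names(coef_names, column_order)
}

# Suffix matching: coefficient names from glm(y ~ cb + ...) look like
# "cbv1.l2" (matrix symbol prefixed to the column name). Column names all
# start with "v", so one column name is never a suffix of another.
match_crossbasis_names <- function(coef_names, column_order) {
  vapply(column_order, function(nm) {
    hits <- which(coef_names == nm | endsWith(coef_names, nm))
    if (length(hits) == 0L)
      stop("cross-basis column '", nm, "' not found among model coefficients")
    if (length(hits) > 1L)
      stop("cross-basis column '", nm, "' matches several coefficients: ",
           paste(coef_names[hits], collapse = ", "))
    hits
  }, integer(1))
}

new_fitted_crossbasis <- function(eta_hat, vcov, dispersion, loglik,
                                  n_obs, n_params, link, column_order) {
  vcov <- (vcov + t(vcov)) / 2  # enforce exact symmetry
  if (any(diag(vcov) < -1e-10))
    stop("variance-covariance matrix has negative diagonal entries")
  if (n_params < length(eta_hat))
    stop("n_params cannot be smaller than the number of cross-basis ",
         "coefficients")
  structure(list(eta_hat = eta_hat, vcov = vcov,
                 dispersion = as.numeric(dispersion),
                 loglik = as.numeric(loglik),
                 n_obs = as.integer(n_obs), n_params = as.integer(n_params),
                 link = link, column_order = column_order),
            class = "fitted_crossbasis")
}

#' @export
print.fitted_crossbasis <- function(x, ...) {
  cat("<fitted_crossbasis> ", length(x$eta_hat), " cross-basis coefficients",
      " (", x$n_params, " model parameters, n = ", x$n_obs, ")\n", sep = "")
  cat("  dispersion ", signif(x$dispersion, 4),
      ", log-likelihood ", signif(x$loglik, 6),
      ", link ", x$link, "\n", sep = "")
  invisible(x)
}

#' Overdispersion-adjusted information criteria
#'
#' For models with overdispersed responses fitted through quasi-likelihood,
#' the usual AIC/BIC penalties are inflated by the estimated dispersion
#' \eqn{\hat\varphi}:
#' \deqn{QAIC = -2\mathcal{L} + 2\,\hat\varphi\,k, \qquad
#'       QBIC = -2\mathcal{L} + \log(n)\,\hat\varphi\,k,}
#' where \eqn{\mathcal{L}} is the log-likelihood at the fitted values, `k`
#' the number of mean-model parameters and `n` the number of observations.
#' Lower is better; with \eqn{\hat\varphi = 1} they reduce to ordinary
#' AIC/BIC.
#'
#' @param fit a [extract_fit()] result (or any list with `loglik`,
#'   `dispersion`, `n_params`, `n_obs`).
#' @return a single number.
#' @export
qaic <- function(fit) {
  check_criteria_inputs(fit)
  -2 * fit$loglik + 2 * fit$dispersion * fit$n_params
}

#' @rdname qaic
#' @export
qbic <- function(fit) {
  check_criteria_inputs(fit)
  -2 * fit$loglik + log(fit$n_obs) * fit$dispersion * fit$n_params
}

check_criteria_inputs <- function(fit) {
  need <- c("loglik", "dispersion", "n_params", "n_obs")
  miss <- need[!need %in% names(fit)]
  if (length(miss))
    stop("fit is missing: ", paste(miss, collapse = ", "))
  if (!is.finite(fit$dispersion) || fit$dispersion <= 0)
    stop("dispersion must be positive")
  if (!is.finite(fit$loglik)) stop("log-likelihood must be finite")
  invisible(fit)
}

#' Write / read a fitted cross-basis as plain interchange files
#'
#' So that fits produced in any environment can feed the prediction step,
#' a `fitted_crossbasis` serializes to three documented plain-text files in
#' `dir`: `coef.csv` (columns `name,estimate`), `vcov.csv` (square matrix
#' with header and row names matching the coefficient names) and
#' `scalars.json` (`dispersion`, `loglik`, `n_obs`, `n_params`, `link`,
#' `loglik_convention`). Row order in the files is immaterial: reading
#' restores cross-basis column order by name.
#'
#' @param fit a `fitted_crossbasis`.
#' @param dir directory to write to / read from (created if needed).
#' @param cb the matching `crossbasis` (or a skeleton from
#'   [crossbasis_from_recipe()]); supplies the required column order.
#' @return `write_fit_interchange()` the directory, invisibly;
#'   `read_fit_interchange()` a `fitted_crossbasis`.
#' @export
write_fit_interchange <- function(fit, dir) {
  stopifnot(inherits(fit, "fitted_crossbasis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(
    data.frame(name = names(fit$eta_hat), estimate = unname(fit$eta_hat)),
    file.path(dir, "coef.csv"), row.names = FALSE)
  vc <- as.data.frame(fit$vcov)
  utils::write.csv(cbind(name = rownames(fit$vcov), vc),
                   file.path(dir, "vcov.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(dispersion = fit$dispersion, loglik = fit$loglik,
         n_obs = fit$n_obs, n_params = fit$n_params, link = fit$link,
         loglik_convention = "poisson_at_fitted_mean"),
    file.path(dir, "scalars.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_fit_interchange
#' @export
read_fit_interchange <- function(dir, cb) {
  stopifnot(inherits(cb, "crossbasis"))
  co <- utils::read.csv(file.path(dir, "coef.csv"))
  vc <- utils::read.csv(file.path(dir, "vcov.csv"), check.names = FALSE)
  sc <- jsonlite::read_json(file.path(dir, "scalars.json"),
                            simplifyVector = TRUE)
  order <- attr(cb, "column_order")
  if (anyDuplicated(co$name)) stop("duplicate coefficient names in coef.csv")
  i <- match(order, co$name)
  if (anyNA(i))
    stop("coef.csv is missing cross-basis columns: ",
         paste(order[is.na(i)], collapse = ", "))
  eta <- stats::setNames(co$estimate[i], order)
  rn <- vc$name
  Vm <- as.matrix(vc[, -1, drop = FALSE])
  ri <- match(order, rn)
  ci <- match(order, colnames(Vm))
  if (anyNA(ri) || anyNA(ci))
    stop("vcov.csv does not cover all cross-basis columns")
  V <- Vm[ri, ci, drop = FALSE]
  dimnames(V) <- list(order, order)
  new_fitted_crossbasis(eta_hat = eta, vcov = V,
                        dispersion = sc$dispersion, loglik = sc$loglik,
                        n_obs = sc$n_obs, n_params = sc$n_params,
                        link = sc$link, column_order = order)
}
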