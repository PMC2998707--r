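#' Analysis run configuration
#'
#' Bundles every choice of a full analysis run — input file and column
#' mapping, the two bases, maximum lag, reference, prediction exposures,
#' confounder model, output directory and seed — into one serializable
#' object, so a run is reproducible from its config alone. Defaults follow
#' common practice in temperature-mortality time-series work: a natural
#' cubic spline of calendar time with 7 df per year for season and trend,
#' day-of-week indicators, and a maximum lag of 30 days.
#'
#' @param input path of the input CSV (regular daily series).
#' @param columns named list mapping roles to column names: `date`,
#'   `outcome`, `exposure`, and optionally `covariates` (character vector of
#'   columns entered linearly).
#' @param var_spec,lag_spec [basis_spec()] objects (or their list forms) for
#'   the predictor and lag spaces.
#' @param max_lag maximum lag in days.
#' @param reference reference exposure for reported contrasts; default is
#'   the exposure median.
#' @param exposures optional extra prediction exposures beyond the default
#'   grid.
#' @param time_df_per_year df per year of the natural cubic spline of time
#'   controlling season and long-term trend; 0 disables it.
#' @param day_of_week include day-of-week indicator variables.
#' @param outdir output directory for [run_fit()].
#' @param seed integer seed recorded with the outputs.
#' @return an object of class `run_config`.
#' @export
run_config <- function(input,
                       columns = list(date = "date", outcome = "count",
                                      exposure = "exposure"),
                       var_spec = basis_spec("natural_cubic_spline", df = 5),
                       lag_spec = basis_spec("natural_cubic_spline", df = 5,
                                             intercept = TRUE),
                       max_lag = 30,
                       reference = NULL,
                       exposures = NULL,
                       time_df_per_year = 7,
                       day_of_week = TRUE,
                       outdir = "distlag-run",
                       seed = 1L) {
  if (is.list(var_spec) && !inherits(var_spec, "basis_spec"))
    var_spec <- basis_spec_from_list(var_spec)
  if (is.list(lag_spec) && !inherits(lag_spec, "basis_spec"))
    lag_spec <- basis_spec_from_list(lag_spec)
  columns <- utils::modifyList(
    list(date = "date", outcome = "count", exposure = "exposure"), columns)
  structure(list(input = input, columns = columns,
                 var_spec = var_spec, lag_spec = lag_spec,
                 max_lag = as.integer(max_lag), reference = reference,
                 exposures = exposures,
                 time_df_per_year = time_df_per_year,
                 day_of_week = isTRUE(day_of_week),
                 outdir = outdir, seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file to write to / read from.
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- config
  out$var_spec <- basis_spec_to_list(config$var_spec)
  out$lag_spec <- basis_spec_to_list(config$lag_spec)
  class(out) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$columns <- as.list(raw$columns)
  do.call(run_config, raw)
}

config_error <- function(...) {
  stop(structure(class = c("distlag_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}
data_error <- function(...) {
  stop(structure(class = c("distlag_data_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}
fit_error <- function(...) {
  stop(structure(class = c("distlag_fit_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

read_series_csv <- function(config) {
  if (!file.exists(config$input))
    config_error("input file not found: ", config$input)
  dat <- utils::read.csv(config$input, stringsAsFactors = FALSE)
  need <- unlist(config$columns[c("date", "outcome", "exposure")])
  covs <- config$columns$covariates
  missing_cols <- setdiff(c(need, covs), names(dat))
  if (length(missing_cols))
    data_error("input is missing columns: ",
               paste(missing_cols, collapse = ", "),
               " (expected date/outcome/exposure mapping: ",
               paste(need, collapse = "/"), ")")
  dates <- as.Date(dat[[config$columns$date]], format = "%Y-%m-%d")
  if (anyNA(dates))
    data_error("dates must be ISO-8601 (YYYY-MM-DD)")
  if (is.unsorted(dates, strictly = TRUE) ||
      any(diff(as.integer(dates)) != 1L))
    data_error("series must be a regular daily sequence with no gaps ",
               "or duplicates")
  list(date = dates,
       y = dat[[config$columns$outcome]],
       x = dat[[config$columns$exposure]],
       covariates = if (length(covs)) dat[covs] else NULL)
}

build_confounder_design <- function(config, dates, covariates) {
  n <- length(dates)
  parts <- list()
  if (config$time_df_per_year > 0) {
    df_time <- max(2L, round(config$time_df_per_year * n / 365.25))
    tm <- splines::ns(seq_len(n), df = df_time)
    colnames(tm) <- paste0("time", seq_len(ncol(tm)))
    parts$time <- tm
  }
  if (config$day_of_week) {
    dow <- factor(format(dates, "%u"))
    if (nlevels(dow) > 1L) {
      dm <- stats::model.matrix(~dow)[, -1, drop = FALSE]
      parts$dow <- dm
    }
  }
  if (!is.null(covariates)) {
    cm <- as.matrix(covariates)
    colnames(cm) <- names(covariates)
    parts$covariates <- cm
  }
  if (length(parts)) do.call(cbind, parts) else NULL
}

#' Fit a full distributed-lag analysis and write its outputs
#'
#' End-to-end run: read the input series, build the cross-basis, fit a
#' quasi-Poisson GLM with the confounder model, and write to
#' `config$outdir`: the cross-basis recipe (`crossbasis_recipe.json`), the
#' coefficient/covariance interchange files (`coef.csv`, `vcov.csv`,
#' `scalars.json`), model criteria (`criteria.json` with QAIC/QBIC), the
#' prediction grid (`grid.csv` + `grid_meta.json`) and a run log
#' (`log.json` with the config, a config hash, package/R versions and the
#' number of rows dropped for incomplete lag histories or missing values).
#'
#' @param config a [run_config()] (or path to its JSON form).
#' @return invisibly, a list with the fitted pieces (`cb`, `fit`, `grid`,
#'   `criteria`, `outdir`).
#' @export
run_fit <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dat <- read_series_csv(config)
  n <- length(dat$y)
  if (config$max_lag >= n)
    data_error("maximum lag (", config$max_lag,
               ") must be smaller than the series length (", n, ")")
  cb <- build_crossbasis(dat$x, config$var_spec, config$lag_spec,
                         config$max_lag)
  conf <- build_confounder_design(config, dat$date, dat$covariates)
  y <- dat$y
  fit <- tryCatch({
    if (is.null(conf)) stats::glm(y ~ cb, family = stats::quasipoisson())
    else stats::glm(y ~ cb + conf, family = stats::quasipoisson())
  }, error = function(e) fit_error("model fit failed: ", conditionMessage(e)))
  fcb <- tryCatch(extract_fit(fit, cb),
                  error = function(e) fit_error(conditionMessage(e)))
  reference <- if (!is.null(config$reference)) config$reference
               else stats::median(dat$x, na.rm = TRUE)
  exposures <- sort(unique(c(
    seq(min(dat$x, na.rm = TRUE), max(dat$x, na.rm = TRUE), length.out = 50),
    config$exposures, reference)))
  grid <- predict_grid(fcb, cb, exposures = exposures, reference = reference)
  criteria <- list(qaic = qaic(fcb), qbic = qbic(fcb),
                   dispersion = fcb$dispersion, n_params = fcb$n_params,
                   n_obs = fcb$n_obs)

  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(crossbasis_recipe(cb),
                       file.path(outdir, "crossbasis_recipe.json"),
                       auto_unbox = TRUE, digits = NA)
  write_fit_interchange(fcb, outdir)
  jsonlite::write_json(criteria, file.path(outdir, "criteria.json"),
                       auto_unbox = TRUE, digits = NA)
  write_grid(grid, file.path(outdir, "grid.csv"))
  cfg_list <- jsonlite::fromJSON(jsonlite::toJSON(
    {cl <- config
     cl$var_spec <- basis_spec_to_list(config$var_spec)
     cl$lag_spec <- basis_spec_to_list(config$lag_spec)
     class(cl) <- NULL; cl}, auto_unbox = TRUE, digits = NA, null = "null"))
  jsonlite::write_json(
    list(config = cfg_list,
         config_hash = config_hash(cfg_list),
         r_version = as.character(getRversion()),
         package_version = as.character(utils::packageVersion("distlag")),
         n_rows = n,
         n_dropped = n - stats::nobs(fit),
         seed = config$seed),
    file.path(outdir, "log.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(list(cb = cb, fit = fcb, grid = grid, criteria = criteria,
                 outdir = outdir))
}

config_hash <- function(x) {
  # stable content hash without extra dependencies: sum of a serialization
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  raw <- utils::head(charToRaw(paste(s, collapse = "")), 1e6)
  sprintf("%08x", sum(as.integer(raw) * seq_along(raw)) %% 2^31)
}

#' Compare cross-basis dimensions by information criteria
#'
#' Refits the analysis of [run_fit()] over a grid of (predictor df, lag df)
#' pairs and tabulates QAIC and QBIC, the two overdispersion-adjusted
#' criteria, together with the number of cross-basis parameters (the product
#' of the dfs). Each criterion's minimizer is flagged; when they disagree
#' no automatic selection is made — parsimony arguments are left to the
#' analyst. A candidate that fails to fit is recorded as failed and the
#' search continues.
#'
#' @param config a [run_config()]; its `var_spec`/`lag_spec` serve as
#'   templates whose df is replaced per candidate.
#' @param df_grid a two-column matrix or data.frame of (var df, lag df)
#'   pairs, or a list of length-2 vectors. At least two candidates.
#' @return a `data.frame` with columns `var_df`, `lag_df`, `params`,
#'   `qaic`, `qbic`, `failed`, `qaic_best`, `qbic_best`.
#' @export
run_model_search <- function(config, df_grid) {
  stopifnot(inherits(config, "run_config"))
  if (is.list(df_grid) && !is.data.frame(df_grid))
    df_grid <- do.call(rbind, df_grid)
  df_grid <- as.matrix(df_grid)
  if (nrow(df_grid) < 2L)
    config_error("model search needs at least two candidate df pairs")
  rows <- lapply(seq_len(nrow(df_grid)), function(i) {
    vd <- df_grid[i, 1]; ld <- df_grid[i, 2]
    cfg <- config
    cfg$var_spec <- respec_df(config$var_spec, vd)
    cfg$lag_spec <- respec_df(config$lag_spec, ld)
    cfg$outdir <- file.path(config$outdir,
                            sprintf("search_v%s_l%s", vd, ld))
    res <- tryCatch(run_fit(cfg), error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(var_df = vd, lag_df = ld, params = vd * ld,
                 qaic = NA_real_, qbic = NA_real_, failed = TRUE)
    } else {
      data.frame(var_df = vd, lag_df = ld,
                 params = length(res$fit$eta_hat),
                 qaic = res$criteria$qaic, qbic = res$criteria$qbic,
                 failed = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  tab$qaic_best <- !tab$failed & tab$qaic == min(tab$qaic, na.rm = TRUE)
  tab$qbic_best <- !tab$failed & tab$qbic == min(tab$qbic, na.rm = TRUE)
  tab
}

# new spec of the same kind/intercept/placement with a different df and
# data-driven knots
respec_df <- function(spec, df) {
  basis_spec(kind = spec$kind, df = as.integer(df),
             intercept = spec$intercept, placement = spec$placement)
}
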