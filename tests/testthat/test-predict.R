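test_that("the grid is a contrast against the reference", {
  toy <- fit_toy_dlnm(n = 900, L = 8, seed = 6)
  g <- predict_grid(toy$fit, toy$cb, exposures = c(5, 12, 20), reference = 20)
  i <- which(g$exposures == 20)
  expect_equal(unname(g$E[i, ]), rep(0, 9))
  expect_equal(unname(g$E_sd[i, ]), rep(0, 9))
  expect_equal(g$e_tot[i], 0)
  expect_equal(g$e_tot_sd[i], 0)
  # overall effect is the row sum of lag-specific effects
  expect_equal(g$e_tot, unname(rowSums(g$E)), tolerance = 1e-10)
  expect_true(all(g$E_sd >= 0) && all(g$e_tot_sd >= 0))
})

test_that("contrasts are additive across references", {
  toy <- fit_toy_dlnm(n = 900, L = 8, seed = 6)
  xs <- c(4, 9, 16)
  g_ref20 <- predict_grid(toy$fit, toy$cb, exposures = c(xs, 9), reference = 20)
  g_ref9 <- predict_grid(toy$fit, toy$cb, exposures = xs, reference = 9)
  for (x in xs) {
    i20 <- which(g_ref20$exposures == x)
    i9 <- which(g_ref9$exposures == x)
    j <- which(g_ref20$exposures == 9)
    expect_equal(g_ref20$E[i20, ] - g_ref20$E[j, ], g_ref9$E[i9, ],
                 tolerance = 1e-10)
  }
})

test_that("a linear predictor basis reduces to the classic DLM lag curve", {
  cfg <- sim_config(n_days = 1000, max_lag = 8, dispersion = 1.2, seed = 31,
                    surface = make_surface("linear_decay", reference = 20,
                                           slope = 0.008))
  dat <- simulate_series(cfg)
  cb <- build_crossbasis(dat$exposure, basis_spec("linear"),
                         basis_spec("natural_cubic_spline", df = 4,
                                    intercept = TRUE), 8)
  fit <- extract_fit(stats::glm(dat$count ~ cb, family = stats::quasipoisson()),
                     cb)
  # implied lag-specific linear effects: beta = C eta
  C <- unclass(evaluate_basis(attr(cb, "lag_spec"), 0:8, warn_range = FALSE))
  beta <- drop(C %*% fit$eta_hat)
  # uncentered prediction at exposure 1 is exactly beta
  g1 <- predict_grid(fit, cb, exposures = 1, reference = NULL)
  expect_equal(unname(g1$E[1, ]), unname(beta), tolerance = 1e-10)
  # centered prediction scales with (x_p - ref)
  g <- suppressWarnings(
    predict_grid(fit, cb, exposures = c(15, 25), reference = 20))
  expect_equal(unname(g$E[g$exposures == 25, ]), unname(5 * beta),
               tolerance = 1e-10)
  expect_equal(unname(g$E[g$exposures == 15, ]), unname(-5 * beta),
               tolerance = 1e-10)
})

test_that("overall standard errors match a Monte-Carlo draw from N(eta, V)", {
  toy <- fit_toy_dlnm(n = 1500, L = 10, seed = 12)
  fit <- toy$fit
  g <- suppressWarnings(
    predict_grid(fit, toy$cb, exposures = c(4, 25), reference = 20))
  # the naive no-covariance sum is wrong ...
  naive <- sqrt(rowSums(g$E_sd^2))
  expect_gt(max(abs(naive - g$e_tot_sd) / g$e_tot_sd), 0.05)
  # ... while the quadratic form matches simulation under the fitted law
  set.seed(2024)
  p <- length(fit$eta_hat)
  draws <- matrix(stats::rnorm(1e5 * p), 1e5, p) %*% chol(fit$vcov)
  var_spec <- attr(toy$cb, "var_spec")
  lag_spec <- attr(toy$cb, "lag_spec")
  C <- unclass(evaluate_basis(lag_spec, 0:10, warn_range = FALSE))
  for (x in c(4, 25)) {
    zc <- unclass(evaluate_basis(var_spec, x, warn_range = FALSE))[1, ] -
      unclass(evaluate_basis(var_spec, 20, warn_range = FALSE))[1, ]
    a_tot <- as.vector(kronecker(zc, colSums(C)))
    mc_sd <- stats::sd(draws %*% a_tot)
    i <- which(g$exposures == x)
    expect_equal(g$e_tot_sd[i], mc_sd, tolerance = 0.02)
  }
})

test_that("risk-scale conversion exponentiates with normal intervals", {
  toy <- fit_toy_dlnm(n = 900, L = 8, seed = 6)
  g <- predict_grid(toy$fit, toy$cb, exposures = c(5, 20), reference = 20)
  tab <- to_risk_scale(g, level = 0.95)
  expect_setequal(unique(tab$lag), c(as.character(0:8), "overall"))
  ref_rows <- tab[tab$exposure == 20, ]
  expect_true(all(ref_rows$rr == 1))
  # CI endpoints are symmetric around the effect on the log scale
  expect_equal(log(tab$rr_high) - tab$effect, tab$effect - log(tab$rr_low))
  # the reporting convention: a point estimate near 1.24 whose 95% limits
  # print as 1.13 and 1.36 (CI symmetric on the log scale)
  sd <- (log(1.36) - log(1.13)) / (2 * stats::qnorm(0.975))
  gx <- g
  gx$e_tot <- rep((log(1.36) + log(1.13)) / 2, length(g$exposures))
  gx$e_tot_sd <- rep(sd, length(g$exposures))
  tx <- to_risk_scale(gx, 0.95)
  ov <- tx[tx$lag == "overall", ][1, ]
  expect_equal(ov$rr, 1.24, tolerance = 0.005)
  expect_equal(ov$rr_low, 1.13, tolerance = 1e-10)
  expect_equal(ov$rr_high, 1.36, tolerance = 1e-10)
  # narrower level nests inside wider
  t90 <- to_risk_scale(g, 0.90)
  t95 <- to_risk_scale(g, 0.95)
  pos <- g$E_sd[1, 1] > 0  # a non-reference row exists
  nz <- tab$sd > 0
  expect_true(all(t90$rr_low[nz] > t95$rr_low[nz]))
  expect_true(all(t90$rr_high[nz] < t95$rr_high[nz]))
  expect_error(to_risk_scale({
    gi <- g; gi$link <- "identity"; gi
  }), "log link")
})

test_that("slices index the grid without interpolation", {
  toy <- fit_toy_dlnm(n = 900, L = 8, seed = 6)
  g <- predict_grid(toy$fit, toy$cb, exposures = c(5, 12, 20), reference = 20)
  s0 <- slice_grid(g, lag = 0)
  expect_equal(nrow(s0), 3)
  expect_equal(s0$effect, unname(g$E[, 1]))
  sref <- slice_grid(g, exposure = 20)
  expect_equal(sref$effect, rep(0, 9), ignore_attr = TRUE)
  # slices over all lags reassemble the grid
  E2 <- vapply(0:8, function(l) slice_grid(g, lag = l)$effect, numeric(3))
  expect_equal(E2, unclass(g$E), ignore_attr = TRUE)
  expect_error(slice_grid(g, lag = 99), "not on the grid")
  expect_error(slice_grid(g, exposure = 7.77), "not on the grid")
  expect_error(slice_grid(g), "exactly one")
})

test_that("grid export writes the long CSV with a JSON sidecar", {
  toy <- fit_toy_dlnm(n = 900, L = 8, seed = 6)
  g <- predict_grid(toy$fit, toy$cb, exposures = c(5, 20), reference = 20)
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "grid.csv")
  write_grid(g, csv)
  expect_true(file.exists(csv))
  expect_true(file.exists(file.path(dir, "grid_meta.json")))
  tab <- utils::read.csv(csv)
  expect_named(tab, c("exposure", "lag", "effect", "sd", "rr", "rr_low",
                      "rr_high"))
  expect_equal(nrow(tab), 2 * (9 + 1))
  meta <- jsonlite::read_json(file.path(dir, "grid_meta.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$reference, 20)
  expect_equal(meta$recipe$L, 8)
  # the sidecar recipe rebuilds a working skeleton
  skel <- crossbasis_from_recipe(meta$recipe)
  g2 <- predict_grid(toy$fit, skel, exposures = c(5, 20), reference = 20)
  expect_equal(g2$E, g$E)
})

test_that("mismatched fit and cross-basis are rejected", {
  toy <- fit_toy_dlnm(n = 900, L = 8, seed = 6)
  other <- build_crossbasis(toy$dat$exposure,
                            basis_spec("natural_cubic_spline", df = 3),
                            basis_spec("natural_cubic_spline", df = 3,
                                       intercept = TRUE), 8)
  expect_error(predict_grid(toy$fit, other, reference = 20), "column order")
  bad <- toy$fit
  bad$vcov[1, 2] <- bad$vcov[2, 1] <- 1e3  # break positive semidefiniteness
  expect_error(predict_grid(bad, toy$cb, exposures = 5, reference = 20),
               "positive semidefinite")
  expect_error(predict_grid(toy$fit, toy$cb, exposures = 5),
               "reference")
})
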