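test_that("threshold and polynomial bases evaluate to their defining forms", {
  th <- basis_spec("threshold", knots = 3)
  expect_equal(unname(unclass(evaluate_basis(th, 5, warn_range = FALSE))[1, 1]), 2)
  expect_equal(unname(unclass(evaluate_basis(th, 2, warn_range = FALSE))[1, 1]), 0)
  expect_equal(unname(unclass(evaluate_basis(th, c(2, 3, 3.5, 10)))[, 1]),
               c(0, 0, 0.5, 7))
  po <- basis_spec("polynomial", degree = 2)
  expect_equal(unname(unclass(evaluate_basis(po, 3))[1, ]), c(3, 9))
  poi <- basis_spec("polynomial", degree = 2, intercept = TRUE)
  expect_equal(unname(unclass(evaluate_basis(poi, 3))[1, ]), c(1, 3, 9))
  expect_equal(unname(unclass(evaluate_basis(basis_spec("constant"), 1:3))[, 1]),
               rep(1, 3))
})

test_that("basis dimensions follow the df conventions", {
  expect_equal(basis_dimension(basis_spec("linear")), 1L)
  expect_equal(basis_dimension(basis_spec("constant")), 1L)
  expect_equal(basis_dimension(
    basis_spec("natural_cubic_spline", knots = c(2, 4, 6, 8),
               boundary = c(0, 10))), 5L)
  expect_equal(basis_dimension(
    basis_spec("natural_cubic_spline", knots = c(2, 4, 6, 8),
               boundary = c(0, 10), intercept = TRUE)), 6L)
  expect_equal(basis_dimension(basis_spec("threshold", knots = c(1, 2))), 2L)
  expect_equal(basis_dimension(basis_spec("strata", knots = c(1, 2))), 2L)
  expect_equal(basis_dimension(
    basis_spec("strata", knots = c(1, 2), intercept = TRUE)), 3L)
  # identity over the lag vector 0..30: one indicator per lag
  id <- evaluate_basis(basis_spec("identity"), 0:30)
  expect_equal(ncol(id), 31L)
  expect_equal(unclass(id), diag(31), ignore_attr = TRUE)
  # evaluated matrices agree with the declared dimension
  x <- toy_exposure(100)
  for (spec in list(basis_spec("natural_cubic_spline", df = 5),
                    basis_spec("polynomial", degree = 3),
                    basis_spec("strata", df = 3),
                    basis_spec("threshold", df = 2))) {
    m <- evaluate_basis(spec, x)
    expect_equal(ncol(m), basis_dimension(attr(m, "spec")))
  }
})

test_that("natural cubic spline matches the truncated-power construction", {
  x <- seq(0, 10, length.out = 200)
  knots <- c(2, 4.5, 7)
  B <- unclass(evaluate_basis(
    basis_spec("natural_cubic_spline", knots = knots, boundary = c(0, 10),
               intercept = TRUE), x))
  O <- ns_truncated_power(x, knots, c(0, 10))
  expect_equal(ncol(B), ncol(O))
  # identical function spaces: each construction's columns are reproduced
  # exactly by the other after the same column conditioning (projection)
  expect_lt(span_residual(B, O), 1e-8)
  expect_lt(span_residual(O, B), 1e-8)
  # without intercept the columns still lie in the full natural spline space
  B0 <- unclass(evaluate_basis(
    basis_spec("natural_cubic_spline", knots = knots, boundary = c(0, 10)), x))
  expect_lt(span_residual(B0, O), 1e-8)
  expect_equal(ncol(B0), ncol(O) - 1L)
  expect_equal(qr(cbind(1, B0))$rank, ncol(O))
})

test_that("natural splines are linear beyond the boundary knots", {
  spec <- basis_spec("natural_cubic_spline", knots = c(3, 5, 7),
                     boundary = c(1, 9))
  h <- 1e-3
  second_deriv <- function(x0) {
    m <- unclass(evaluate_basis(spec, c(x0 - h, x0, x0 + h),
                                warn_range = FALSE))
    (m[1, ] - 2 * m[2, ] + m[3, ]) / h^2
  }
  interior_max <- max(abs(vapply(seq(1.5, 8.5, by = 0.5), second_deriv,
                                 numeric(4))))
  outside <- max(abs(vapply(c(-2, 0.5, 9.5, 12), second_deriv, numeric(4))))
  expect_lt(outside, 1e-6 * interior_max)
})

test_that("spline fits are invariant to shifting inputs and knots", {
  x <- seq(-3, 14, length.out = 120)
  shift <- 100
  B1 <- unclass(evaluate_basis(
    basis_spec("natural_cubic_spline", knots = c(2, 6, 9),
               boundary = c(-3, 14), intercept = TRUE), x))
  B2 <- unclass(evaluate_basis(
    basis_spec("natural_cubic_spline", knots = c(2, 6, 9) + shift,
               boundary = c(-3, 14) + shift, intercept = TRUE), x + shift))
  expect_lt(max(abs(proj_mat(B1) - proj_mat(B2))), 1e-8)
})

test_that("strata indicators partition the range", {
  x <- toy_exposure(300)
  m <- unclass(evaluate_basis(
    basis_spec("strata", knots = c(5, 10, 15), intercept = TRUE), x))
  expect_true(all(rowSums(m) == 1))
  expect_true(all(m %in% c(0, 1)))
  # without intercept the lowest interval is the dropped reference
  m0 <- unclass(evaluate_basis(basis_spec("strata", knots = c(5, 10, 15)), x))
  expect_equal(m0, m[, -1], ignore_attr = TRUE)
})

test_that("evaluation is deterministic and propagates missing values", {
  spec <- basis_spec("natural_cubic_spline", df = 4)
  x <- toy_exposure(50)
  expect_identical(unclass(evaluate_basis(spec, x)),
                   unclass(evaluate_basis(spec, x)))
  fixed <- basis_spec("natural_cubic_spline", knots = c(5, 10),
                      boundary = c(0, 20))
  rep5 <- unclass(evaluate_basis(fixed, rep(7.3, 5), warn_range = FALSE))
  for (i in 2:5) expect_identical(rep5[i, ], rep5[1, ])
  xm <- x; xm[c(3, 17)] <- NA
  m <- evaluate_basis(basis_spec("polynomial", degree = 2), xm)
  expect_true(all(is.na(m[c(3, 17), ])))
  expect_true(all(!is.na(m[-c(3, 17), ])))
})

test_that("invalid specs and inputs are rejected", {
  expect_error(basis_spec("natural_cubic_spline", knots = c(4, 2)),
               "increasing")
  expect_error(basis_spec("linear", intercept = TRUE), "intercept")
  expect_error(basis_spec("natural_cubic_spline", knots = c(2, 12),
                          boundary = c(0, 10)), "inside")
  expect_error(evaluate_basis(basis_spec("identity"), c(0.5, 1.2)),
               "integer")
  expect_warning(evaluate_basis(basis_spec("threshold", knots = 50),
                                toy_exposure(100)), "range")
  expect_error(basis_dimension(
    structure(list(kind = "bogus"), class = "basis_spec")), "unknown")
})

test_that("log-scale lag knots are denser at short lags", {
  expect_equal(make_lag_knots(30, 1), sqrt(30))
  k <- make_lag_knots(30, 3)
  expect_length(k, 3)
  expect_true(all(diff(k) > 0))
  expect_true(all(k > 0 & k < 30))
  expect_lt(k[2] - k[1], k[3] - k[2])
  expect_error(make_lag_knots(2, 2), "smaller")
})

test_that("basis specs round-trip through plain lists and JSON", {
  spec <- basis_spec("natural_cubic_spline", knots = c(2, 5), boundary = c(0, 9),
                     intercept = TRUE)
  back <- basis_spec_from_list(basis_spec_to_list(spec))
  expect_equal(back, spec)
  # through JSON, as embedded in output files
  js <- jsonlite::toJSON(basis_spec_to_list(spec), auto_unbox = TRUE, digits = NA)
  back2 <- basis_spec_from_list(jsonlite::fromJSON(js))
  x <- seq(0, 9, length.out = 40)
  expect_equal(unclass(evaluate_basis(back2, x)),
               unclass(evaluate_basis(spec, x)), ignore_attr = TRUE)
})
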