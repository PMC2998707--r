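# Independent oracle constructions used across tests. These deliberately
# avoid the package's own code paths (and splines::ns) so that agreement is
# informative.

# Natural cubic spline basis via the textbook truncated-power construction:
# with knots xi_1 < ... < xi_K (boundary knots included), the K basis
# functions are 1, x, and N_{k+2} = d_k - d_{K-1}, where
# d_k(x) = ((x - xi_k)_+^3 - (x - xi_K)_+^3) / (xi_K - xi_k).
# Spans the space of cubic splines linear beyond the boundary knots.
ns_truncated_power <- function(x, internal_knots, boundary) {
  xi <- c(boundary[1], internal_knots, boundary[2])
  K <- length(xi)
  d <- function(k) {
    (pmax(x - xi[k], 0)^3 - pmax(x - xi[K], 0)^3) / (xi[K] - xi[k])
  }
  cols <- cbind(1, x)
  for (k in seq_len(K - 2)) cols <- cbind(cols, d(k) - d(K - 1))
  cols
}

# Projection matrix onto the column space of B (tolerant of conditioning).
proj_mat <- function(B) {
  q <- qr.Q(qr(B))
  tcrossprod(q)
}

# max abs residual of each column of A after projection onto span(B)
span_residual <- function(A, B) {
  P <- proj_mat(B)
  max(abs(A - P %*% A))
}

# Brute-force cross-basis: naive quadruple loop over (t, j, k, l) computing
# w_{t,(j,k)} = sum_l z_{t-l, j} c_{l, k}, NA where the history is short.
brute_force_crossbasis <- function(x, Z, C, L) {
  n <- length(x)
  v_x <- ncol(Z); v_l <- ncol(C)
  W <- matrix(NA_real_, n, v_x * v_l)
  for (t in seq_len(n)) {
    if (t <= L) next
    for (j in seq_len(v_x)) {
      for (k in seq_len(v_l)) {
        s <- 0
        for (l in 0:L) s <- s + Z[t - l, j] * C[l + 1, k]
        W[t, (j - 1) * v_l + k] <- s
      }
    }
  }
  W
}

# A deterministic temperature-like series without using the generator.
toy_exposure <- function(n, seed = 1) {
  set.seed(seed)
  12 + 8 * cos(2 * pi * seq_len(n) / 365.25) + rnorm(n, 0, 3)
}

# Small simulated study fit used by several tests.
fit_toy_dlnm <- function(n = 1200, L = 10, seed = 3,
                         surface = "ushape_decay", dispersion = 1.5,
                         var_spec = basis_spec("polynomial", degree = 2),
                         lag_spec = basis_spec("natural_cubic_spline",
                                               df = 4, intercept = TRUE)) {
  cfg <- sim_config(n_days = n, surface = surface, max_lag = L,
                    dispersion = dispersion, seed = seed)
  dat <- simulate_series(cfg)
  cb <- build_crossbasis(dat$exposure, var_spec, lag_spec, L)
  t <- seq_len(n)
  fit <- stats::glm(dat$count ~ cb + cos(2 * pi * t / 365.25) +
                      sin(2 * pi * t / 365.25),
                    family = stats::quasipoisson())
  list(cfg = cfg, dat = dat, cb = cb, model = fit,
       fit = extract_fit(fit, cb))
}
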