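# Matern correlation, SPDE precision, AR(1) coupling, PC priors, sampling.

# independent Bessel oracle: K_nu(x) = int_0^inf exp(-x cosh t) cosh(nu t) dt
bessel_k_oracle <- function(x, nu) {
  stats::integrate(function(t) exp(-x * cosh(t)) * cosh(nu * t),
                   0, 30, rel.tol = 1e-12)$value
}

test_that("Matern correlation endpoints and monotonicity", {
  expect_equal(matern_correlation(0, kappa = 2), 1.0)
  expect_lt(matern_correlation(1e6, kappa = 1), 1e-12)
  h <- seq(0.01, 3, by = 0.01)
  expect_true(all(diff(matern_correlation(h, kappa = 1.5)) < 0))
  expect_true(all(matern_correlation(h, kappa = 1.5) > 0))
  expect_error(matern_correlation(-1, 1), "non-negative")
})

test_that("correlation at the reported range is 0.1397 (rounds to 0.1)", {
  for (kappa in c(0.5, 1, 8.81)) {
    h <- sqrt(8) / kappa
    oracle <- (kappa * h) * bessel_k_oracle(kappa * h, 1)
    got <- matern_correlation(h, kappa)
    expect_equal(got, oracle, tolerance = 1e-9)
    expect_equal(got, 0.1397, tolerance = 1e-3)
    expect_equal(round(got, 1), 0.1)
    expect_true(got > 0.10 && got < 0.15)
  }
})

test_that("range/scale conversions", {
  expect_equal(kappa_from_range(sqrt(8)), 1.0)
  expect_equal(kappa_from_range(0.321), sqrt(8) / 0.321)
  expect_equal(kappa_from_range(0.321), 8.811, tolerance = 1e-3)
  rho <- c(0.05, 0.5, 5)
  expect_equal(range_from_kappa(kappa_from_range(rho)), rho, tolerance = 1e-12)
  expect_error(kappa_from_range(0), "positive")
  expect_error(range_from_kappa(-1), "positive")
})

test_that("tau gives the prescribed marginal SD", {
  expect_equal(tau_from_sigma(1, 1), 1 / sqrt(4 * pi), tolerance = 1e-6)
  expect_equal(tau_from_sigma(1, 1), 0.28209, tolerance = 1e-4)
  expect_equal(tau_from_sigma(2, 1.3), tau_from_sigma(1, 1.3) / 2)
  expect_error(tau_from_sigma(-1, 1), "positive")
})

test_that("simulated field SD matches sigma at interior vertices", {
  m <- fine_square_mesh()
  fem <- fem_matrices(m)
  sigma <- 1.3; rho <- 0.4
  kap <- kappa_from_range(rho)
  Q <- spatial_precision(kap, tau_from_sigma(sigma, kap), fem)
  x <- sample_field(Q, seed = 21, n_draws = 400)
  interior <- m$loc[, 1] > 0.25 & m$loc[, 1] < 0.75 &
              m$loc[, 2] > 0.25 & m$loc[, 2] < 0.75
  sds <- apply(x[interior, ], 1, sd)
  mc_se <- sigma / sqrt(2 * 400)
  expect_lt(abs(mean(sds) - sigma), 3 * mc_se + 0.05 * sigma)
})

test_that("spatial precision: dominant term, symmetry, SPD", {
  fem1 <- fem_matrices(square_mesh())
  tau <- 0.3
  q_large <- spatial_precision(1e4, tau, fem1)
  ref <- tau^2 * 1e16 * fem1$c0
  expect_lt(Matrix::norm(q_large - ref, "F") / Matrix::norm(ref, "F"), 1e-6)

  m <- fine_square_mesh(spacing = 0.25, max_edge = 0.35)
  fem <- fem_matrices(m)
  kap <- kappa_from_range(0.4)
  Q <- spatial_precision(kap, tau_from_sigma(1, kap), fem)
  expect_lt(max(abs(Q - Matrix::t(Q))), 1e-12)
  ev <- eigen(as.matrix(Q), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("SPDE correlations track the Matern function", {
  m <- suppressWarnings(build_mesh(hex_lattice(0.065), max_edge = 0.07,
                                   cutoff = 0.065 / 4, extend_offset = 0.1))
  expect_lte(m$n, 600)
  fem <- fem_matrices(m)
  rho <- 0.5
  kap <- kappa_from_range(rho)
  Q <- spatial_precision(kap, tau_from_sigma(1, kap), fem)
  V <- solve(as.matrix(Q))
  interior <- which(m$loc[, 1] > 0.2 & m$loc[, 1] < 0.8 &
                    m$loc[, 2] > 0.2 & m$loc[, 2] < 0.8)
  i0 <- interior[which.min((m$loc[interior, 1] - 0.5)^2 +
                           (m$loc[interior, 2] - 0.5)^2)]
  h <- sqrt((m$loc[interior, 1] - m$loc[i0, 1])^2 +
            (m$loc[interior, 2] - m$loc[i0, 2])^2)
  corr <- V[interior, i0] / sqrt(diag(V)[interior] * V[i0, i0])
  sel <- h >= 0.07 & h <= 1.5 * rho
  expect_gt(sum(sel), 20)
  expect_lt(max(abs(corr[sel] - matern_correlation(h[sel], kap))), 0.05)
})

test_that("AR(1) precision matches hand-inverted covariances", {
  expect_equal(as.matrix(ar1_precision(0, 3)), diag(3), tolerance = 1e-12)
  q <- as.matrix(ar1_precision(0.5, 3))
  expect_equal(diag(q), c(4, 5, 4) / 3, tolerance = 1e-12)
  expect_equal(q[1, 2], -2 / 3, tolerance = 1e-12)
  expect_equal(q[1, 3], 0)
  # inverse is a^|i-j| (unit marginal variance)
  a <- 0.627; T <- 5
  V <- solve(as.matrix(ar1_precision(a, T)))
  expect_equal(V[1, T], a^(T - 1), tolerance = 1e-10)
  expect_equal(diag(V), rep(1, T), tolerance = 1e-10)
  expect_error(ar1_precision(1, 4), "stationarity")
})

test_that("space-time precision: block structure, stationarity, persistence", {
  m <- fine_square_mesh(spacing = 0.3, max_edge = 0.45)
  fem <- fem_matrices(m)
  spde <- list(rho = 0.5, sigma = 1.2)

  # a = 0: block diagonal with T identical spatial blocks
  Q0 <- spacetime_precision(spde, list(a = 0, n_years = 3), fem)
  n <- m$n
  kap <- kappa_from_range(spde$rho)
  qs <- spatial_precision(kap, tau_from_sigma(spde$sigma, kap), fem)
  expect_lt(max(abs(Q0[1:n, 1:n] - qs)), 1e-10)
  expect_equal(max(abs(Q0[1:n, (n + 1):(2 * n)])), 0)

  # marginal variance at each vertex is independent of the year
  a <- 0.627
  Q <- spacetime_precision(spde, list(a = a, n_years = 4), fem)
  V <- solve(as.matrix(Q))
  interior <- which(!m$boundary)
  vars <- sapply(0:3, function(t) diag(V)[t * n + interior])
  spread <- apply(vars, 1, function(v) diff(range(v)) / mean(v))
  expect_lt(max(spread), 0.02)
  # lag-1 correlation equals a at a fixed interior vertex
  v0 <- interior[1]
  expect_equal(V[v0, n + v0] / sqrt(V[v0, v0] * V[n + v0, n + v0]), a,
               tolerance = 1e-6)

  # simulation oracle for the persistence
  x <- sample_field(Q, seed = 5, n_draws = 2000)
  x1 <- as.vector(x[interior, ]); x2 <- as.vector(x[n + interior, ])
  r <- cor(x1, x2)
  expect_lt(abs(r - a), 3 * (1 - a^2) / sqrt(2000) + 0.03)
})

test_that("PC prior calibration statements hold by numerical integration", {
  pr <- pc_prior(rho0 = 0.5, alpha_rho = 0.5, sigma0 = 0.75, alpha_sigma = 0.5)
  p_below <- stats::integrate(function(r) pr$lambda_rho * r^-2 *
                                exp(-pr$lambda_rho / r), 0, 0.5,
                              rel.tol = 1e-10)$value
  expect_equal(p_below, 0.5, tolerance = 1e-6)
  p_above <- stats::integrate(function(s) pr$lambda_sigma *
                                exp(-pr$lambda_sigma * s), 0.75, Inf,
                              rel.tol = 1e-10)$value
  expect_equal(p_above, 0.5, tolerance = 1e-6)

  # joint density integrates to 1 (product form)
  tot_rho <- stats::integrate(function(r) pr$lambda_rho * r^-2 *
                                exp(-pr$lambda_rho / r), 0, Inf)$value
  tot_sig <- stats::integrate(function(s) pr$lambda_sigma *
                                exp(-pr$lambda_sigma * s), 0, Inf)$value
  expect_equal(tot_rho * tot_sig, 1, tolerance = 1e-4)

  # density is consistent with the calibrated rates
  expect_equal(pc_prior_log_density(0.4, 0.6, pr),
               log(pr$lambda_rho) - 2 * log(0.4) - pr$lambda_rho / 0.4 +
               log(pr$lambda_sigma) - pr$lambda_sigma * 0.6,
               tolerance = 1e-12)
})

test_that("PC prior quantiles hold on a calibration grid", {
  for (rho0 in c(0.2, 1, 3)) for (alpha in c(0.2, 0.5, 0.8)) {
    pr <- pc_prior(rho0 = rho0, alpha_rho = alpha, sigma0 = 1,
                   alpha_sigma = alpha)
    p <- stats::integrate(function(r) pr$lambda_rho * r^-2 *
                            exp(-pr$lambda_rho / r), 0, rho0,
                          rel.tol = 1e-10)$value
    expect_equal(p, alpha, tolerance = 1e-6)
    ps <- stats::integrate(function(s) pr$lambda_sigma *
                             exp(-pr$lambda_sigma * s), 1, Inf)$value
    expect_equal(ps, alpha, tolerance = 1e-6)
  }
  expect_error(pc_prior(rho0 = -1), "positive")
  expect_error(pc_prior_log_density(0.5, 0.5, list(a = 1)), "calibrated")
})

test_that("precision matrices round-trip through the triplet text format", {
  fem <- fem_matrices(square_mesh())
  Q <- spatial_precision(2, 0.5, fem)
  path <- tempfile(fileext = ".txt")
  write_precision_triplets(Q, path)
  Q2 <- read_precision_triplets(path)
  expect_lt(max(abs(Q - Q2)), 1e-15)
})

test_that("field sampling is reproducible, zero-mean, with covariance Q^-1", {
  m <- fine_square_mesh(spacing = 0.35, max_edge = 0.5)
  fem <- fem_matrices(m)
  Q <- spacetime_precision(list(rho = 0.5, sigma = 1),
                           list(a = 0.4, n_years = 2), fem)
  x1 <- sample_field(Q, seed = 42)
  x2 <- sample_field(Q, seed = 42)
  expect_identical(x1, x2)

  nd <- 5000
  X <- sample_field(Q, seed = 7, n_draws = nd)
  V <- solve(as.matrix(Q))
  se_mean <- sqrt(diag(V) / nd)
  expect_true(all(abs(rowMeans(X)) < 4 * se_mean + 1e-9))
  S <- tcrossprod(X - rowMeans(X)) / (nd - 1)
  se_cov <- sqrt((outer(diag(V), diag(V)) + V^2) / nd)
  expect_true(all(abs(S - V) < 5 * se_cov + 1e-9))
})
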