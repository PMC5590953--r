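# Laplace inner approximation, hyperparameter optimization, prediction.

test_that("gaussian-likelihood mode equals the GLS solution", {
  set.seed(41)
  n <- 60
  df <- data.frame(lon = runif(n), lat = runif(n), year = 2000L,
                   count = rpois(n, 8))
  spec <- model_spec(spatial = "constant", family = "gaussian",
                     gaussian_sd = 1.4)
  theta <- c(log_rho = log(0.4), log_sigma = log(1.1))
  ga <- gaussian_approximation(spec, survey_dataset(df), theta = theta,
                               mesh_args = list(max_edge = 0.3, cutoff = 0.03))
  fr <- ga$frame
  Qp <- gmrfish:::.prior_precision(fr, ga$theta)$Q
  M <- as.matrix(fr$M)
  H <- as.matrix(Qp) + crossprod(M) / 1.4^2
  gls <- solve(H, crossprod(M, df$count) / 1.4^2)
  expect_equal(ga$mode, as.numeric(gls), tolerance = 1e-10)
  expect_true(ga$converged)
})

test_that("Laplace evidence is exact for a gaussian likelihood", {
  set.seed(42)
  n <- 40
  df <- data.frame(lon = runif(n), lat = runif(n), year = 2000L,
                   count = rpois(n, 5))
  sd <- 1.1
  spec <- model_spec(spatial = "constant", family = "gaussian",
                     gaussian_sd = sd)
  theta <- c(log_rho = log(0.5), log_sigma = log(0.9))
  ga <- gaussian_approximation(spec, survey_dataset(df), theta = theta,
                               mesh_args = list(max_edge = 0.35, cutoff = 0.03))
  fr <- ga$frame
  Qp <- as.matrix(gmrfish:::.prior_precision(fr, ga$theta)$Q)
  M <- as.matrix(fr$M)
  S <- M %*% solve(Qp, t(M)) + sd^2 * diag(n)
  y <- df$count
  exact <- -0.5 * (n * log(2 * pi) + determinant(S)$modulus +
                   t(y) %*% solve(S, y))
  expect_equal(ga$log_evidence, as.numeric(exact), tolerance = 1e-8)
})

test_that("zero counts pull every fitted mean below 1", {
  set.seed(43)
  n <- 50
  df <- data.frame(lon = runif(n), lat = runif(n), year = 2000L,
                   count = 0L)
  spec <- model_spec(spatial = "constant", family = "poisson")
  ga <- gaussian_approximation(spec, survey_dataset(df),
                               mesh_args = list(max_edge = 0.4, cutoff = 0.03))
  expect_true(all(exp(ga$eta) < 1))
})

test_that("the inner mode is independent of the starting point", {
  set.seed(44)
  n <- 70
  df <- data.frame(lon = runif(n), lat = runif(n), year = 2000L,
                   count = rpois(n, 4))
  spec <- model_spec(spatial = "constant", family = "poisson")
  fr <- gmrfish:::.build_frame(spec, survey_dataset(df),
                               mesh_args = list(max_edge = 0.35, cutoff = 0.03))
  th <- gmrfish:::.theta_init(fr)
  prior <- gmrfish:::.prior_precision(fr, th)
  op <- gmrfish:::.obs_params_from_theta(fr, th)
  m1 <- gmrfish:::.inner_laplace(fr, prior, op, start = numeric(fr$p))
  m2 <- gmrfish:::.inner_laplace(fr, prior, op,
                                 start = rnorm(fr$p, 0, 0.5))
  expect_equal(m1$mode, m2$mode, tolerance = 1e-8)
})

test_that("grid weights are normalized and the fit reports the posterior mode", {
  sv <- small_survey(seed = 2, n_years = 3, sets = 50)
  spec <- model_spec(spatial = "ar1", family = "negative_binomial")
  fit <- fit_abundance_model(spec, sv,
                             mesh_args = list(max_edge = 0.25, cutoff = 0.05),
                             control = list(maxit = 50))
  expect_equal(sum(fit$hyper_grid$weight), 1, tolerance = 1e-12)
  expect_equal(nrow(fit$hyper_grid), 2 * 4 + 1)
  expect_true(all(fit$latent_sd > 0))
  expect_true(all(is.finite(fit$fitted_mu)))
  # the mode row carries the highest (or tied) posterior density
  expect_true(fit$hyper_grid$lp[1] >= max(fit$hyper_grid$lp) - 1e-6)
})

test_that("prediction matches fitted values at observation locations", {
  sv <- small_survey(seed = 3, n_years = 3, sets = 40)
  spec <- model_spec(spatial = "ar1", family = "negative_binomial")
  fit <- fit_abundance_model(spec, sv,
                             mesh_args = list(max_edge = 0.3, cutoff = 0.04),
                             control = list(maxit = 40, grid = FALSE))
  i <- which(sv$year == sv$year[1])[1:5]
  pr <- predict_surface(fit, cbind(sv$lon[i], sv$lat[i]), year = sv$year[1])
  expect_equal(pr$mean, fit$fitted_eta_mean[i], tolerance = 1e-8)
  expect_false(any(pr$outside))

  # a data-free boundary vertex is more uncertain than the data-dense centre
  bl <- fit$mesh$loc[which(fit$mesh$boundary)[1], ]
  pr2 <- predict_surface(fit, rbind(c(0.5, 0.5), bl), year = sv$year[1])
  expect_gt(pr2$sd[2], pr2$sd[1])

  # outside the triangulation: masked, not an error
  pr3 <- predict_surface(fit, rbind(c(50, 50)), year = sv$year[1])
  expect_true(pr3$outside[1])
  expect_true(is.na(pr3$mean[1]))
  expect_error(predict_surface(fit, rbind(c(0.5, 0.5)), year = 1900),
               "not in the fitted data")
})

test_that("a near-degenerate field prior gives a flat surface at the intercept", {
  set.seed(45)
  n <- 60
  df <- data.frame(lon = runif(n), lat = runif(n), year = 2000L,
                   count = rpois(n, exp(1.2)))
  spec <- model_spec(spatial = "constant", family = "poisson")
  fit <- fit_abundance_model(spec, survey_dataset(df),
    mesh_args = list(max_edge = 0.35, cutoff = 0.04),
    control = list(maxit = 0, grid = FALSE,
                   theta_init = c(log_rho = log(0.5), log_sigma = log(1e-4))))
  pr <- predict_surface(fit, cbind(runif(20, 0.2, 0.8), runif(20, 0.2, 0.8)))
  expect_lt(diff(range(pr$mean)), 1e-3)
  expect_equal(mean(pr$mean), fit$intercept, tolerance = 1e-4)
})

test_that("replicating every observation reduces latent uncertainty", {
  sv <- small_survey(seed = 4, n_years = 2, sets = 40)
  spec <- model_spec(spatial = "replicated", family = "negative_binomial")
  ctl <- list(maxit = 40, grid = FALSE, compute_sd = TRUE)
  fit1 <- fit_abundance_model(spec, sv,
    mesh_args = list(max_edge = 0.3, cutoff = 0.05), control = ctl)
  sv2 <- survey_dataset(rbind(as.data.frame(sv), as.data.frame(sv)))
  # hyperparameters held at the original mode: the property concerns the
  # Gaussian approximation, not re-optimized hyperparameters
  ctl2 <- list(maxit = 0, grid = FALSE, compute_sd = TRUE,
               theta_init = fit1$hyper_mode$theta)
  fit2 <- fit_abundance_model(spec, sv2, mesh = fit1$mesh, control = ctl2)
  expect_lt(mean(fit2$latent_sd), mean(fit1$latent_sd))
})

test_that("posterior intervals cover the simulated linear predictor", {
  covered <- total <- 0
  for (seed in 1:3) {
    sv <- small_survey(seed = seed, n_years = 4, sets = 60)
    truth <- attr(sv, "truth")
    spec <- model_spec(spatial = "ar1", family = "negative_binomial")
    fit <- fit_abundance_model(spec, sv,
      mesh_args = list(max_edge = 0.2, cutoff = 0.04),
      control = list(maxit = 80, grid = FALSE, compute_sd = TRUE))
    lo <- fit$fitted_eta_mean - 1.96 * fit$fitted_eta_sd
    hi <- fit$fitted_eta_mean + 1.96 * fit$fitted_eta_sd
    covered <- covered + sum(truth$eta >= lo & truth$eta <= hi)
    total <- total + fit$n_obs
  }
  expect_gte(covered / total, 0.90)
})

test_that("persistence estimates stay near zero for temporally independent fields", {
  a_hat <- vapply(1:3, function(seed) {
    sv <- small_survey(seed = 10 + seed, n_years = 10, sets = 100, a = 0)
    spec <- model_spec(spatial = "ar1", family = "negative_binomial")
    fit <- fit_abundance_model(spec, sv,
      mesh_args = list(max_edge = 0.2, cutoff = 0.05), control = fast_ctl)
    fit$hyper_mode$a
  }, numeric(1))
  expect_gte(sum(abs(a_hat) < 0.15), 2)
  expect_true(all(abs(a_hat) < 0.3))
})
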