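# Matern correlation, SPDE precision matrices, AR(1) temporal coupling and
# penalized-complexity priors. Throughout: smoothness nu = 1 and dimension
# d = 2 (SPDE order alpha = 2), so the spatial range rho (the distance at
# which correlation falls to ~0.1, exactly 0.1397 for nu = 1) satisfies
# rho = sqrt(8 nu)/kappa and the stationary marginal variance is
# sigma^2 = 1/(4 pi kappa^2 tau^2).

#' Matern correlation function
#'
#' \eqn{C(h) = (\kappa h)^\nu K_\nu(\kappa h) / (\Gamma(\nu) 2^{\nu-1})},
#' with \eqn{C(0) = 1} by continuity.
#'
#' @param h non-negative distance (vectorised).
#' @param kappa spatial scale parameter, > 0.
#' @param nu smoothness, > 0 (default 1).
#' @return correlation values in (0, 1].
#' @export
matern_correlation <- function(h, kappa, nu = 1) {
  if (any(h < 0)) stop("distance h must be non-negative")
  if (kappa <= 0 || nu <= 0) stop("kappa and nu must be positive")
  x <- kappa * h
  out <- numeric(length(x))
  z <- x > 0 & x < 705            # besselK underflows to 0 beyond ~705
  out[x == 0] <- 1
  out[z] <- x[z]^nu * besselK(x[z], nu) / (gamma(nu) * 2^(nu - 1))
  out[x >= 705] <- 0
  pmin(out, 1)
}

#' Convert spatial range to the Matern scale parameter
#'
#' The empirically reported range rho is the distance at which the Matern
#' correlation drops to about 0.1; \eqn{\kappa = \sqrt{8\nu}/\rho}.
#'
#' @param rho spatial range, > 0.
#' @param nu smoothness (default 1).
#' @export
kappa_from_range <- function(rho, nu = 1) {
  if (any(rho <= 0)) stop("rho must be positive")
  sqrt(8 * nu) / rho
}

#' Inverse of \code{kappa_from_range}
#' @param kappa scale parameter, > 0.
#' @param nu smoothness (default 1).
#' @export
range_from_kappa <- function(kappa, nu = 1) {
  if (any(kappa <= 0)) stop("kappa must be positive")
  sqrt(8 * nu) / kappa
}

#' Precision scaling giving a prescribed marginal standard deviation
#'
#' For nu = 1 in two dimensions the stationary Matern field has marginal
#' variance \eqn{1/(4\pi\kappa^2\tau^2)}; this returns the \eqn{\tau} for
#' which that variance equals \code{sigma^2}.
#'
#' @param sigma target marginal SD, > 0.
#' @param kappa scale parameter, > 0.
#' @export
tau_from_sigma <- function(sigma, kappa) {
  if (any(sigma <= 0) || any(kappa <= 0)) stop("sigma and kappa must be positive")
  1 / (sigma * kappa * sqrt(4 * pi))
}

#' SPDE spatial precision matrix
#'
#' \eqn{Q_s = \tau^2 (\kappa^4 C + 2\kappa^2 G + G C^{-1} G)} with lumped
#' mass C and stiffness G; the GMRF with this precision approximates the
#' Matern (nu = 1) field on the mesh.
#'
#' @param kappa scale, > 0.
#' @param tau precision scaling, > 0.
#' @param fem a \code{gmrfish_fem} from \code{\link{fem_matrices}}.
#' @return sparse symmetric positive-definite matrix.
#' @export
spatial_precision <- function(kappa, tau, fem) {
  if (kappa <= 0 || tau <= 0) stop("kappa and tau must be positive")
  cinv <- Matrix::Diagonal(fem$n, 1 / Matrix::diag(fem$c0))
  q <- tau^2 * (kappa^4 * fem$c0 + 2 * kappa^2 * fem$g1 +
                fem$g1 %*% cinv %*% fem$g1)
  methods::as(Matrix::forceSymmetric(q), "CsparseMatrix")
}

#' AR(1) precision matrix with unit stationary marginal variance
#'
#' Tridiagonal precision of a stationary AR(1) process scaled so every
#' marginal variance is 1; its inverse has entries \eqn{a^{|i-j|}}.
#'
#' @param a persistence coefficient, |a| < 1.
#' @param T number of time points, >= 1.
#' @export
ar1_precision <- function(a, T) {
  if (abs(a) >= 1) stop("stationarity requires |a| < 1")
  if (T < 1) stop("T must be >= 1")
  if (T == 1) return(methods::as(Matrix::Matrix(1, 1, 1, sparse = TRUE), "CsparseMatrix"))
  d <- c(1, rep(1 + a^2, T - 2), 1) / (1 - a^2)
  o <- rep(-a / (1 - a^2), T - 1)
  q <- Matrix::bandSparse(T, k = c(0, 1), diagonals = list(d, o), symmetric = TRUE)
  methods::as(q, "CsparseMatrix")
}

#' Joint space-time precision (AR(1) in time, SPDE Matern in space)
#'
#' Kronecker product of the unit-variance AR(1) precision and the spatial
#' precision scaled to marginal SD \code{spde$sigma}; every vertex-year then
#' has stationary marginal SD sigma, and the year-to-year innovation variance
#' is \eqn{\sigma^2 (1 - a^2)}. Layout is year-major: entry
#' \code{(t-1)*n + v} is vertex v in year t.
#'
#' @param spde list with elements \code{rho} and \code{sigma} (see
#'   \code{\link{spde_params}}).
#' @param temporal list with elements \code{a} and \code{n_years}.
#' @param fem a \code{gmrfish_fem}.
#' @export
spacetime_precision <- function(spde, temporal, fem) {
  kappa <- kappa_from_range(spde$rho)
  tau <- tau_from_sigma(spde$sigma, kappa)
  qs <- spatial_precision(kappa, tau, fem)
  qt <- ar1_precision(temporal$a, temporal$n_years)
  methods::as(Matrix::forceSymmetric(Matrix::kronecker(qt, qs)), "CsparseMatrix")
}

#' SPDE parameter bundle
#'
#' @param rho spatial range (connectivity), > 0.
#' @param sigma stationary marginal SD of the field (spatial variance), > 0.
#' @param nu smoothness, fixed at 1.
#' @return list with rho, sigma, kappa, tau, nu.
#' @export
spde_params <- function(rho, sigma, nu = 1) {
  if (rho <= 0 || sigma <= 0) stop("rho and sigma must be positive")
  if (nu != 1) stop("only nu = 1 is supported")
  kappa <- kappa_from_range(rho, nu)
  list(rho = rho, sigma = sigma, kappa = kappa,
       tau = tau_from_sigma(sigma, kappa), nu = nu)
}

#' Temporal (persistence) parameter bundle
#' @param a AR(1) persistence, |a| < 1.
#' @param n_years number of years.
#' @export
temporal_params <- function(a, n_years) {
  if (abs(a) >= 1) stop("stationarity requires |a| < 1")
  list(a = a, n_years = as.integer(n_years),
       sigma_omega_factor = sqrt(1 - a^2))
}

## ---- penalized-complexity priors -------------------------------------------

#' Calibrate penalized-complexity priors for (rho, sigma)
#'
#' The PC prior shrinks toward the base model rho = Inf, sigma = 0. It is
#' calibrated by two tail statements: \eqn{P(\rho < \rho_0) = \alpha_\rho}
#' and \eqn{P(\sigma > \sigma_0) = \alpha_\sigma}. With d = 2 the range
#' density is \eqn{\pi(\rho) = \lambda_\rho \rho^{-2} e^{-\lambda_\rho/\rho}}
#' with \eqn{\lambda_\rho = -\log(\alpha_\rho)\,\rho_0}; sigma is exponential
#' with rate \eqn{\lambda_\sigma = -\log(\alpha_\sigma)/\sigma_0}.
#'
#' @param rho0 reference range.
#' @param alpha_rho prior probability that rho < rho0.
#' @param sigma0 reference SD.
#' @param alpha_sigma prior probability that sigma > sigma0.
#' @return object of class \code{gmrfish_pc_prior}.
#' @export
pc_prior <- function(rho0 = 0.5, alpha_rho = 0.5, sigma0 = 0.75,
                     alpha_sigma = 0.5) {
  if (rho0 <= 0 || sigma0 <= 0) stop("rho0 and sigma0 must be positive")
  if (alpha_rho <= 0 || alpha_rho >= 1 || alpha_sigma <= 0 || alpha_sigma >= 1)
    stop("alpha probabilities must lie strictly in (0,1)")
  d <- 2
  structure(list(rho0 = rho0, alpha_rho = alpha_rho, sigma0 = sigma0,
                 alpha_sigma = alpha_sigma,
                 lambda_rho = -log(alpha_rho) * rho0^(d / 2),
                 lambda_sigma = -log(alpha_sigma) / sigma0, d = d),
            class = "gmrfish_pc_prior")
}

#' Joint PC-prior log density at (rho, sigma)
#' @param rho range value, > 0.
#' @param sigma SD value, > 0.
#' @param prior a \code{gmrfish_pc_prior}.
#' @export
pc_prior_log_density <- function(rho, sigma, prior) {
  if (!inherits(prior, "gmrfish_pc_prior") || is.null(prior$lambda_rho))
    stop("prior must be a calibrated gmrfish_pc_prior")
  if (any(rho <= 0) || any(sigma <= 0)) stop("rho and sigma must be positive")
  d <- prior$d
  lr <- prior$lambda_rho; ls <- prior$lambda_sigma
  log(d / 2) + log(lr) + (-d / 2 - 1) * log(rho) - lr * rho^(-d / 2) +
    log(ls) - ls * sigma
}

#' Write a sparse precision matrix in coordinate (triplet) text format
#'
#' One "i j x" line per stored nonzero of the lower triangle (1-based
#' indices), preceded by a "n n nnz" header line; a debugging interchange
#' format.
#'
#' @param Q sparse symmetric matrix.
#' @param path output file path.
#' @export
write_precision_triplets <- function(Q, path) {
  Tm <- methods::as(methods::as(Matrix::forceSymmetric(Q), "CsparseMatrix"),
                    "TsparseMatrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d %d", nrow(Q), ncol(Q), length(Tm@x)), con)
  writeLines(sprintf("%d %d %.17g", Tm@i + 1L, Tm@j + 1L, Tm@x), con)
  invisible(path)
}

#' Read a coordinate (triplet) precision file
#' @param path file written by \code{\link{write_precision_triplets}}.
#' @return sparse symmetric matrix.
#' @export
read_precision_triplets <- function(path) {
  hdr <- scan(path, what = integer(), nmax = 3, quiet = TRUE)
  d <- utils::read.table(path, skip = 1, col.names = c("i", "j", "x"))
  Matrix::sparseMatrix(i = d$i, j = d$j, x = d$x, dims = hdr[1:2],
                       symmetric = TRUE)
}

## ---- field simulation -------------------------------------------------------

#' Draw a zero-mean Gaussian field with a given sparse precision
#'
#' Uses the permuted sparse Cholesky factor: with \eqn{Q = P' L L' P}, the
#' draw is \eqn{x = P' L^{-T} z}, \eqn{z \sim N(0, I)}.
#'
#' @param Q sparse symmetric positive-definite precision matrix.
#' @param seed integer seed (draws are reproducible given the seed); if NULL
#'   the current RNG stream is used.
#' @param n_draws number of independent draws.
#' @return matrix with \code{nrow(Q)} rows and \code{n_draws} columns.
#' @export
sample_field <- function(Q, seed = NULL, n_draws = 1) {
  ch <- tryCatch(Matrix::Cholesky(methods::as(Matrix::forceSymmetric(Q), "CsparseMatrix"),
                                  LDL = FALSE, perm = TRUE),
                 error = function(e) stop("precision factorization failed: ", conditionMessage(e)))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(Q)
  z <- matrix(stats::rnorm(n * n_draws), n, n_draws)
  x <- Matrix::solve(ch, Matrix::solve(ch, z, system = "Lt"), system = "Pt")
  as.matrix(x)
}
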