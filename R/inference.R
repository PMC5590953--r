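# Latent-Gaussian inference: an inner Gaussian (Laplace) approximation of
# the latent field given hyperparameters, and an outer optimization over the
# hyperparameters under PC priors (empirical-Bayes mode), followed by a small
# axis grid around the mode whose normalized weights approximate the
# hyperparameter posterior. This is a deliberately simplified re-statement of
# the nested-Laplace strategy used by latent-Gaussian model software, at desk
# scale, on top of sparse Cholesky factorization.

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- model frame ------------------------------------------------------------

# Assembles everything about (spec, data, mesh) that does not depend on the
# hyperparameters: the latent layout [field | intercept | smooth contrasts],
# the sparse observation matrix M, prior building blocks, and caches for
# symbolic factorizations and warm starts.
.build_frame <- function(spec, data, mesh = NULL, mesh_args = list()) {
  data <- survey_dataset(as.data.frame(data))
  fr <- new.env(parent = emptyenv())
  fr$spec <- spec
  fr$y <- data$count
  fr$n_obs <- nrow(data)
  years <- sort(unique(data$year))
  fr$years <- years
  T <- length(years)
  if (spec$spatial == "ar1" && T < 2)
    stop("ar1 spatial structure requires at least 2 years")
  fr$T_field <- switch(spec$spatial, none = 0L, constant = 1L, T)
  yix <- match(data$year, years)

  if (spec$spatial != "none") {
    if (is.null(mesh)) {
      coords <- cbind(data$lon, data$lat)
      diam <- sqrt(sum((apply(coords, 2, max) - apply(coords, 2, min))^2))
      mesh <- do.call(build_mesh, c(list(locations = coords,
        max_edge = mesh_args$max_edge %||% (diam / 8),
        cutoff = mesh_args$cutoff %||% (diam / 40)),
        mesh_args[setdiff(names(mesh_args), c("max_edge", "cutoff"))]))
    }
    fr$mesh <- mesh
    fr$fem <- fem_matrices(mesh)
    A <- projection_matrix(mesh, cbind(data$lon, data$lat))
    if (fr$T_field > 1L) {
      trip <- Matrix::summary(methods::as(A, "TsparseMatrix"))
      A <- Matrix::sparseMatrix(i = trip$i, j = trip$j + (yix[trip$i] - 1L) * mesh$n,
                                x = trip$x, dims = c(fr$n_obs, mesh$n * fr$T_field))
    }
    fr$A_st <- A
    fr$n_vertices <- mesh$n
    fr$domain_diameter <- sqrt(sum((apply(mesh$loc, 2, max) -
                                    apply(mesh$loc, 2, min))^2))
  } else {
    fr$A_st <- NULL
    fr$n_vertices <- 0L
    fr$domain_diameter <- NA_real_
  }

  # covariate smooths (collinearity gate first)
  covs <- spec$covariates
  if (length(covs)) {
    missing_cols <- setdiff(covs, names(data))
    if (length(missing_cols)) stop("covariates not in data: ",
                                   paste(missing_cols, collapse = ", "))
    if (length(covs) >= 2) {
      R <- stats::cor(as.data.frame(data)[covs],
                      use = "pairwise.complete.obs")
      bad <- which(abs(R) >= spec$collinearity_threshold & row(R) < col(R),
                   arr.ind = TRUE)
      if (nrow(bad)) stop("covariates rejected together (|r| >= ",
                          spec$collinearity_threshold, "): ",
                          paste(covs[bad[1, 1]], covs[bad[1, 2]], sep = " ~ "))
    }
  }
  fr$smooths <- lapply(covs, function(nm)
    build_covariate_smooth(data[[nm]], n_knots = spec$n_knots, name = nm))
  names(fr$smooths) <- covs

  # latent layout
  nf <- fr$n_vertices * fr$T_field
  fr$idx_field <- if (nf) seq_len(nf) else integer(0)
  fr$idx_intercept <- nf + 1L
  off <- nf + 1L
  fr$idx_gamma <- list()
  blocks <- list()
  if (!is.null(fr$A_st)) blocks <- c(blocks, list(fr$A_st))
  blocks <- c(blocks, list(Matrix::Matrix(1, fr$n_obs, 1, sparse = TRUE)))
  for (nm in covs) {
    sm <- fr$smooths[[nm]]
    kz <- ncol(sm$Z)
    fr$idx_gamma[[nm]] <- off + seq_len(kz)
    off <- off + kz
    blocks <- c(blocks, list(sm$design %*% sm$Z))
  }
  fr$p <- off
  fr$M <- methods::as(do.call(cbind, blocks), "CsparseMatrix")
  fr$intercept_prec <- 1e-2       # weak N(0, 10^2) prior on the intercept
  fr$smooth_ridge <- 1e-6         # proper prior in the RW2 linear null direction
  fr$smooth_S <- lapply(fr$smooths, function(sm) {
    S <- t(sm$Z) %*% sm$penalty %*% sm$Z
    list(S = S, eig = pmax(eigen(S, symmetric = TRUE, only.values = TRUE)$values, 0))
  })
  fr$chQs <- NULL; fr$chH <- NULL; fr$last_mode <- NULL; fr$gscale <- NULL
  fr$data <- data
  fr
}

# hyperparameter vector layout for a frame
.theta_names <- function(fr) {
  spec <- fr$spec
  nm <- character(0)
  if (spec$spatial != "none") nm <- c(nm, "log_rho", "log_sigma")
  if (spec$spatial == "ar1") nm <- c(nm, "z_a")
  if (spec$family == "negative_binomial") nm <- c(nm, "phi")
  if (length(fr$smooths)) nm <- c(nm, paste0("log_tf_", names(fr$smooths)))
  nm
}

.theta_init <- function(fr) {
  nm <- .theta_names(fr)
  th <- stats::setNames(numeric(length(nm)), nm)
  if ("log_rho" %in% nm) th["log_rho"] <- log(0.25 * fr$domain_diameter)
  if ("log_sigma" %in% nm) th["log_sigma"] <- 0
  if ("z_a" %in% nm) th["z_a"] <- log(3)      # a = 0.5
  if ("phi" %in% nm) th["phi"] <- 1
  th
}

.theta_decode <- function(fr, theta) {
  out <- list()
  if (fr$spec$spatial != "none") {
    out$rho <- exp(theta[["log_rho"]])
    out$sigma <- exp(theta[["log_sigma"]])
  }
  out$a <- if (fr$spec$spatial == "ar1") {
    z <- theta[["z_a"]]; (exp(z) - 1) / (exp(z) + 1)
  } else 0
  out$phi <- if (fr$spec$family == "negative_binomial") theta[["phi"]] else NA_real_
  tf <- theta[grep("^log_tf_", names(theta))]
  out$tau_f <- stats::setNames(exp(as.numeric(tf)),
                               sub("^log_tf_", "", names(tf)))
  out
}

# prior precision (sparse blockdiag) and its log determinant
.prior_precision <- function(fr, theta) {
  pars <- .theta_decode(fr, theta)
  blocks <- list(); logdet <- 0
  if (fr$spec$spatial != "none") {
    kappa <- kappa_from_range(pars$rho)
    tau <- tau_from_sigma(pars$sigma, kappa)
    qs <- spatial_precision(kappa, tau, fr$fem)
    if (is.null(fr$chQs)) fr$chQs <- Matrix::Cholesky(qs, LDL = FALSE, perm = TRUE)
    else fr$chQs <- Matrix::update(fr$chQs, qs)
    ld_qs <- 2 * as.numeric(Matrix::determinant(fr$chQs, sqrt = TRUE)$modulus)
    T <- fr$T_field
    if (T == 1L) {
      blocks <- c(blocks, list(qs)); logdet <- logdet + ld_qs
    } else {
      qt <- ar1_precision(pars$a, T)
      blocks <- c(blocks, list(Matrix::kronecker(qt, qs)))
      logdet <- logdet + T * ld_qs - fr$n_vertices * (T - 1) * log(1 - pars$a^2)
    }
  }
  blocks <- c(blocks, list(Matrix::Matrix(fr$intercept_prec, 1, 1, sparse = TRUE)))
  logdet <- logdet + log(fr$intercept_prec)
  for (nm in names(fr$smooths)) {
    tf <- pars$tau_f[[nm]]
    sb <- fr$smooth_S[[nm]]
    blocks <- c(blocks, list(Matrix::Matrix(tf * sb$S +
      fr$smooth_ridge * diag(nrow(sb$S)), sparse = TRUE)))
    logdet <- logdet + sum(log(tf * sb$eig + fr$smooth_ridge))
  }
  q <- methods::as(Matrix::forceSymmetric(Matrix::bdiag(blocks)), "CsparseMatrix")
  list(Q = q, logdet = logdet, pars = pars)
}

# log prior of the hyperparameters on the transformed (optimization) scale,
# Jacobians included
.log_prior_theta <- function(fr, theta) {
  pars <- .theta_decode(fr, theta)
  lp <- 0
  if (fr$spec$spatial != "none") {
    lp <- lp + pc_prior_log_density(pars$rho, pars$sigma, fr$spec$prior) +
      theta[["log_rho"]] + theta[["log_sigma"]]
  }
  if (fr$spec$spatial == "ar1")
    lp <- lp + stats::dnorm(theta[["z_a"]], 0, 2, log = TRUE)
  if (fr$spec$family == "negative_binomial")
    lp <- lp + stats::dnorm(theta[["phi"]], 0, 5, log = TRUE)
  for (nm in names(fr$smooths)) {
    tf <- pars$tau_f[[nm]]
    lp <- lp + stats::dgamma(tf, shape = 1, rate = 0.01, log = TRUE) + log(tf)
  }
  as.numeric(lp)
}

.obs_params_from_theta <- function(fr, theta) {
  if (fr$spec$family == "negative_binomial") obs_params("negative_binomial",
                                                        phi = theta[["phi"]])
  else if (fr$spec$family == "poisson") obs_params("poisson")
  else obs_params("gaussian", sd = fr$spec$gaussian_sd)
}

.eta_to_mu <- function(fr, eta) if (fr$spec$family == "gaussian") eta else exp(pmin(eta, 38))

## ---- inner Gaussian approximation -------------------------------------------

# Newton iterations on the latent field for fixed hyperparameters.
.inner_laplace <- function(fr, prior, op, start = NULL, maxit = 50,
                           tol = 1e-8) {
  M <- fr$M; y <- fr$y; Qp <- prior$Q
  x <- start %||% fr$last_mode %||% numeric(fr$p)
  if (length(x) != fr$p) x <- numeric(fr$p)
  obj_of <- function(x) {
    eta <- as.numeric(M %*% x)
    mu <- .eta_to_mu(fr, eta)
    ll <- observation_loglik(y, mu, op)
    list(eta = eta, ll = ll,
         obj = ll$value - 0.5 * as.numeric(Matrix::crossprod(x, Qp %*% x)))
  }
  st <- obj_of(x)
  if (!is.finite(st$obj)) { x <- numeric(fr$p); st <- obj_of(x) }
  converged <- FALSE; gnorm <- NA_real_
  for (it in seq_len(maxit)) {
    grad <- as.numeric(Matrix::crossprod(M, st$ll$grad)) - as.numeric(Qp %*% x)
    gnorm <- sqrt(sum(grad^2))
    # gradient scale frozen at the first (cold-start) call so warm-started
    # refits share the same convergence yardstick
    if (is.null(fr$gscale)) fr$gscale <- max(1, gnorm)
    gscale <- fr$gscale
    if (gnorm < tol * gscale) { converged <- TRUE; break }
    W <- pmax(st$ll$neg_hess_diag, 1e-12)
    Msc <- M; Msc@x <- Msc@x * W[Msc@i + 1L]
    H <- Matrix::forceSymmetric(Qp + Matrix::crossprod(M, Msc))
    ch <- tryCatch({
      if (is.null(fr$chH)) fr$chH <- Matrix::Cholesky(H, LDL = FALSE, perm = TRUE, super = TRUE)
      else fr$chH <- Matrix::update(fr$chH, H)
      fr$chH
    }, error = function(e) NULL)
    if (is.null(ch)) {
      H2 <- H + Matrix::Diagonal(fr$p, 1e-6 * max(abs(Matrix::diag(H))))
      ch <- tryCatch({ fr$chH <- Matrix::Cholesky(Matrix::forceSymmetric(H2),
                                                  LDL = FALSE, perm = TRUE); fr$chH },
                     error = function(e) stop("indefinite Hessian in inner Newton"))
    }
    step <- as.numeric(Matrix::solve(ch, grad))
    tstep <- 1
    stalled <- FALSE
    repeat {
      cand <- obj_of(x + tstep * step)
      if (is.finite(cand$obj) && cand$obj >= st$obj - 1e-12) break
      tstep <- tstep / 2
      if (tstep < 1e-8) {
        # roundoff plateau: accept the current point if essentially converged
        if (gnorm < 1e-5 * gscale) { stalled <- TRUE; break }
        stop("inner Newton step-halving failed to improve; last |grad| = ",
             format(gnorm))
      }
    }
    if (stalled) { converged <- TRUE; break }
    x <- x + tstep * step
    st <- cand
  }
  # final Hessian/factorization at the mode
  W <- pmax(st$ll$neg_hess_diag, 1e-12)
  Msc <- M; Msc@x <- Msc@x * W[Msc@i + 1L]
  H <- Matrix::forceSymmetric(Qp + Matrix::crossprod(M, Msc))
  if (is.null(fr$chH)) fr$chH <- Matrix::Cholesky(H, LDL = FALSE, perm = TRUE, super = TRUE)
  else fr$chH <- Matrix::update(fr$chH, H)
  logdetH <- 2 * as.numeric(Matrix::determinant(fr$chH, sqrt = TRUE)$modulus)
  fr$last_mode <- x
  list(mode = x, eta = st$eta, loglik = st$ll$value,
       quad = as.numeric(Matrix::crossprod(x, prior$Q %*% x)),
       obj = st$obj, logdetH = logdetH, chol = fr$chH, H = H,
       converged = converged, iterations = it, grad_norm = gnorm)
}

#' Gaussian (Laplace) approximation of the latent field at fixed
#' hyperparameters
#'
#' Runs Newton iterations on the joint latent vector (field weights,
#' intercept, smooth contrasts) for the given hyperparameters and returns the
#' mode together with the Gaussian approximation whose precision is
#' \code{Q_prior + t(M) W M} (W = negative log-likelihood Hessian in eta).
#'
#' @param spec a \code{gmrfish_model_spec}.
#' @param data a survey dataset.
#' @param theta named hyperparameter vector on the transformed scale
#'   (\code{log_rho}, \code{log_sigma}, \code{z_a}, \code{phi},
#'   \code{log_tf_*}); defaults are filled for missing entries.
#' @param mesh optional prebuilt \code{gmrfish_mesh}.
#' @param mesh_args list passed to \code{\link{build_mesh}} when no mesh is
#'   given.
#' @return list with \code{mode}, \code{eta} (at observations),
#'   \code{loglik}, \code{logdetH}, \code{log_evidence} (Laplace
#'   approximation to log p(y | theta)), convergence report, and the frame
#'   internals.
#' @export
gaussian_approximation <- function(spec, data, theta = NULL, mesh = NULL,
                                   mesh_args = list()) {
  fr <- .build_frame(spec, data, mesh, mesh_args)
  th <- .theta_init(fr)
  if (!is.null(theta)) th[names(theta)] <- unlist(theta)
  prior <- .prior_precision(fr, th)
  op <- .obs_params_from_theta(fr, th)
  inner <- .inner_laplace(fr, prior, op)
  inner$log_evidence <- inner$loglik - 0.5 * inner$quad +
    0.5 * prior$logdet - 0.5 * inner$logdetH
  inner$theta <- th
  inner$frame <- fr
  inner
}

## ---- outer optimization ------------------------------------------------------

#' Fit the spatio-temporal abundance model
#'
#' Maximizes the Laplace approximation to the hyperparameter posterior
#' (conditional evidence plus PC-prior and auxiliary prior densities) with
#' Nelder-Mead on the transformed hyperparameters, then evaluates a small
#' axis grid around the mode; latent marginals are the weight-mixed grid
#' summaries. This is an empirical-Bayes-mode simplification of full nested
#' integration.
#'
#' @param spec a \code{gmrfish_model_spec}.
#' @param data survey dataset (see \code{\link{survey_dataset}}).
#' @param mesh optional \code{gmrfish_mesh}; built from the data otherwise.
#' @param mesh_args mesh construction arguments (\code{max_edge},
#'   \code{cutoff}) when no mesh is given.
#' @param control list: \code{maxit} (Nelder-Mead iterations, default 150),
#'   \code{reltol} (default 1e-6), \code{grid} (evaluate the axis grid,
#'   default TRUE), \code{grid_delta} (grid step in posterior-SD units,
#'   default 1), \code{compute_sd} (latent/fitted SDs via the factored
#'   precision, default TRUE), \code{theta_init} (named start values).
#' @return object of class \code{gmrfish_fit}.
#' @export
fit_abundance_model <- function(spec, data, mesh = NULL, mesh_args = list(),
                                control = list()) {
  ctl <- utils::modifyList(list(maxit = 150, reltol = 1e-6, grid = TRUE,
                                grid_delta = 1, compute_sd = TRUE,
                                theta_init = NULL), control)
  fr <- .build_frame(spec, data, mesh, mesh_args)
  th0 <- .theta_init(fr)
  if (!is.null(ctl$theta_init)) th0[names(ctl$theta_init)] <- unlist(ctl$theta_init)
  nm <- names(th0)

  lp_of <- function(thv) {
    th <- stats::setNames(thv, nm)
    prior <- tryCatch(.prior_precision(fr, th), error = function(e) NULL)
    if (is.null(prior)) return(-1e10)
    inner <- tryCatch(.inner_laplace(fr, prior, .obs_params_from_theta(fr, th)),
                      error = function(e) NULL)
    if (is.null(inner)) return(-1e10)
    inner$loglik - 0.5 * inner$quad + 0.5 * prior$logdet -
      0.5 * inner$logdetH + .log_prior_theta(fr, th)
  }

  if (length(nm) && ctl$maxit > 0) {
    if (length(nm) == 1L) {
      opt <- stats::optimize(function(v) -lp_of(v),
                             interval = c(th0 - 8, th0 + 8), tol = 1e-5)
      theta_hat <- stats::setNames(opt$minimum, nm)
      lp_hat <- -opt$objective
    } else {
      opt <- stats::optim(as.numeric(th0), function(v) -lp_of(v),
                          method = "Nelder-Mead",
                          control = list(maxit = ctl$maxit, reltol = ctl$reltol))
      theta_hat <- stats::setNames(opt$par, nm)
      lp_hat <- -opt$value
    }
  } else if (length(nm)) {       # maxit = 0: hyperparameters held at theta_init
    theta_hat <- th0
    lp_hat <- lp_of(as.numeric(th0))
  } else {
    theta_hat <- th0
    lp_hat <- lp_of(numeric(0))
  }

  # grid around the mode (axis design scaled by the local curvature)
  grid_theta <- matrix(theta_hat, 1, length(nm),
                       dimnames = list(NULL, nm))
  grid_lp <- lp_hat
  if (ctl$grid && length(nm)) {
    hstep <- 0.3
    scales <- vapply(seq_along(nm), function(i) {
      e <- numeric(length(nm)); e[i] <- hstep
      h <- (-lp_of(theta_hat + e) + 2 * lp_hat - lp_of(theta_hat - e)) / hstep^2
      1 / sqrt(max(h, 0.25))
    }, numeric(1))
    scales <- pmin(scales, 2)
    for (i in seq_along(nm)) for (sgn in c(-1, 1)) {
      thp <- theta_hat
      thp[i] <- thp[i] + sgn * ctl$grid_delta * scales[i]
      grid_theta <- rbind(grid_theta, thp)
      grid_lp <- c(grid_lp, lp_of(thp))
    }
  }
  w <- exp(grid_lp - max(grid_lp)); w <- w / sum(w)

  # latent summaries per grid point (means), SDs at the mode
  K <- nrow(grid_theta)
  x_grid <- matrix(0, fr$p, K)
  eta_grid <- matrix(0, fr$n_obs, K)
  inner_mode <- NULL
  for (k in seq_len(K)) {
    th <- stats::setNames(grid_theta[k, ], nm)
    prior <- .prior_precision(fr, th)
    inner <- .inner_laplace(fr, prior, .obs_params_from_theta(fr, th))
    x_grid[, k] <- inner$mode
    eta_grid[, k] <- inner$eta
    if (k == 1) inner_mode <- inner
  }
  # re-establish the factorization at the mode for downstream use
  prior_mode <- .prior_precision(fr, theta_hat)
  inner_mode <- .inner_laplace(fr, prior_mode,
                               .obs_params_from_theta(fr, theta_hat))
  x_mean <- as.numeric(x_grid %*% w)
  eta_mean <- as.numeric(eta_grid %*% w)

  latent_sd <- rep(NA_real_, fr$p)
  eta_sd <- rep(NA_real_, fr$n_obs)
  eta_within_sd <- rep(NA_real_, fr$n_obs)
  if (ctl$compute_sd) {
    Vd <- as.matrix(Matrix::solve(inner_mode$chol,
                                  diag(1, fr$p)))
    v_mode <- pmax(diag(Vd), 0)
    # mixture variance: within-point variance (mode) + between-point spread
    spread <- as.numeric((x_grid - x_mean)^2 %*% w)
    latent_sd <- sqrt(v_mode + spread)
    S <- as.matrix(Matrix::solve(inner_mode$chol, Matrix::t(fr$M)))
    v_eta <- pmax(Matrix::colSums(Matrix::t(fr$M) * S), 0)
    eta_spread <- as.numeric((eta_grid - eta_mean)^2 %*% w)
    eta_within_sd <- sqrt(v_eta)
    eta_sd <- sqrt(v_eta + eta_spread)
  }

  pars <- .theta_decode(fr, theta_hat)
  fitted_mu <- if (fr$spec$family == "gaussian") eta_mean else {
    if (ctl$compute_sd) exp(eta_mean + 0.5 * eta_sd^2) else exp(eta_mean)
  }
  boundary_warning <- fr$spec$spatial == "ar1" && abs(pars$a) > 0.995

  field_mean <- if (fr$n_vertices)
    matrix(x_mean[fr$idx_field], fr$n_vertices, fr$T_field) else NULL
  field_sd <- if (fr$n_vertices && ctl$compute_sd)
    matrix(latent_sd[fr$idx_field], fr$n_vertices, fr$T_field) else NULL
  smooth_coefs <- lapply(names(fr$smooths), function(nmm)
    as.numeric(fr$smooths[[nmm]]$Z %*% x_mean[fr$idx_gamma[[nmm]]]))
  names(smooth_coefs) <- names(fr$smooths)

  structure(list(
    spec = spec, mesh = fr$mesh, years = fr$years,
    hyper_mode = c(list(theta = theta_hat), pars),
    hyper_grid = data.frame(grid_theta, lp = grid_lp, weight = w),
    log_marginal = lp_hat,
    latent_mean = x_mean, latent_sd = latent_sd,
    field_mean = field_mean, field_sd = field_sd,
    intercept = x_mean[fr$idx_intercept],
    smooth_coefs = smooth_coefs,
    fitted_eta_mean = eta_mean, fitted_eta_sd = eta_sd,
    fitted_eta_within_sd = eta_within_sd,
    fitted_mu = fitted_mu,
    eta_grid = eta_grid, x_grid = x_grid, weights = w,
    y = fr$y, n_obs = fr$n_obs,
    converged = inner_mode$converged,
    newton_report = list(iterations = inner_mode$iterations,
                         grad_norm = inner_mode$grad_norm),
    boundary_warning = boundary_warning,
    frame = fr), class = "gmrfish_fit")
}

#' @export
print.gmrfish_fit <- function(x, ...) {
  hm <- x$hyper_mode
  cat("gmrfish fit:", x$spec$spatial, "spatial structure,",
      x$spec$family, "family\n")
  if (!is.null(hm$rho))
    cat(sprintf("  rho = %.4g  sigma = %.4g", hm$rho, hm$sigma))
  if (x$spec$spatial == "ar1") cat(sprintf("  a = %.4g", hm$a))
  if (is.finite(hm$phi %||% NA)) cat(sprintf("  phi = %.4g", hm$phi))
  cat(sprintf("\n  n_obs = %d, log posterior at mode = %.3f\n",
              x$n_obs, x$log_marginal))
  if (isTRUE(x$boundary_warning))
    cat("  warning: persistence estimate at the stationarity boundary\n")
  invisible(x)
}

#' Posterior surface prediction on a grid
#'
#' Posterior mean and SD of the linear predictor (log predicted count scale)
#' at arbitrary locations for a given year. Grid points outside the mesh are
#' flagged and returned as NA rather than raising an error.
#'
#' @param fit a \code{gmrfish_fit}.
#' @param grid two-column coordinate matrix.
#' @param year survey year (must be one of the fitted years unless the
#'   spatial structure is "constant").
#' @param covariate_values data frame of covariate values at the grid points
#'   (required when the model has covariate smooths).
#' @return data frame with lon, lat, mean, sd, outside.
#' @export
predict_surface <- function(fit, grid, year = NULL,
                            covariate_values = NULL) {
  fr <- fit$frame
  grid <- as.matrix(grid)
  A <- projection_matrix(fit$mesh, grid, allow_outside = TRUE)
  outside <- attr(A, "outside")
  tix <- 1L
  if (fr$T_field > 1L) {
    if (is.null(year)) stop("year is required for time-varying fields")
    tix <- match(year, fit$years)
    if (is.na(tix)) stop("year ", year, " was not in the fitted data")
  }
  m <- nrow(grid)
  blocks <- list()
  if (fr$n_vertices) {
    if (fr$T_field > 1L) {
      trip <- Matrix::summary(methods::as(A, "TsparseMatrix"))
      Afull <- Matrix::sparseMatrix(i = trip$i, j = trip$j + (tix - 1L) * fr$n_vertices,
                                    x = trip$x,
                                    dims = c(m, fr$n_vertices * fr$T_field))
    } else Afull <- A
    blocks <- c(blocks, list(Afull))
  }
  blocks <- c(blocks, list(Matrix::Matrix(1, m, 1, sparse = TRUE)))
  for (nm in names(fr$smooths)) {
    if (is.null(covariate_values) || is.null(covariate_values[[nm]]))
      stop("covariate values for '", nm, "' are required for prediction")
    sm <- fr$smooths[[nm]]
    blocks <- c(blocks, list(.interp_design(
      pmin(pmax(covariate_values[[nm]], min(sm$knots)), max(sm$knots)),
      sm$knots) %*% sm$Z))
  }
  Mp <- methods::as(do.call(cbind, blocks), "CsparseMatrix")
  mean <- as.numeric(Mp %*% fit$latent_mean)
  sd <- rep(NA_real_, m)
  if (!is.null(fit$frame$chH)) {
    S <- as.matrix(Matrix::solve(fit$frame$chH, Matrix::t(Mp)))
    sd <- sqrt(pmax(Matrix::colSums(Matrix::t(Mp) * S), 0))
  }
  mean[outside] <- NA_real_; sd[outside] <- NA_real_
  out <- data.frame(lon = grid[, 1], lat = grid[, 2], mean = mean, sd = sd,
                    outside = seq_len(m) %in% outside)
  out
}
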