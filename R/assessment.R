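# Model comparison: DIC (expected deviance + effective parameters),
# cross-validated conditional predictive ordinates (CPO) and their summed
# log (LPML), and the root mean squared estimation error (RMSEE).
# Expectations over the latent Gaussian are taken by Gauss-Hermite
# quadrature, which is exact for the gaussian harness family.

# Gauss-Hermite nodes/weights by Golub-Welsch (physicists' convention:
# integrates f against exp(-x^2))
.gauss_hermite <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b; J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# E[ f(eta) ] for eta ~ N(m, s^2), vectorised over observations; f returns a
# per-observation vector given an eta vector
.gh_expect <- function(m, s, f, n_quad = 9) {
  gh <- .gauss_hermite(n_quad)
  out <- numeric(length(m))
  for (q in seq_len(n_quad))
    out <- out + gh$weights[q] * f(m + sqrt(2) * s * gh$nodes[q])
  out / sqrt(pi)
}

#' Deviance information criterion of a fit
#'
#' The mean deviance E[D] is averaged over the hyperparameter grid (weights)
#' and over the latent Gaussian marginals (Gauss-Hermite quadrature in eta);
#' p_D is the mean deviance minus the deviance at the posterior mean, and
#' DIC = E[D] + p_D. Lower is better. A negative p_D (possible under the
#' Laplace approximation) triggers a warning.
#'
#' @param fit a \code{gmrfish_fit} fitted with \code{compute_sd = TRUE}.
#' @param n_quad Gauss-Hermite nodes (default 9).
#' @return list with \code{dic}, \code{p_d}, \code{mean_deviance}.
#' @export
dic <- function(fit, n_quad = 9) {
  if (is.null(fit$eta_grid) || is.null(fit$weights))
    stop("fit has no hyperparameter grid")
  if (any(!is.finite(fit$fitted_eta_within_sd)))
    stop("fit has no latent SDs; refit with compute_sd = TRUE")
  fr <- fit$frame
  y <- fit$y
  K <- length(fit$weights)
  thnames <- setdiff(names(fit$hyper_grid), c("lp", "weight"))
  mean_dev <- 0
  for (k in seq_len(K)) {
    th <- stats::setNames(as.numeric(fit$hyper_grid[k, thnames]), thnames)
    op <- .obs_params_from_theta(fr, th)
    dev_k <- .gh_expect(fit$eta_grid[, k], fit$fitted_eta_within_sd,
                        function(eta) -2 * .obs_ll_vec(y, .eta_to_mu(fr, eta), op),
                        n_quad)
    mean_dev <- mean_dev + fit$weights[k] * sum(dev_k)
  }
  op_mode <- .obs_params_from_theta(fr, fit$hyper_mode$theta)
  dev_at_mean <- -2 * sum(.obs_ll_vec(y, .eta_to_mu(fr, fit$fitted_eta_mean),
                                      op_mode))
  p_d <- mean_dev - dev_at_mean
  if (p_d < 0) warning("negative effective number of parameters (p_D = ",
                       format(p_d), ")")
  list(dic = mean_dev + p_d, p_d = p_d, mean_deviance = mean_dev)
}

#' Cross-validated conditional predictive ordinates and LPML
#'
#' Observations are partitioned into W equal-sized random folds (seeded).
#' For each fold the model is refit without that fold (hyperparameter mode
#' and latent field both refit on the retained data), and each held-out
#' observation's predictive density is evaluated under its own fold's fit by
#' integrating the observation density over the Gaussian marginal of its
#' linear predictor. LPML is the sum of log CPO; larger is better. With
#' W = n (singleton folds) this is exact leave-one-out.
#'
#' @param spec a \code{gmrfish_model_spec}.
#' @param data survey dataset.
#' @param W number of folds (default: fold size 5\% of the data, i.e. W = 20,
#'   capped at n).
#' @param seed integer seed for the fold assignment.
#' @param mesh optional mesh shared by all fold fits (built from the full
#'   data otherwise, so held-out locations stay in-domain).
#' @param mesh_args mesh construction arguments.
#' @param control fit control passed to \code{\link{fit_abundance_model}}
#'   (defaults tuned for refits: no grid).
#' @param n_quad Gauss-Hermite nodes for the predictive integral (the
#'   gaussian family uses the exact convolution instead).
#' @param folds optional explicit fold assignment (integer vector in 1..W),
#'   overriding the seeded random partition.
#' @return list with \code{cpo} (per observation), \code{lpml}, \code{W},
#'   \code{folds}, and \code{n_floored} (predictive densities floored at
#'   1e-300).
#' @export
cpo_lpml <- function(spec, data, W = NULL, seed = 1, mesh = NULL,
                     mesh_args = list(), control = list(), n_quad = 15,
                     folds = NULL) {
  data <- survey_dataset(as.data.frame(data))
  n <- nrow(data)
  if (!is.null(folds)) W <- max(folds)
  if (is.null(W)) W <- min(20L, n)
  W <- as.integer(W)
  if (W < 2) stop("W must be >= 2")
  if (W > n) stop("more folds than observations")
  if (is.null(mesh) && spec$spatial != "none") {
    coords <- cbind(data$lon, data$lat)
    diam <- sqrt(sum((apply(coords, 2, max) - apply(coords, 2, min))^2))
    mesh <- do.call(build_mesh, c(list(locations = coords,
      max_edge = mesh_args$max_edge %||% (diam / 8),
      cutoff = mesh_args$cutoff %||% (diam / 40)),
      mesh_args[setdiff(names(mesh_args), c("max_edge", "cutoff"))]))
  }
  ctl <- utils::modifyList(list(grid = FALSE, compute_sd = FALSE), control)
  if (is.null(folds)) {
    set.seed(seed)
    folds <- sample(rep(seq_len(W), length.out = n))
  }
  if (any(tabulate(folds, W) == 0)) stop("every fold must be nonempty")
  cpo <- rep(NA_real_, n)
  n_floored <- 0L
  for (w in seq_len(W)) {
    ho <- which(folds == w)
    train <- data[-ho, , drop = FALSE]
    fit <- fit_abundance_model(spec, train, mesh = mesh, control = ctl)
    fr <- fit$frame
    # linear-predictor marginals at the held-out records, in the train basis
    m <- length(ho)
    blocks <- list()
    if (fr$n_vertices) {
      A <- projection_matrix(mesh, cbind(data$lon[ho], data$lat[ho]),
                             allow_outside = TRUE)
      if (fr$T_field > 1L) {
        tix <- match(data$year[ho], fit$years)
        if (any(is.na(tix)))
          stop("a fold removed an entire year; use fewer folds")
        trip <- Matrix::summary(methods::as(A, "TsparseMatrix"))
        A <- Matrix::sparseMatrix(i = trip$i,
          j = trip$j + (tix[trip$i] - 1L) * fr$n_vertices,
          x = trip$x, dims = c(m, fr$n_vertices * fr$T_field))
      }
      blocks <- c(blocks, list(A))
    }
    blocks <- c(blocks, list(Matrix::Matrix(1, m, 1, sparse = TRUE)))
    for (nm in names(fr$smooths)) {
      sm <- fr$smooths[[nm]]
      vals <- pmin(pmax(data[[nm]][ho], min(sm$knots)), max(sm$knots))
      blocks <- c(blocks, list(.interp_design(vals, sm$knots) %*% sm$Z))
    }
    Mho <- methods::as(do.call(cbind, blocks), "CsparseMatrix")
    mean_ho <- as.numeric(Mho %*% fit$latent_mean)
    S <- as.matrix(Matrix::solve(fr$chH, Matrix::t(Mho)))
    var_ho <- pmax(Matrix::colSums(Matrix::t(Mho) * S), 0)
    op <- .obs_params_from_theta(fr, fit$hyper_mode$theta)
    yho <- data$count[ho]
    dens <- if (fr$spec$family == "gaussian")
      stats::dnorm(yho, mean_ho, sqrt(op$sd^2 + var_ho))   # exact convolution
    else .gh_expect(mean_ho, sqrt(var_ho),
                    function(eta) exp(.obs_ll_vec(yho, .eta_to_mu(fr, eta), op)),
                    n_quad)
    fl <- dens < 1e-300
    n_floored <- n_floored + sum(fl)
    dens[fl] <- 1e-300
    cpo[ho] <- dens
  }
  if (n_floored > 0)
    warning(n_floored, " predictive densities floored at 1e-300")
  list(cpo = cpo, lpml = sum(log(cpo)), W = W, folds = folds,
       n_floored = n_floored)
}

#' Root mean squared estimation error
#'
#' \eqn{\sqrt{\frac{1}{n} \sum (y - E[Y])^2}} between observed counts and
#' fitted means; smaller is better. By default the response-scale mean uses
#' the lognormal plug-in \eqn{\exp(\hat\eta + \frac{1}{2} sd^2)}; set
#' \code{type = "plain"} for \eqn{\exp(\hat\eta)}.
#'
#' @param fit a \code{gmrfish_fit}, or NULL if \code{fitted} and
#'   \code{counts} are given directly.
#' @param type "plugin" (default) or "plain".
#' @param fitted,counts optional explicit vectors (bypass the fit object).
#' @export
rmsee <- function(fit = NULL, type = c("plugin", "plain"), fitted = NULL,
                  counts = NULL) {
  type <- match.arg(type)
  if (is.null(fitted)) {
    if (is.null(fit)) stop("provide a fit or fitted/counts vectors")
    fitted <- if (type == "plain" && fit$spec$family != "gaussian")
      exp(fit$fitted_eta_mean) else fit$fitted_mu
    counts <- fit$y
  }
  if (length(fitted) != length(counts)) stop("length mismatch")
  sqrt(mean((counts - fitted)^2))
}

#' Candidate-model comparison table
#'
#' One row per fitted candidate with DIC (lower better), LPML (higher
#' better, if supplied) and RMSEE (lower better); the best model by each
#' criterion is flagged, ties are flagged, and disagreement between criteria
#' is recorded in the \code{disagreement} attribute.
#'
#' @param fits list of \code{gmrfish_fit} objects on identical data.
#' @param labels candidate names.
#' @param lpml optional numeric vector of LPML values (one per fit).
#' @return data frame of class \code{gmrfish_comparison}.
#' @export
model_comparison_table <- function(fits, labels = NULL, lpml = NULL) {
  if (length(fits) < 2) stop("need at least 2 fits to compare")
  y0 <- fits[[1]]$y
  same <- vapply(fits, function(f) length(f$y) == length(y0) &&
                   all(f$y == y0), logical(1))
  if (!all(same)) stop("fits are not comparable: different datasets")
  if (is.null(labels))
    labels <- vapply(fits, function(f)
      paste0(f$spec$spatial, if (length(f$spec$covariates))
        paste0("+", paste(f$spec$covariates, collapse = "+")) else ""),
      character(1))
  dics <- vapply(fits, function(f) dic(f)$dic, numeric(1))
  rmsees <- vapply(fits, rmsee, numeric(1))
  if (is.null(lpml)) lpml <- rep(NA_real_, length(fits))
  tab <- data.frame(model = labels, DIC = dics, LPML = lpml, RMSEE = rmsees)
  tab$best_dic <- dics == min(dics)
  tab$best_lpml <- if (all(is.na(lpml))) NA else lpml == max(lpml, na.rm = TRUE)
  tab$best_rmsee <- rmsees == min(rmsees)
  attr(tab, "tie") <- sum(tab$best_dic) > 1 || sum(tab$best_rmsee) > 1
  picks <- c(which.min(dics), if (!all(is.na(lpml))) which.max(lpml),
             which.min(rmsees))
  attr(tab, "disagreement") <- length(unique(picks)) > 1
  attr(tab, "directions") <- c(DIC = "lower", LPML = "higher", RMSEE = "lower")
  class(tab) <- c("gmrfish_comparison", "data.frame")
  tab
}
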