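# Observation model: survey data container, covariate smooths, linear
# predictor assembly and count likelihoods. The linear predictor is
#   eta(s,t) = beta0 + xi(s,t) + sum_j f_j(c_j(s,t))
# with a log link (mu = exp(eta)) for the count families. An explicit
# intercept is carried because the latent field has mean zero.

#' Validate and type a survey dataset
#'
#' Required columns: \code{lon}, \code{lat}, \code{year}, \code{count}.
#' Optional: \code{subzone} (character label), \code{distance_towed} (km),
#' plus any number of numeric covariate columns (e.g. temperature, depth,
#' relative exploitation), which are preserved and listed in the
#' \code{covariates} attribute.
#'
#' @param df data frame of trawl records.
#' @return the data frame with class \code{gmrfish_survey} and attribute
#'   \code{covariates}.
#' @export
survey_dataset <- function(df) {
  req <- c("lon", "lat", "year", "count")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing required survey columns: ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(df$lon)) || any(!is.finite(df$lat)))
    stop("coordinates must be finite")
  if (any(df$count < 0)) stop("counts must be non-negative")
  if (any(df$count != round(df$count))) stop("counts must be integers")
  df$year <- as.integer(df$year)
  covs <- setdiff(names(df)[vapply(df, is.numeric, logical(1))],
                  c(req, "subzone"))
  attr(df, "covariates") <- covs
  class(df) <- unique(c("gmrfish_survey", class(df)))
  df
}

#' Covariate subsets free of strong pairwise collinearity
#'
#' Computes pairwise Pearson correlations on complete observations and
#' returns the maximal subsets of covariates in which every pair has
#' |r| below \code{threshold} (strongly collinear covariates, e.g. nitrate
#' and silicate, never co-occur in a subset).
#'
#' @param data a \code{gmrfish_survey} (or data frame with the covariates).
#' @param covariates character vector; default: all covariates in the data.
#' @param threshold correlation threshold (default 0.9).
#' @return list of character vectors (maximal admissible subsets), with the
#'   correlation matrix as attribute \code{correlations}.
#' @export
collinearity_screen <- function(data, covariates = NULL, threshold = 0.9) {
  if (is.null(covariates)) covariates <- attr(data, "covariates")
  if (length(covariates) < 2) stop("need at least 2 covariates to screen")
  X <- as.data.frame(data)[covariates]
  cc <- stats::complete.cases(X)
  if (sum(cc) < 3) stop("need at least 3 complete observations")
  X <- X[cc, , drop = FALSE]
  sds <- vapply(X, stats::sd, numeric(1))
  if (any(sds == 0)) stop("degenerate covariate (constant): ",
                          paste(covariates[sds == 0], collapse = ", "))
  R <- stats::cor(X)
  k <- length(covariates)
  # compatibility graph: edge when the pair may co-occur
  ok <- abs(R) < threshold
  diag(ok) <- TRUE
  subsets <- .maximal_cliques(ok)
  out <- lapply(subsets, function(s) covariates[sort(s)])
  attr(out, "correlations") <- R
  out
}

# Bron-Kerbosch maximal cliques of a small undirected graph (logical adjacency)
.maximal_cliques <- function(adj) {
  n <- nrow(adj)
  out <- list()
  bk <- function(r, p, x) {
    if (!length(p) && !length(x)) { out[[length(out) + 1L]] <<- r; return() }
    for (v in p) {
      nb <- which(adj[v, ] & seq_len(n) != v)
      bk(c(r, v), intersect(p, nb), intersect(x, nb))
      p <- setdiff(p, v)
      x <- c(x, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))
  out
}

#' Piecewise-linear covariate smooth with a random-walk(2) penalty
#'
#' Knots at equal quantiles of the observed values; the design matrix maps
#' each observation to a linear interpolation between its two bracketing
#' knots. The penalty is the squared second difference of the knot
#' coefficients, whose null space is {constant, linear}; a sum-to-zero
#' constraint (via an orthogonal contrast basis) keeps the smooth
#' identifiable next to the intercept.
#'
#' @param values numeric vector of covariate values.
#' @param n_knots number of knots (>= 4; default 25, reduced to the number
#'   of distinct values if necessary).
#' @param name covariate name.
#' @return object of class \code{gmrfish_smooth}: knots, sparse design
#'   \code{design}, penalty matrix \code{penalty} (k x k), contrast basis
#'   \code{Z} (k x (k-1)).
#' @export
build_covariate_smooth <- function(values, n_knots = 25, name = "covariate") {
  if (n_knots < 4) stop("configuration error: n_knots must be >= 4")
  if (any(!is.finite(values)))
    stop("missing covariate value in '", name, "': no silent imputation")
  ux <- sort(unique(values))
  if (length(ux) < n_knots) n_knots <- length(ux)
  if (n_knots < 4) stop("need at least 4 distinct covariate values")
  knots <- unique(stats::quantile(values, probs = seq(0, 1, length.out = n_knots),
                                  type = 7, names = FALSE))
  k <- length(knots)
  if (k < 4) stop("could not place 4 distinct equal-quantile knots")
  design <- .interp_design(values, knots)
  # spacing-aware second differences: null space is exactly
  # {constant, linear in the covariate} for unequal quantile knots
  h <- diff(knots)
  D <- matrix(0, k - 2, k)
  for (j in seq_len(k - 2))
    D[j, j:(j + 2)] <- c(1 / h[j], -(1 / h[j] + 1 / h[j + 1]), 1 / h[j + 1])
  penalty <- crossprod(D)
  Z <- qr.Q(qr(matrix(1, k, 1)), complete = TRUE)[, -1, drop = FALSE]
  structure(list(name = name, knots = knots, design = design,
                 penalty = penalty, Z = Z, k = k),
            class = "gmrfish_smooth")
}

# sparse linear-interpolation design of x onto ordered knots (clamped ends)
.interp_design <- function(x, knots) {
  k <- length(knots)
  xi <- pmin(pmax(x, knots[1]), knots[k])
  j <- findInterval(xi, knots, rightmost.closed = TRUE)
  j <- pmin(j, k - 1L)
  w <- (xi - knots[j]) / (knots[j + 1L] - knots[j])
  Matrix::sparseMatrix(i = rep(seq_along(x), 2L), j = c(j, j + 1L),
                       x = c(1 - w, w), dims = c(length(x), k))
}

#' Evaluate a smooth's penalty quadratic form
#' @param smooth a \code{gmrfish_smooth}.
#' @param f coefficient vector at the knots.
#' @export
smooth_penalty_quadform <- function(smooth, f) {
  as.numeric(t(f) %*% smooth$penalty %*% f)
}

#' Evaluate a fitted smooth at new covariate values
#' @param smooth a \code{gmrfish_smooth}.
#' @param coef knot coefficients (length k).
#' @param newvalues covariate values at which to evaluate.
#' @export
smooth_effect <- function(smooth, coef, newvalues) {
  if (any(!is.finite(newvalues)))
    stop("missing covariate value in '", smooth$name, "'")
  as.numeric(.interp_design(newvalues, smooth$knots) %*% coef)
}

#' Assemble the linear predictor
#'
#' \eqn{\eta = \beta_0 + \xi_{obs} + \sum_j f_j(c_j)}; under the log link
#' \eqn{\mu = \exp(\eta)}.
#'
#' @param field_at_obs latent field values projected to the observations
#'   (zero-length or NULL for models without a field).
#' @param smooth_values list of numeric vectors, one per covariate smooth
#'   (each already evaluated at the observations).
#' @param intercept scalar intercept.
#' @return list with \code{eta} and \code{mu}.
#' @export
assemble_linear_predictor <- function(field_at_obs = NULL,
                                      smooth_values = list(),
                                      intercept = 0) {
  lens <- c(if (length(field_at_obs)) length(field_at_obs),
            vapply(smooth_values, length, integer(1)))
  if (length(unique(lens)) > 1) stop("non-conformable component lengths")
  n <- if (length(lens)) lens[1] else 1L
  eta <- rep(intercept, n)
  if (length(field_at_obs)) eta <- eta + field_at_obs
  for (s in smooth_values) {
    if (any(!is.finite(s))) stop("missing covariate value: no silent imputation")
    eta <- eta + s
  }
  list(eta = eta, mu = exp(eta))
}

#' Observation family parameters
#'
#' @param family one of "poisson", "negative_binomial", "gaussian" (the
#'   gaussian identity-link family is a test/diagnostic harness).
#' @param phi log of the negative-binomial size parameter (phi = log n);
#'   the NB variance is \eqn{\mu (1 + \mu/n)}.
#' @param sd known standard deviation for the gaussian family.
#' @export
obs_params <- function(family = c("negative_binomial", "poisson", "gaussian"),
                       phi = 0, sd = 1) {
  family <- match.arg(family)
  size <- exp(phi)
  if (family == "negative_binomial" && size <= 0) stop("NB size must be > 0")
  structure(list(family = family, phi = phi, size = size, sd = sd),
            class = "gmrfish_obs_params")
}

#' Observation log-likelihood with derivatives in eta
#'
#' Returns the total log-likelihood, the gradient and the negative Hessian
#' diagonal with respect to the linear predictor eta (log link for count
#' families, identity for gaussian). The negative-binomial pmf is evaluated
#' from its lgamma form, with variance \eqn{\mu(1 + \mu/n)}.
#'
#' @param counts observed response vector (non-negative integers for count
#'   families).
#' @param mu mean vector (> 0 for count families); for the gaussian family
#'   this is the mean itself (eta).
#' @param params a \code{gmrfish_obs_params}.
#' @export
observation_loglik <- function(counts, mu, params) {
  y <- counts
  if (params$family != "gaussian") {
    if (any(y < 0) || any(y != round(y)))
      stop("validation error: counts must be non-negative integers")
    if (any(mu <= 0)) stop("mu must be positive")
  }
  switch(params$family,
    poisson = {
      value <- sum(y * log(mu) - mu - lgamma(y + 1))
      list(value = value, grad = y - mu, neg_hess_diag = mu)
    },
    negative_binomial = {
      n <- params$size
      value <- sum(lgamma(y + n) - lgamma(n) - lgamma(y + 1) +
                   n * (log(n) - log(n + mu)) + y * (log(mu) - log(n + mu)))
      grad <- n * (y - mu) / (n + mu)
      list(value = value, grad = grad,
           neg_hess_diag = n * mu * (n + y) / (n + mu)^2)
    },
    gaussian = {
      sd <- params$sd
      value <- sum(stats::dnorm(y, mu, sd, log = TRUE))
      list(value = value, grad = (y - mu) / sd^2,
           neg_hess_diag = rep(1 / sd^2, length(y)))
    })
}

# per-observation log density (no validation; internal fast path)
.obs_ll_vec <- function(y, mu, params) {
  switch(params$family,
    poisson = y * log(mu) - mu - lgamma(y + 1),
    negative_binomial = {
      n <- params$size
      lgamma(y + n) - lgamma(n) - lgamma(y + 1) +
        n * (log(n) - log(n + mu)) + y * (log(mu) - log(n + mu))
    },
    gaussian = stats::dnorm(y, mu, params$sd, log = TRUE))
}

#' Model specification
#'
#' @param spatial one of "none", "constant" (a single field shared by all
#'   years), "replicated" (independent fields each year) or "ar1"
#'   (fields coupled by the persistence parameter a).
#' @param covariates character vector of covariate names to smooth.
#' @param family observation family ("negative_binomial", "poisson",
#'   "gaussian").
#' @param prior a \code{gmrfish_pc_prior} for (rho, sigma).
#' @param n_knots knots per covariate smooth.
#' @param gaussian_sd known SD when family = "gaussian".
#' @param collinearity_threshold pairwise |r| at or above which covariates are
#'   rejected together.
#' @export
model_spec <- function(spatial = c("ar1", "constant", "replicated", "none"),
                       covariates = character(0),
                       family = c("negative_binomial", "poisson", "gaussian"),
                       prior = pc_prior(), n_knots = 25, gaussian_sd = 1,
                       collinearity_threshold = 0.9) {
  structure(list(spatial = match.arg(spatial), covariates = covariates,
                 family = match.arg(family), prior = prior,
                 n_knots = n_knots, gaussian_sd = gaussian_sd,
                 collinearity_threshold = collinearity_threshold),
            class = "gmrfish_model_spec")
}
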