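# Shared fixtures: all built in code at test time.

unit_square <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))

# a hand-built mesh object (no refinement machinery): unit square as two
# right triangles
square_mesh <- function() {
  structure(list(
    loc = cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
    tri = rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)),
    boundary = rep(TRUE, 4), n = 4L, data_index = 1:4,
    data_assign = 1:4, max_edge = 2, cutoff = 0.01, min_angle = 45),
    class = "gmrfish_mesh")
}

# single unit right triangle mesh
right_triangle_mesh <- function() {
  structure(list(
    loc = cbind(c(0, 1, 0), c(0, 0, 1)),
    tri = matrix(c(1L, 2L, 3L), 1, 3),
    boundary = rep(TRUE, 3), n = 3L, data_index = 1:3,
    data_assign = 1:3, max_edge = 2, cutoff = 0.01, min_angle = 45),
    class = "gmrfish_mesh")
}

# small meshed unit square with interior structure
fine_square_mesh <- function(spacing = 0.12, max_edge = 0.15, seed = 99) {
  set.seed(seed)
  g <- seq(0.02, 0.98, by = spacing)
  pts <- as.matrix(expand.grid(g, g))
  pts <- pts + matrix(stats::runif(length(pts), -spacing / 6, spacing / 6),
                      ncol = 2)
  build_mesh(pts, max_edge = max_edge, cutoff = spacing / 5)
}

# conjugate gaussian toy: y_i ~ N(mu, sd^2), mu ~ N(0, 100) (the model's
# weak intercept prior); returns data + closed-form LOO predictive densities
conjugate_gaussian_toy <- function(n = 10, sd = 1, seed = 3) {
  set.seed(seed)
  y <- round(pmax(stats::rnorm(n, 3, sd), 0))   # integer counts for the schema
  df <- data.frame(lon = stats::runif(n), lat = stats::runif(n),
                   year = 2000L, count = y)
  v0 <- 100  # matches the intercept prior N(0, 10^2)
  loo <- vapply(seq_len(n), function(i) {
    vi <- 1 / (1 / v0 + (n - 1) / sd^2)
    mi <- vi * sum(y[-i]) / sd^2
    stats::dnorm(y[i], mi, sqrt(sd^2 + vi))
  }, numeric(1))
  list(data = survey_dataset(df), loo = loo, y = y, sd = sd)
}

# small synthetic survey for fitting tests (unit square, no covariates)
small_survey <- function(seed = 1, n_years = 4, sets = 60, rho = 0.3,
                         sigma = 1.2, a = 0.5, phi = 1, intercept = 2) {
  sc <- scenario_config(domain = unit_square, n_years = n_years,
                        sets_per_year = sets, rho = rho, sigma = sigma,
                        a = a, phi = phi, intercept = intercept, seed = seed,
                        covariate_effects = list(), mesh_max_edge = 0.12)
  simulate_survey(sc)
}

fast_ctl <- list(maxit = 60, grid = FALSE, compute_sd = FALSE)

# near-equilateral lattice over the unit square (high FEM quality)
hex_lattice <- function(s) {
  ys <- seq(0, 1, by = s * sqrt(3) / 2)
  do.call(rbind, lapply(seq_along(ys), function(i) {
    xs <- seq(if (i %% 2) 0 else s / 2, 1, by = s)
    cbind(xs, ys[i])
  }))
}
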