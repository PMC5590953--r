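# Synthetic trawl surveys with the statistical structure the model assumes:
# a Matern GMRF latent log-density with AR(1) year-to-year persistence,
# smooth covariate effects, and negative-binomial counts, sampled by a
# stratified-random survey design over an irregular shelf-shaped domain.
# Collapse scenarios build the latent surface from deterministic bumps whose
# plateau height stays constant while their extent shrinks (hyperstability
# by construction).

# ray-casting point-in-polygon; poly is a closed or open ring (matrix)
.point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# distance from points to the polygon boundary (for boundary tie detection)
.dist_to_ring <- function(px, py, poly) {
  n <- nrow(poly)
  d2 <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    ax <- poly[j, 1]; ay <- poly[j, 2]
    bx <- poly[i, 1]; by <- poly[i, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    tt <- if (L2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
    d2 <- pmin(d2, (px - (ax + tt * vx))^2 + (py - (ay + tt * vy))^2)
    j <- i
  }
  sqrt(d2)
}

#' Default shelf-shaped survey domain (polygon ring)
#' @return two-column matrix of polygon vertices (degrees).
#' @export
default_domain <- function() {
  cbind(c(0.0, 1.5, 3.0, 4.0, 4.3, 3.9, 3.0, 1.5, 0.4),
        c(0.0, -0.3, 0.0, 0.4, 1.2, 1.8, 1.9, 2.2, 1.5))
}

#' Scenario configuration for the survey simulator
#'
#' Defaults emulate an annual summer ground-fish trawl survey: about 200
#' sets per year on an irregular shelf, an 18-year span, a latent field with
#' range 0.3 degrees, SD 1.5 and persistence 0.6, and negative-binomial
#' counts with log-size 1.
#'
#' @param domain polygon ring (two-column matrix).
#' @param n_years number of survey years.
#' @param sets_per_year trawl sets per year (stratified by sub-zone with
#'   effort proportional to zone area).
#' @param rho,sigma,a true field parameters (range, stationary SD,
#'   persistence).
#' @param intercept baseline log abundance.
#' @param family "negative_binomial" or "poisson"; \code{phi} is the NB
#'   log size.
#' @param covariate_effects named list of functions applied to generated
#'   covariates and added to the linear predictor (default: a mild
#'   cold-water preference on "temperature").
#' @param n_zones number of sub-zones (vertical bands).
#' @param collapse_window year indices c(first, last) of the engineered
#'   collapse (collapse scenarios only).
#' @param contraction final bump radius as a fraction of the initial radius
#'   over the collapse window (in (0, 1)).
#' @param seed integer seed.
#' @param mesh_max_edge,mesh_cutoff simulation mesh controls.
#' @export
scenario_config <- function(domain = default_domain(), n_years = 18,
                            sets_per_year = 200, rho = 0.3, sigma = 1.5,
                            a = 0.6, intercept = 2,
                            family = "negative_binomial", phi = 1,
                            covariate_effects = list(
                              temperature = function(v) 0.08 * (6 - v)),
                            n_zones = 3, collapse_window = NULL,
                            contraction = 0.07, seed = 1,
                            mesh_max_edge = NULL, mesh_cutoff = NULL) {
  if (sets_per_year < 1) stop("sets_per_year must be >= 1")
  if (rho <= 0 || sigma <= 0 || abs(a) >= 1) stop("invalid field parameters")
  if (!is.null(collapse_window)) {
    if (collapse_window[1] < 1 || collapse_window[2] > n_years ||
        collapse_window[1] >= collapse_window[2])
      stop("collapse window must lie inside the year span")
    if (contraction <= 0) stop("config error: contraction schedule reaches zero area")
  }
  structure(list(domain = domain, n_years = as.integer(n_years),
                 sets_per_year = as.integer(sets_per_year), rho = rho,
                 sigma = sigma, a = a, intercept = intercept,
                 family = family, phi = phi,
                 covariate_effects = covariate_effects, n_zones = n_zones,
                 collapse_window = collapse_window,
                 contraction = contraction, seed = as.integer(seed),
                 mesh_max_edge = mesh_max_edge, mesh_cutoff = mesh_cutoff),
            class = "gmrfish_scenario")
}

# zone id of points: vertical bands of equal width over the domain bbox
.zone_of <- function(x, cfg) {
  br <- seq(min(cfg$domain[, 1]), max(cfg$domain[, 1]),
            length.out = cfg$n_zones + 1)
  pmin(pmax(findInterval(x, br, rightmost.closed = TRUE), 1L), cfg$n_zones)
}

# stratified-random sites: effort proportional to zone area
.survey_sites <- function(cfg, n) {
  bbox <- apply(cfg$domain, 2, range)
  # zone areas by MC on a deterministic grid
  gx <- seq(bbox[1, 1], bbox[2, 1], length.out = 120)
  gy <- seq(bbox[1, 2], bbox[2, 2], length.out = 80)
  gr <- expand.grid(x = gx, y = gy)
  inside <- .point_in_polygon(gr$x, gr$y, cfg$domain)
  zl <- .zone_of(gr$x[inside], cfg)
  frac <- tabulate(zl, cfg$n_zones) / sum(inside)
  n_zone <- round(n * frac)
  n_zone[cfg$n_zones] <- n - sum(n_zone[-cfg$n_zones])
  out <- matrix(NA_real_, 0, 2)
  for (z in seq_len(cfg$n_zones)) {
    got <- 0L
    while (got < n_zone[z]) {
      m <- max(20L, 4L * (n_zone[z] - got))
      px <- stats::runif(m, bbox[1, 1], bbox[2, 1])
      py <- stats::runif(m, bbox[1, 2], bbox[2, 2])
      ok <- .point_in_polygon(px, py, cfg$domain) & .zone_of(px, cfg) == z
      take <- utils::head(which(ok), n_zone[z] - got)
      out <- rbind(out, cbind(px[take], py[take]))
      got <- got + length(take)
    }
  }
  out
}

# simulation mesh: quasi-regular grid of in-domain points + polygon ring
.sim_mesh <- function(cfg) {
  bbox <- apply(cfg$domain, 2, range)
  diam <- sqrt(sum((bbox[2, ] - bbox[1, ])^2))
  max_edge <- cfg$mesh_max_edge %||% max(cfg$rho / 1.2, diam / 16)
  sp <- max_edge * 0.9
  gx <- seq(bbox[1, 1], bbox[2, 1], by = sp)
  gy <- seq(bbox[1, 2], bbox[2, 2], by = sp)
  gr <- as.matrix(expand.grid(gx, gy))
  # deterministic jitter de-regularises the grid (regular grids are
  # cocircular, which degrades Delaunay quality)
  k <- seq_len(nrow(gr))
  gr[, 1] <- gr[, 1] + 0.15 * sp * sin(k * 2.399963)
  gr[, 2] <- gr[, 2] + 0.15 * sp * cos(k * 1.618034)
  gr <- gr[.point_in_polygon(gr[, 1], gr[, 2], cfg$domain), , drop = FALSE]
  pts <- rbind(gr, cfg$domain)
  if (nrow(pts) < 3) stop("domain polygon too small for the simulation mesh")
  build_mesh(pts, max_edge = max_edge,
             cutoff = cfg$mesh_cutoff %||% (max_edge / 4))
}

# deterministic temperature-like covariate surface
.sim_temperature <- function(x, y, t, cfg) {
  bbox <- apply(cfg$domain, 2, range)
  xs <- (x - bbox[1, 1]) / (bbox[2, 1] - bbox[1, 1])
  ys <- (y - bbox[1, 2]) / (bbox[2, 2] - bbox[1, 2])
  4 + 4 * xs + 2 * sin(pi * ys) + 0.05 * t + stats::rnorm(length(x), 0, 0.4)
}

.sample_counts <- function(mu, cfg) {
  if (cfg$family == "poisson") stats::rpois(length(mu), mu)
  else stats::rnbinom(length(mu), size = exp(cfg$phi), mu = mu)
}

#' Simulate a trawl survey from the generative model
#'
#' Draws the latent field over a simulation mesh from the space-time SPDE
#' precision, places stratified-random survey sites each year, evaluates the
#' linear predictor with the configured covariate effects, and samples
#' counts. The hidden truth (field values, parameters, mesh) is attached as
#' the \code{truth} attribute for recovery tests.
#'
#' @param config a \code{gmrfish_scenario}.
#' @return a \code{gmrfish_survey} data frame with attribute \code{truth}.
#' @export
simulate_survey <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  mesh <- .sim_mesh(cfg)
  fem <- fem_matrices(mesh)
  T <- cfg$n_years
  Q <- spacetime_precision(list(rho = cfg$rho, sigma = cfg$sigma),
                           list(a = cfg$a, n_years = T), fem)
  xi <- matrix(sample_field(Q), mesh$n, T)
  rows <- vector("list", T)
  for (t in seq_len(T)) {
    sites <- .survey_sites(cfg, cfg$sets_per_year)
    A <- projection_matrix(mesh, sites, allow_outside = TRUE)
    f <- as.numeric(A %*% xi[, t])
    temp <- .sim_temperature(sites[, 1], sites[, 2], t, cfg)
    eta <- cfg$intercept + f
    covs <- list(temperature = temp)
    for (nm in names(cfg$covariate_effects))
      if (!is.null(covs[[nm]]))
        eta <- eta + cfg$covariate_effects[[nm]](covs[[nm]])
    mu <- exp(eta)
    rows[[t]] <- data.frame(lon = sites[, 1], lat = sites[, 2],
                            year = 2000L + t, count = .sample_counts(mu, cfg),
                            temperature = temp,
                            subzone = paste0("Z", .zone_of(sites[, 1], cfg)),
                            distance_towed = round(stats::runif(nrow(sites), 1.5, 3.5), 2),
                            eta_true = eta)
  }
  df <- do.call(rbind, rows)
  truth <- list(field = xi, mesh = mesh, rho = cfg$rho, sigma = cfg$sigma,
                a = cfg$a, phi = cfg$phi, intercept = cfg$intercept)
  eta_true <- df$eta_true
  df$eta_true <- NULL
  out <- survey_dataset(df)
  attr(out, "truth") <- c(truth, list(eta = eta_true))
  out
}

# plateau bump: height h inside 0.7*r, linear falloff to 0 at r
.bump <- function(d, h, r) h * pmin(1, pmax(0, (r - d) / (0.3 * r)))

#' Simulate an occupancy-abundance collapse (hyperstability) scenario
#'
#' The latent log-density is a deterministic surface of plateau bumps (the
#' dense aggregations) on top of a broad, low-contrast background field (a
#' persistent large-range environmental gradient). Over the collapse window
#' the bump radii shrink on an accelerating (quadratic) schedule to
#' \code{contraction} times their initial radius while the plateau heights
#' stay exactly constant, and the middle bump is eliminated entirely at
#' mid-window — occupied area contracts while core-area maxima do not move
#' (hyperstability by construction). Once the aggregations fall below the
#' survey's resolution only the broad background remains visible, so annual
#' fits see the field flatten: the range rho grows while the spatial SD
#' sigma drops, the erosion signature. The \code{truth} attribute carries
#' the deterministic surface on an evaluation grid and the true occupied
#' area (cells strictly above the surface's own 75th percentile) per year.
#'
#' @param config a \code{gmrfish_scenario} with a \code{collapse_window}.
#' @return a \code{gmrfish_survey} with attribute \code{truth}.
#' @export
simulate_collapse <- function(config) {
  cfg <- config
  if (is.null(cfg$collapse_window))
    stop("config has no collapse window")
  set.seed(cfg$seed)
  bbox <- apply(cfg$domain, 2, range)
  width <- bbox[2, 1] - bbox[1, 1]
  centers <- rbind(c(0.22, 0.45), c(0.5, 0.55), c(0.78, 0.5))
  centers <- cbind(bbox[1, 1] + centers[, 1] * width,
                   bbox[1, 2] + centers[, 2] * (bbox[2, 2] - bbox[1, 2]))
  h <- 4
  # bumps jointly cover < 25% of the domain, so the surface's own 75th
  # percentile sits at the flat baseline and "occupied" = bump footprint
  r0 <- 0.10 * width
  w0 <- cfg$collapse_window[1]; w1 <- cfg$collapse_window[2]
  kill_year <- ceiling((w0 + w1) / 2)
  # gentle shrink, then a one-year crash at kill_year (serial depletion is
  # abrupt), then continued slight shrink: strictly decreasing inside the
  # window, never zero
  radius_at <- function(t) {
    if (t <= w0) r0
    else if (t < kill_year)
      r0 * (1 - 0.15 * (t - w0) / max(1, kill_year - w0))
    else if (t == kill_year) r0 * cfg$contraction
    else r0 * cfg$contraction *
      (1 - 0.5 * min(1, (t - kill_year) / max(1, w1 - kill_year)))
  }
  surf <- function(x, y, t) {
    r <- radius_at(t)
    out <- rep(cfg$intercept, length(x))
    for (b in seq_len(nrow(centers))) {
      if (b == 2 && t >= kill_year) next
      d <- sqrt((x - centers[b, 1])^2 + (y - centers[b, 2])^2)
      out <- out + .bump(d, h, r)
    }
    out
  }
  # broad low-contrast background: large range, small SD, persistent
  # across years (the environmental gradient that outlives the aggregations)
  mesh <- .sim_mesh(cfg)
  fem <- fem_matrices(mesh)
  kap <- kappa_from_range(0.8 * width)
  qs <- spatial_precision(kap, tau_from_sigma(0.6, kap), fem)
  res <- sample_field(qs, n_draws = cfg$n_years)

  # evaluation grid for the truth (includes the bump centers); fine enough
  # to resolve the smallest post-crash radii
  gx <- seq(bbox[1, 1], bbox[2, 1], length.out = 240)
  gy <- seq(bbox[1, 2], bbox[2, 2], length.out = 140)
  gr <- as.matrix(expand.grid(gx, gy))
  gin <- .point_in_polygon(gr[, 1], gr[, 2], cfg$domain)
  eval_pts <- rbind(gr[gin, , drop = FALSE], centers)
  eta_det_grid <- sapply(seq_len(cfg$n_years), function(t)
    surf(eval_pts[, 1], eval_pts[, 2], t))
  # area where the deterministic surface exceeds its own 75th percentile:
  # the bumps cover < 25% of the domain, so that threshold is the flat
  # baseline and the occupied area is exactly the (disjoint) bump footprint
  dom_area <- abs(sum(cfg$domain[, 1] * c(cfg$domain[-1, 2], cfg$domain[1, 2]) -
                      cfg$domain[, 2] * c(cfg$domain[-1, 1], cfg$domain[1, 1]))) / 2
  occupied <- vapply(seq_len(cfg$n_years), function(t) {
    alive <- if (t >= kill_year) c(1, 3) else 1:3
    length(alive) * pi * radius_at(t)^2 / dom_area
  }, numeric(1))

  rows <- vector("list", cfg$n_years)
  for (t in seq_len(cfg$n_years)) {
    sites <- .survey_sites(cfg, cfg$sets_per_year)
    A <- projection_matrix(mesh, sites, allow_outside = TRUE)
    eta <- surf(sites[, 1], sites[, 2], t) + as.numeric(A %*% res[, t])
    rows[[t]] <- data.frame(lon = sites[, 1], lat = sites[, 2],
                            year = 2000L + t,
                            count = .sample_counts(exp(eta), cfg),
                            subzone = paste0("Z", .zone_of(sites[, 1], cfg)))
  }
  out <- survey_dataset(do.call(rbind, rows))
  attr(out, "truth") <- list(
    surface = surf, eval_points = eval_pts, eta_det = eta_det_grid,
    occupied_area = occupied, bump_height = h, centers = centers,
    radius_at = radius_at, kill_year = kill_year,
    window = cfg$collapse_window, mesh = mesh)
  out
}

#' Simulate annual landings allocated across sub-zones
#'
#' Landings shares are proportional to (zone survey abundance)^targeting:
#' targeting = 0 spreads effort evenly, targeting = 1 matches the abundance
#' distribution (relative exploitation then equals 1 in every zone), and
#' targeting > 1 concentrates effort on dense zones, emulating local
#' overfishing.
#'
#' @param survey a survey dataset with subzone labels.
#' @param targeting non-negative exponent.
#' @param total_per_year total landings per year (arbitrary tonnes).
#' @param seed optional seed (the allocation itself is deterministic).
#' @return data frame with subzone, year, landings.
#' @export
simulate_landings <- function(survey, targeting = 1, total_per_year = 1000,
                              seed = NULL) {
  if (is.null(survey$subzone)) stop("survey has no sub-zones")
  if (targeting < 0) stop("targeting must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  ab <- stats::aggregate(count ~ subzone + year, data = as.data.frame(survey),
                         FUN = sum)
  out <- do.call(rbind, lapply(split(ab, ab$year), function(d) {
    wgt <- if (targeting == 0) rep(1, nrow(d)) else d$count^targeting
    if (sum(wgt) == 0) wgt <- rep(1, nrow(d))
    data.frame(subzone = d$subzone, year = d$year,
               landings = total_per_year * wgt / sum(wgt))
  }))
  rownames(out) <- NULL
  out
}
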