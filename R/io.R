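# Readers/writers and run configuration. CSV is the canonical tabular
# format (survey and landings extracts), GeoJSON for sub-zone polygons,
# JSON for artifacts; the run configuration is YAML or JSON validated
# against a schema before any computation.

#' Read a survey CSV
#'
#' Required columns: lon, lat, year, count. Unknown numeric columns are
#' preserved as covariates; \code{subzone} and \code{distance_towed} are
#' recognised. Negative counts and unparsable rows are rejected with
#' row-numbered errors.
#'
#' @param path CSV file path.
#' @return a \code{gmrfish_survey}.
#' @export
read_survey_csv <- function(path) {
  if (!file.exists(path)) stop("survey file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("lon", "lat", "year", "count")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("schema error: missing required column(s): ",
                         paste(miss, collapse = ", "))
  for (col in req) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) stop("unparsable value in column '", col, "' at row(s): ",
                          paste(utils::head(bad, 10), collapse = ", "))
    na <- which(is.na(v))
    if (length(na)) stop("missing value in column '", col, "' at row(s): ",
                         paste(utils::head(na, 10), collapse = ", "))
    df[[col]] <- v
  }
  survey_dataset(df)
}

#' Write a survey dataset to CSV
#' @param survey a \code{gmrfish_survey}.
#' @param path output path.
#' @export
write_survey_csv <- function(survey, path) {
  utils::write.csv(as.data.frame(survey), path, row.names = FALSE)
  invisible(path)
}

#' Read a landings CSV (columns: subzone, year, landings)
#' @param path CSV file path.
#' @return data frame with yearly totals in attribute \code{totals}.
#' @export
read_landings_csv <- function(path) {
  if (!file.exists(path)) stop("landings file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("subzone", "year", "landings"), names(df))
  if (length(miss)) stop("schema error: missing required column(s): ",
                         paste(miss, collapse = ", "))
  df$year <- as.integer(df$year)
  df$landings <- as.numeric(df$landings)
  if (any(is.na(df$landings))) stop("unparsable landings at row(s): ",
    paste(utils::head(which(is.na(df$landings)), 10), collapse = ", "))
  if (any(df$landings < 0)) stop("negative landings at row(s): ",
    paste(utils::head(which(df$landings < 0), 10), collapse = ", "))
  attr(df, "totals") <- stats::aggregate(landings ~ year, df, sum)
  df
}

#' Write a landings table to CSV
#' @param landings data frame with subzone, year, landings.
#' @param path output path.
#' @export
write_landings_csv <- function(landings, path) {
  utils::write.csv(as.data.frame(landings)[c("subzone", "year", "landings")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read sub-zone polygons from GeoJSON
#'
#' Supports a FeatureCollection of Polygon/MultiPolygon features; the zone
#' label is taken from the \code{subzone} property (or the first property).
#'
#' @param path GeoJSON file path.
#' @return named list of polygon rings (two-column matrices).
#' @export
read_zones_geojson <- function(path) {
  if (!file.exists(path)) stop("zones file not found: ", path)
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("expected a GeoJSON FeatureCollection")
  out <- list()
  for (ft in gj$features) {
    props <- ft$properties
    label <- if (!is.null(props$subzone)) props$subzone
             else if (length(props)) props[[1]] else paste0("zone", length(out) + 1)
    geom <- ft$geometry
    rings <- switch(geom$type,
      Polygon = list(geom$coordinates[[1]]),
      MultiPolygon = lapply(geom$coordinates, function(p) p[[1]]),
      stop("unsupported geometry type: ", geom$type))
    for (rg in rings) {
      mat <- do.call(rbind, lapply(rg, function(xy) c(xy[[1]], xy[[2]])))
      out[[length(out) + 1L]] <- mat
      names(out)[length(out)] <- as.character(label)
    }
  }
  out
}

#' Write sub-zone polygons to GeoJSON
#' @param zones named list of polygon rings.
#' @param path output path.
#' @export
write_zones_geojson <- function(zones, path) {
  feats <- lapply(names(zones), function(nm) {
    ring <- zones[[nm]]
    if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
    list(type = "Feature", properties = list(subzone = nm),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(i) as.numeric(ring[i, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Assign survey records to sub-zones by point-in-polygon
#'
#' Zones are tested in alphabetical label order with first match winning, so
#' points on a shared boundary get the alphabetically lowest zone label.
#'
#' @param survey survey dataset.
#' @param zones named list of polygon rings.
#' @param boundary_tol distance treated as "on the boundary".
#' @export
assign_subzones <- function(survey, zones, boundary_tol = 1e-9) {
  labels <- sort(names(zones))
  sz <- rep(NA_character_, nrow(survey))
  for (lb in labels) {
    ring <- zones[[lb]]
    un <- which(is.na(sz))
    if (!length(un)) break
    hit <- .point_in_polygon(survey$lon[un], survey$lat[un], ring) |
      .dist_to_ring(survey$lon[un], survey$lat[un], ring) <= boundary_tol
    sz[un[hit]] <- lb
  }
  survey$subzone <- sz
  survey_dataset(as.data.frame(survey))
}

## ---- run configuration -------------------------------------------------------

.config_schema <- list(
  model = list(spatial = "character", covariates = "character",
               family = "character", n_knots = "numeric"),
  prior = list(rho0 = "numeric", alpha_rho = "numeric", sigma0 = "numeric",
               alpha_sigma = "numeric"),
  mesh = list(max_edge = "numeric", cutoff = "numeric"),
  assessment = list(folds = "numeric", seed = "numeric"),
  diagnostics = list(quantile = "numeric", delta_rho = "numeric",
                     delta_sigma = "numeric", min_sets = "numeric"),
  fit = list(maxit = "numeric", grid = "logical", compute_sd = "logical"),
  simulate = list(n_years = "numeric", sets_per_year = "numeric",
                  rho = "numeric", sigma = "numeric", a = "numeric",
                  intercept = "numeric", phi = "numeric",
                  collapse_window = "numeric", contraction = "numeric")
)

#' Default run configuration
#'
#' Prior and diagnostic defaults follow the reference analysis: rho0 = 0.5
#' with P(rho < 0.5) = 0.5, sigma0 = 0.75 with P(sigma > 0.75) = 0.5,
#' core-range quantile 0.75, smoothness nu = 1.
#' @export
default_config <- function() {
  list(model = list(spatial = "ar1", covariates = character(0),
                    family = "negative_binomial", n_knots = 25),
       prior = list(rho0 = 0.5, alpha_rho = 0.5, sigma0 = 0.75,
                    alpha_sigma = 0.5),
       mesh = list(),
       assessment = list(folds = 20, seed = 1),
       diagnostics = list(quantile = 0.75, delta_rho = log(1.5),
                          delta_sigma = log(1.2), min_sets = 30),
       fit = list(maxit = 150, grid = TRUE, compute_sd = TRUE),
       simulate = list(n_years = 18, sets_per_year = 200, rho = 0.3,
                       sigma = 1.5, a = 0.6, intercept = 2, phi = 1))
}

#' Validate a configuration list against the schema
#' @param config configuration list.
#' @return the config merged over the defaults, or an error naming the first
#'   offending entry.
#' @export
validate_config <- function(config) {
  for (sec in names(config)) {
    if (!sec %in% names(.config_schema))
      stop("unknown config section: ", sec)
    for (key in names(config[[sec]])) {
      want <- .config_schema[[sec]][[key]]
      if (is.null(want)) stop("unknown config key: ", sec, ".", key)
      val <- config[[sec]][[key]]
      ok <- switch(want, numeric = is.numeric(val),
                   character = is.character(val), logical = is.logical(val))
      if (!ok && length(val)) stop("config ", sec, ".", key, " must be ", want)
    }
  }
  cfg <- default_config()
  for (sec in names(config))
    cfg[[sec]] <- utils::modifyList(cfg[[sec]], config[[sec]],
                                    keep.null = TRUE)
  if (cfg$prior$rho0 <= 0 || cfg$prior$sigma0 <= 0 ||
      cfg$prior$alpha_rho <= 0 || cfg$prior$alpha_rho >= 1 ||
      cfg$prior$alpha_sigma <= 0 || cfg$prior$alpha_sigma >= 1)
    stop("invalid prior calibration in config")
  if (cfg$diagnostics$quantile <= 0 || cfg$diagnostics$quantile >= 1)
    stop("config diagnostics.quantile must be in (0,1)")
  cfg
}

#' Read a YAML or JSON run configuration
#' @param path file path (.yaml/.yml or .json).
#' @export
read_config <- function(path) {
  if (is.null(path)) return(validate_config(list()))
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (!is.null(raw$model$covariates))
    raw$model$covariates <- as.character(raw$model$covariates)
  validate_config(raw)
}

# polynomial rolling hash of a deparsed object (stable run identifier)
.config_hash <- function(obj) {
  s <- paste(deparse(obj), collapse = "")
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Serialise a fit to a JSON artifact
#'
#' Includes hyperparameter mode and grid, the intercept and smooth
#' coefficients, per-observation fitted means and the observed counts (so
#' that RMSEE is recomputable from the artifact alone), and a config hash.
#'
#' @param fit a \code{gmrfish_fit}.
#' @param path output JSON path.
#' @param config optional configuration used for the fit.
#' @export
write_fit_json <- function(fit, path, config = NULL) {
  hm <- fit$hyper_mode
  obj <- list(
    package = "gmrfish", version = "0.1.0",
    spec = list(spatial = fit$spec$spatial, family = fit$spec$family,
                covariates = fit$spec$covariates),
    config_hash = if (!is.null(config)) .config_hash(config) else NA,
    hyper_mode = list(rho = hm$rho, sigma = hm$sigma, a = hm$a, phi = hm$phi,
                      tau_f = as.list(hm$tau_f), theta = as.list(hm$theta)),
    hyper_grid = fit$hyper_grid,
    log_marginal = fit$log_marginal,
    intercept = fit$intercept,
    smooth_coefs = fit$smooth_coefs,
    years = fit$years,
    fitted_mu = fit$fitted_mu,
    counts = fit$y,
    converged = fit$converged,
    boundary_warning = fit$boundary_warning)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}
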