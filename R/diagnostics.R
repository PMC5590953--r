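# Spatial stock-structure diagnostics: relative exploitation by sub-zone,
# per-year (rho_t, sigma_t) trajectories from annual spatial fits, core-range
# masks at the 75th percentile of predicted abundance, and the
# erosion/recovery classifier for trajectory transitions. Local overfishing
# (serial depletion of high-density patches) is expected to appear as a
# simultaneous increase in the range rho and decrease in the spatial SD
# sigma: the field flattens.

#' Relative exploitation by sub-zone and year
#'
#' \eqn{RE(i,t) = \frac{Landings_{i,t}/Landings_t}{OBIS_{i,t}/OBIS_t}}: the
#' ratio of a sub-zone's share of the year's landings to its share of the
#' year's survey abundance. RE > 1 marks disproportionate harvesting.
#' Sub-zones with zero survey abundance but positive landings are flagged
#' undefined (NA), not infinite; years with zero total survey count are
#' excluded with a warning.
#'
#' @param landings data frame with columns subzone, year, landings.
#' @param survey a survey dataset with a \code{subzone} column.
#' @return data frame (class \code{gmrfish_re_table}) with columns subzone,
#'   year, landings, landings_total, obis, obis_total, re.
#' @export
relative_exploitation <- function(landings, survey) {
  if (!all(c("subzone", "year", "landings") %in% names(landings)))
    stop("landings must have columns subzone, year, landings")
  if (is.null(survey$subzone)) stop("survey has no subzone labels")
  ob <- stats::aggregate(count ~ subzone + year, data = as.data.frame(survey),
                         FUN = sum)
  names(ob)[3] <- "obis"
  la <- stats::aggregate(landings ~ subzone + year, data = landings, FUN = sum)
  tab <- merge(la, ob, by = c("subzone", "year"), all = TRUE)
  tab$landings[is.na(tab$landings)] <- 0
  tab$obis[is.na(tab$obis)] <- 0
  lt <- tapply(tab$landings, tab$year, sum)
  ot <- tapply(tab$obis, tab$year, sum)
  tab$landings_total <- as.numeric(lt[as.character(tab$year)])
  tab$obis_total <- as.numeric(ot[as.character(tab$year)])
  zero_years <- names(ot)[ot == 0]
  if (length(zero_years)) {
    warning("years with zero total survey count excluded: ",
            paste(zero_years, collapse = ", "))
    tab <- tab[!(tab$year %in% as.integer(zero_years)), , drop = FALSE]
  }
  ls <- tab$landings / tab$landings_total
  os <- tab$obis / tab$obis_total
  tab$re <- ifelse(os == 0 & ls > 0, NA_real_,
                   ifelse(os == 0, 0, ls / os))
  tab <- tab[order(tab$year, tab$subzone),
             c("subzone", "year", "landings", "landings_total",
               "obis", "obis_total", "re")]
  rownames(tab) <- NULL
  class(tab) <- c("gmrfish_re_table", "data.frame")
  tab
}

#' Join relative exploitation back onto survey records as a covariate
#'
#' Records whose (subzone, year) has undefined RE get NA and are counted;
#' they are dropped (with a message) when used in a smooth.
#'
#' @param survey survey dataset with subzone labels.
#' @param re_table output of \code{\link{relative_exploitation}}.
#' @param name covariate column name (default "re").
#' @export
attach_relative_exploitation <- function(survey, re_table, name = "re") {
  key <- paste(survey$subzone, survey$year)
  tkey <- paste(re_table$subzone, re_table$year)
  survey[[name]] <- re_table$re[match(key, tkey)]
  n_na <- sum(is.na(survey[[name]]))
  if (n_na) message(n_na, " records have undefined relative exploitation")
  survey_dataset(as.data.frame(survey))
}

#' Per-year spatial parameter trajectory
#'
#' Fits the spatial model to each year of data separately (a single spatial
#' field, no persistence parameter) and records the per-year range rho_t and
#' spatial SD sigma_t. Years with fewer than \code{min_sets} records, or
#' whose fit fails, are marked missing rather than dropped silently. A rho_t
#' exceeding the domain diameter is flagged (reported, never clamped).
#'
#' @param spec a \code{gmrfish_model_spec}; its spatial structure is replaced
#'   by "constant" for the annual fits.
#' @param data survey dataset.
#' @param mesh optional shared mesh (built on the full data otherwise).
#' @param mesh_args mesh construction arguments.
#' @param min_sets minimum records per year (default 30).
#' @param control fit control (defaults: no grid, no SDs — point estimates).
#' @return data frame of class \code{gmrfish_trajectory}: year, rho, sigma,
#'   n_sets, converged, rho_exceeds_domain.
#' @export
annual_parameter_series <- function(spec, data, mesh = NULL,
                                    mesh_args = list(), min_sets = 30,
                                    control = list()) {
  data <- survey_dataset(as.data.frame(data))
  spec_y <- spec
  spec_y$spatial <- "constant"
  if (is.null(mesh)) {
    coords <- cbind(data$lon, data$lat)
    diam <- sqrt(sum((apply(coords, 2, max) - apply(coords, 2, min))^2))
    mesh <- do.call(build_mesh, c(list(locations = coords,
      max_edge = mesh_args$max_edge %||% (diam / 8),
      cutoff = mesh_args$cutoff %||% (diam / 40)),
      mesh_args[setdiff(names(mesh_args), c("max_edge", "cutoff"))]))
  }
  diam <- sqrt(sum((apply(mesh$loc, 2, max) - apply(mesh$loc, 2, min))^2))
  ctl <- utils::modifyList(list(grid = FALSE, compute_sd = FALSE,
                                maxit = 200), control)
  years <- sort(unique(data$year))
  out <- data.frame(year = years, rho = NA_real_, sigma = NA_real_,
                    n_sets = NA_integer_, converged = FALSE,
                    rho_exceeds_domain = NA)
  ok_any <- FALSE
  for (i in seq_along(years)) {
    dy <- data[data$year == years[i], , drop = FALSE]
    out$n_sets[i] <- nrow(dy)
    if (nrow(dy) < min_sets) next
    fit <- tryCatch(fit_abundance_model(spec_y, dy, mesh = mesh,
                                        control = ctl),
                    error = function(e) NULL)
    if (is.null(fit)) {      # retry once from a flatter start
      ctl2 <- utils::modifyList(ctl, list(theta_init = c(
        log_rho = log(diam), log_sigma = -1)))
      fit <- tryCatch(fit_abundance_model(spec_y, dy, mesh = mesh,
                                          control = ctl2),
                      error = function(e) NULL)
    }
    if (is.null(fit)) next
    out$rho[i] <- fit$hyper_mode$rho
    out$sigma[i] <- fit$hyper_mode$sigma
    out$converged[i] <- isTRUE(fit$converged)
    out$rho_exceeds_domain[i] <- fit$hyper_mode$rho > diam
    ok_any <- TRUE
  }
  if (!ok_any) stop("all annual fits failed")
  attr(out, "domain_diameter") <- diam
  class(out) <- c("gmrfish_trajectory", "data.frame")
  out
}

#' Classify year-to-year transitions of a (rho, sigma) trajectory
#'
#' For each consecutive pair of available years the movement
#' \eqn{(\Delta \log \rho, \Delta \log \sigma)} is labelled:
#' \describe{
#'   \item{erosion}{rho increases strongly while sigma decreases — the field
#'     flattens, the signature of spatial stock erosion and, at the extreme,
#'     destruction (movement to the lower left of the range/SD plane).}
#'   \item{recovery}{rho decreases strongly while sigma increases —
#'     structure re-establishes together with contrast.}
#'   \item{fluctuation}{both movements below their thresholds.}
#'   \item{stable}{anything else (one large movement without the other).}
#' }
#' Transitions touching a missing year are skipped and reported.
#'
#' @param trajectory a \code{gmrfish_trajectory} (or data frame with year,
#'   rho, sigma).
#' @param delta_rho log-scale threshold for a "large" rho movement
#'   (default log(1.5)).
#' @param delta_sigma log-scale threshold for a "large" sigma movement
#'   (default log(1.2)).
#' @return data frame with from, to, dlog_rho, dlog_sigma, label; skipped
#'   transitions in attribute \code{skipped}.
#' @export
erosion_classify <- function(trajectory, delta_rho = log(1.5),
                             delta_sigma = log(1.2)) {
  tr <- as.data.frame(trajectory)
  if (nrow(tr) < 2) stop("need at least 2 years to classify transitions")
  tr <- tr[order(tr$year), , drop = FALSE]
  from <- tr$year[-nrow(tr)]; to <- tr$year[-1]
  dr <- diff(log(tr$rho)); ds <- diff(log(tr$sigma))
  ok <- is.finite(dr) & is.finite(ds)
  label <- rep(NA_character_, length(dr))
  label[ok & dr > delta_rho & ds < -delta_sigma] <- "erosion"
  label[ok & dr < -delta_rho & ds > delta_sigma] <- "recovery"
  label[ok & is.na(label) & abs(dr) <= delta_rho & abs(ds) <= delta_sigma] <-
    "fluctuation"
  label[ok & is.na(label)] <- "stable"
  out <- data.frame(from = from, to = to, dlog_rho = dr, dlog_sigma = ds,
                    label = label)
  attr(out, "skipped") <- out[!ok, c("from", "to")]
  attr(out, "thresholds") <- c(delta_rho = delta_rho,
                               delta_sigma = delta_sigma)
  out
}

#' Core-range mask at a quantile of predicted abundance
#'
#' Thresholds predicted surfaces at a quantile of the predicted values
#' (default the 75th percentile, pooled across all years so that
#' contraction over time is visible) and masks the cells at or above it.
#' Connected components (8-neighbour) are labelled as patches with areas,
#' centroids and pairwise centroid separations, reported both in coordinate
#' units and in multiples of the range rho when given.
#'
#' @param surfaces a matrix of predicted values (one year), or a named list
#'   of matrices (one per year) on a common grid. Rows index x, columns y.
#' @param x,y grid coordinates (defaults: unit spacing).
#' @param quantile threshold quantile in (0, 1), default 0.75.
#' @param pooled if TRUE (default) one threshold is computed from all years
#'   pooled; otherwise per year.
#' @param rho optional range estimate for separation in units of rho.
#' @return list of class \code{gmrfish_core_range}: threshold, per-year
#'   masks, patches (per year), degenerate flag.
#' @export
core_range_mask <- function(surfaces, x = NULL, y = NULL, quantile = 0.75,
                            pooled = TRUE, rho = NULL) {
  if (is.matrix(surfaces)) surfaces <- list(surface = surfaces)
  dims <- dim(surfaces[[1]])
  if (is.null(x)) x <- seq_len(dims[1])
  if (is.null(y)) y <- seq_len(dims[2])
  cell <- (if (length(x) > 1) mean(diff(x)) else 1) *
          (if (length(y) > 1) mean(diff(y)) else 1)
  vals <- unlist(lapply(surfaces, function(s) s[is.finite(s)]))
  if (!length(vals)) stop("no finite surface values")
  degenerate <- FALSE
  thr_pooled <- stats::quantile(vals, probs = quantile, type = 7, names = FALSE)
  out_years <- lapply(names(surfaces), function(nm) {
    s <- surfaces[[nm]]
    thr <- if (pooled) thr_pooled else
      stats::quantile(s[is.finite(s)], probs = quantile, type = 7, names = FALSE)
    mask <- is.finite(s) & s >= thr
    if (all(mask[is.finite(s)])) degenerate <<- TRUE
    lab <- .label_components(mask)
    patches <- .patch_summary(lab, s, x, y, cell, rho)
    list(year = nm, threshold = thr, mask = mask, labels = lab,
         patches = patches)
  })
  names(out_years) <- names(surfaces)
  structure(list(threshold = if (pooled) thr_pooled else NA_real_,
                 quantile = quantile, pooled = pooled, years = out_years,
                 cell_area = cell, degenerate = degenerate),
            class = "gmrfish_core_range")
}

# 8-neighbour connected components of a logical matrix (iterative BFS)
.label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      cl <- queue[length(queue)]; queue <- queue[-length(queue)]
      i <- ((cl - 1L) %% nr) + 1L
      j <- ((cl - 1L) %/% nr) + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1L || ii > nr || jj < 1L || jj > nc) next
        cl2 <- (jj - 1L) * nr + ii
        if (mask[cl2] && lab[cl2] == 0L) { lab[cl2] <- cur; queue <- c(queue, cl2) }
      }
    }
  }
  lab
}

.patch_summary <- function(lab, s, x, y, cell, rho) {
  k <- max(lab)
  if (k == 0) return(data.frame(patch = integer(0), area = numeric(0),
                                max_value = numeric(0), cx = numeric(0),
                                cy = numeric(0)))
  nr <- nrow(lab)
  df <- do.call(rbind, lapply(seq_len(k), function(p) {
    cells <- which(lab == p)
    i <- ((cells - 1L) %% nr) + 1L
    j <- ((cells - 1L) %/% nr) + 1L
    data.frame(patch = p, area = length(cells) * cell,
               n_cells = length(cells),
               max_value = max(s[cells]), cx = mean(x[i]), cy = mean(y[j]))
  }))
  sep <- NULL
  if (k >= 2) {
    pr <- t(utils::combn(k, 2))
    d <- sqrt((df$cx[pr[, 1]] - df$cx[pr[, 2]])^2 +
              (df$cy[pr[, 1]] - df$cy[pr[, 2]])^2)
    sep <- data.frame(patch_a = pr[, 1], patch_b = pr[, 2], separation = d,
                      separation_over_rho = if (!is.null(rho)) d / rho else NA_real_)
  }
  attr(df, "separations") <- sep
  df
}
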