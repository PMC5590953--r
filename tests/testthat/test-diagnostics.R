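# Relative exploitation, annual parameter trajectories, core-range masks,
# and the erosion/recovery classifier.

toy_survey_zones <- function() {
  survey_dataset(data.frame(
    lon = rep(c(0.2, 0.5, 0.8), 4), lat = 0.5,
    year = rep(c(2000L, 2001L), each = 6),
    count = c(10, 10, 80, 10, 10, 80,     # year 2000: shares .1 .1 .8
              25, 25, 50, 25, 25, 50),    # year 2001: shares .25 .25 .5
    subzone = rep(c("A", "B", "C"), 4)))
}

test_that("relative exploitation equals the ratio of shares", {
  sv <- toy_survey_zones()
  landings <- data.frame(subzone = rep(c("A", "B", "C"), 2),
                         year = rep(c(2000L, 2001L), each = 3),
                         landings = c(20, 20, 160,     # matched shares
                                      100, 50, 50))    # A overharvested
  re <- relative_exploitation(landings, sv)
  # equal shares -> RE = 1
  expect_equal(re$re[re$year == 2000], rep(1, 3), tolerance = 1e-12)
  # landings share 0.5 vs survey share 0.25 -> RE = 2
  expect_equal(re$re[re$year == 2001 & re$subzone == "A"], 2, tolerance = 1e-12)
  # full hand computation, 3 zones x 2 years
  hand <- c(1, 1, 1, 2, 1, 0.5)
  expect_equal(re$re[order(re$year, re$subzone)], hand, tolerance = 1e-12)
  # share conservation per year
  for (yr in c(2000, 2001)) {
    sub <- re[re$year == yr, ]
    expect_equal(sum(sub$landings / sub$landings_total), 1, tolerance = 1e-12)
    expect_equal(sum(sub$obis / sub$obis_total), 1, tolerance = 1e-12)
  }
})

test_that("undefined RE cells are NA, zero survey years are excluded", {
  sv <- survey_dataset(data.frame(lon = c(0.1, 0.9, 0.1, 0.9),
                                  lat = 0.5,
                                  year = c(2000L, 2000L, 2001L, 2001L),
                                  count = c(5L, 0L, 0L, 0L),
                                  subzone = c("A", "B", "A", "B")))
  landings <- data.frame(subzone = rep(c("A", "B"), 2),
                         year = rep(c(2000L, 2001L), each = 2),
                         landings = c(10, 10, 10, 10))
  expect_warning(re <- relative_exploitation(landings, sv),
                 "zero total survey count")
  expect_false(2001 %in% re$year)
  # zone B in 2000: landings > 0 but no survey abundance -> NA, not Inf
  expect_true(is.na(re$re[re$subzone == "B"]))
  # attach as covariate: NA propagates and is reported
  expect_message(sv2 <- attach_relative_exploitation(sv, re),
                 "undefined relative exploitation")
  expect_true("re" %in% attr(sv2, "covariates"))
})

test_that("annual fits recover a constant field's range and flag short years", {
  # one fixed spatial field observed for 5 years (no persistence dynamics)
  set.seed(61)
  m <- suppressWarnings(build_mesh(hex_lattice(0.1), max_edge = 0.11,
                                   cutoff = 0.02))
  fem <- fem_matrices(m)
  rho_true <- 0.35; sigma_true <- 1.3
  kap <- kappa_from_range(rho_true)
  Q <- spatial_precision(kap, tau_from_sigma(sigma_true, kap), fem)
  xi <- sample_field(Q, seed = 61)
  rows <- lapply(1:5, function(t) {
    sites <- cbind(runif(120), runif(120))
    f <- as.numeric(projection_matrix(m, sites, allow_outside = TRUE) %*% xi)
    data.frame(lon = sites[, 1], lat = sites[, 2], year = 2000L + t,
               count = rpois(120, exp(1.5 + f)))
  })
  rows[[6]] <- data.frame(lon = runif(5), lat = runif(5), year = 2006L,
                          count = 1L)   # too few sets
  sv <- survey_dataset(do.call(rbind, rows))
  spec <- model_spec(spatial = "constant", family = "poisson")
  traj <- annual_parameter_series(spec, sv,
                                  mesh_args = list(max_edge = 0.2, cutoff = 0.04),
                                  min_sets = 30)
  expect_s3_class(traj, "gmrfish_trajectory")
  expect_true(is.na(traj$rho[traj$year == 2006]))
  expect_equal(traj$n_sets[traj$year == 2006], 5L)
  est <- traj$rho[traj$year != 2006]
  expect_lt(abs(median(est) - rho_true) / rho_true, 0.3)
  expect_false(any(traj$rho_exceeds_domain[traj$year != 2006]))
})

test_that("core-range mask thresholds by order statistics", {
  s <- matrix(1:100, 10, 10)
  cr <- core_range_mask(s, quantile = 0.75)
  expect_equal(sum(cr$years[[1]]$mask), 25L)
  # raising the quantile never enlarges the mask
  masks <- sapply(c(0.5, 0.6, 0.75, 0.9, 0.95),
                  function(q) sum(core_range_mask(s, quantile = q)$years[[1]]$mask))
  expect_true(all(diff(masks) < 0))
  # degenerate all-equal surface: everything masked, flagged
  cr2 <- core_range_mask(matrix(1, 5, 5))
  expect_true(cr2$degenerate)
  expect_true(all(cr2$years[[1]]$mask))
})

test_that("two bumps give two patches with separation reported in rho units", {
  x <- seq(0, 3, length.out = 61); y <- seq(0, 1, length.out = 21)
  rho <- 0.4
  s <- outer(x, y, function(xx, yy)
    exp(-((xx - 0.75)^2 + (yy - 0.5)^2) / 0.02) +
    exp(-((xx - 1.95)^2 + (yy - 0.5)^2) / 0.02))  # centres 3 rho apart
  cr <- core_range_mask(s, x = x, y = y, quantile = 0.75, rho = rho)
  p <- cr$years[[1]]$patches
  expect_equal(nrow(p), 2L)
  sep <- attr(p, "separations")
  expect_gte(sep$separation_over_rho[1], 2)
  expect_equal(sep$separation[1], 1.2, tolerance = 0.05)
})

test_that("contraction shrinks patch area but not patch maxima", {
  x <- seq(0, 1, length.out = 41); y <- seq(0, 1, length.out = 41)
  bump <- function(w) outer(x, y, function(xx, yy)
    5 * pmin(1, pmax(0, (w - sqrt((xx - 0.5)^2 + (yy - 0.5)^2)) / (0.3 * w))))
  s1 <- bump(0.3); s2 <- bump(0.15)   # year 2 shrunk around the maximum
  # quantile 0.9 places the pooled threshold inside the bump values (the
  # flat zero background covers more than 75% of the pooled cells)
  cr <- core_range_mask(list(y1 = s1, y2 = s2), x = x, y = y, quantile = 0.9)
  p1 <- cr$years$y1$patches; p2 <- cr$years$y2$patches
  expect_lt(p2$area[1], p1$area[1])
  expect_equal(p2$max_value[1], p1$max_value[1], tolerance = 1e-12)
})

test_that("the classifier reproduces the reference collapse transitions", {
  # second collapse: rho 4.40 -> 26.43 with sigma 4.2 -> 2.1
  tr <- data.frame(year = 1:2, rho = c(4.40, 26.43), sigma = c(4.2, 2.1))
  expect_equal(erosion_classify(tr)$label, "erosion")
  # first collapse: rho 2.61 -> 7.50 with sigma 2.8 -> 2.2
  tr2 <- data.frame(year = 1:2, rho = c(2.61, 7.50), sigma = c(2.8, 2.2))
  expect_equal(erosion_classify(tr2)$label, "erosion")
  # no movement at all is fluctuation
  tr3 <- data.frame(year = 1:2, rho = c(1, 1), sigma = c(1, 1))
  expect_equal(erosion_classify(tr3)$label, "fluctuation")
  # one large movement without the other is merely "stable"
  tr4 <- data.frame(year = 1:2, rho = c(1, 3), sigma = c(1, 1))
  expect_equal(erosion_classify(tr4)$label, "stable")
  # recovery is the mirror image
  tr5 <- data.frame(year = 1:2, rho = c(7.50, 2.61), sigma = c(2.2, 2.8))
  expect_equal(erosion_classify(tr5)$label, "recovery")
})

test_that("reversing time maps erosion to recovery exactly", {
  set.seed(62)
  tr <- data.frame(year = 1:12, rho = exp(rnorm(12, 0, 0.8)),
                   sigma = exp(rnorm(12, 0, 0.5)))
  fwd <- erosion_classify(tr)
  rev_tr <- data.frame(year = 1:12, rho = rev(tr$rho), sigma = rev(tr$sigma))
  bwd <- erosion_classify(rev_tr)
  map <- c(erosion = "recovery", recovery = "erosion",
           fluctuation = "fluctuation", stable = "stable")
  expect_equal(unname(map[rev(fwd$label)]), bwd$label)
})

test_that("missing years skip transitions with a report", {
  tr <- data.frame(year = 1:4, rho = c(1, NA, 2, 3), sigma = c(1, NA, 1, 1))
  lab <- erosion_classify(tr)
  expect_true(all(is.na(lab$label[1:2])))
  expect_equal(nrow(attr(lab, "skipped")), 2L)
  expect_error(erosion_classify(tr[1, ]), "at least 2 years")
})
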