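# Triangulated domains and finite-element matrices for the SPDE
# representation of a Matern field. Coordinates (typically degrees of
# longitude/latitude) are treated as planar Euclidean throughout, matching
# the scale on which the spatial range is reported.

## ---- low-level Delaunay machinery -----------------------------------------

# circumcircle of triangle (p1, p2, p3): returns c(cx, cy, r^2)
.circum <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < .Machine$double.xmin) return(c(NA_real_, NA_real_, Inf))
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
}

# Incremental Bowyer-Watson triangulation kept in an environment so that
# refinement can insert vertices without re-triangulating from scratch.
.bw_init <- function(pts) {
  env <- new.env(parent = emptyenv())
  rng <- apply(pts, 2, range)
  ctr <- colMeans(rng)
  span <- max(rng[2, ] - rng[1, ], 1e-9)
  m <- 64 * span
  super <- rbind(ctr + c(-m, -m), ctr + c(m, -m), ctr + c(0, 1.5 * m))
  env$P <- super                       # grows; rows 1:3 are super vertices
  env$tri <- matrix(c(1L, 2L, 3L), 1L, 3L)
  env$cc <- matrix(.circum(super[1, ], super[2, ], super[3, ]), 1L, 3L)
  for (i in seq_len(nrow(pts))) .bw_insert(env, pts[i, ])
  env
}

.bw_insert <- function(env, p) {
  env$P <- rbind(env$P, p)
  ip <- nrow(env$P)
  cc <- env$cc
  bad <- which((p[1] - cc[, 1])^2 + (p[2] - cc[, 2])^2 <= cc[, 3] * (1 + 1e-12))
  if (!length(bad)) { # duplicate/outside pathological; retry with loose tol
    bad <- which((p[1] - cc[, 1])^2 + (p[2] - cc[, 2])^2 <= cc[, 3] * (1 + 1e-7))
    if (!length(bad)) stop("triangulation insertion failed (point outside super-triangle?)")
  }
  bt <- env$tri[bad, , drop = FALSE]
  ed <- rbind(bt[, c(1L, 2L)], bt[, c(2L, 3L)], bt[, c(3L, 1L)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  boundary <- ed[!(key %in% key[duplicated(key)]), , drop = FALSE]
  env$tri <- env$tri[-bad, , drop = FALSE]
  env$cc <- env$cc[-bad, , drop = FALSE]
  newt <- cbind(boundary, ip)
  newcc <- t(apply(newt, 1L, function(tr)
    .circum(env$P[tr[1], ], env$P[tr[2], ], env$P[tr[3], ])))
  env$tri <- rbind(env$tri, newt)
  env$cc <- rbind(env$cc, newcc)
  invisible(ip)
}

# triangles not touching the super vertices, reindexed to data vertices
.bw_extract <- function(env) {
  keep <- rowSums(env$tri <= 3L) == 0L
  tri <- env$tri[keep, , drop = FALSE] - 3L
  P <- env$P[-(1:3), , drop = FALSE]
  # drop numerically degenerate slivers
  if (nrow(tri)) {
    a <- .tri_areas(P, tri)
    tri <- tri[a > 1e-12 * max(a), , drop = FALSE]
  }
  list(loc = P, tri = tri)
}

.tri_areas <- function(P, tri) {
  x1 <- P[tri[, 1], 1]; y1 <- P[tri[, 1], 2]
  x2 <- P[tri[, 2], 1]; y2 <- P[tri[, 2], 2]
  x3 <- P[tri[, 3], 1]; y3 <- P[tri[, 3], 2]
  0.5 * abs((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
}

# unique undirected edges (two-column index matrix)
.mesh_edges <- function(tri) {
  ed <- rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(3L, 1L)])
  ed <- cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  ed[!duplicated(paste(ed[, 1], ed[, 2])), , drop = FALSE]
}

.edge_lengths <- function(P, ed) {
  sqrt((P[ed[, 1], 1] - P[ed[, 2], 1])^2 + (P[ed[, 1], 2] - P[ed[, 2], 2])^2)
}

.min_angles <- function(P, tri) {
  a <- .edge_len3(P, tri)
  # law of cosines per corner, vectorised over triangles
  ang <- function(o, s1, s2) acos(pmin(1, pmax(-1, (s1^2 + s2^2 - o^2) / (2 * s1 * s2))))
  pmin(ang(a[, 1], a[, 2], a[, 3]), ang(a[, 2], a[, 1], a[, 3]),
       ang(a[, 3], a[, 1], a[, 2])) * 180 / pi
}

.edge_len3 <- function(P, tri) {
  d <- function(i, j) sqrt(rowSums((P[tri[, i], , drop = FALSE] -
                                    P[tri[, j], , drop = FALSE])^2))
  cbind(d(2, 3), d(1, 3), d(1, 2))  # edge opposite vertex 1, 2, 3
}

## ---- cutoff merging and hull extension ------------------------------------

# Greedy clustering: points within `cutoff` of an existing cluster seed join
# it (ties broken by input order); each cluster is represented by its centroid.
.cutoff_merge <- function(loc, cutoff) {
  n <- nrow(loc)
  assign <- integer(n)
  seeds <- matrix(0, 0, 2)
  for (i in seq_len(n)) {
    if (nrow(seeds)) {
      d2 <- (seeds[, 1] - loc[i, 1])^2 + (seeds[, 2] - loc[i, 2])^2
      j <- which(d2 <= cutoff^2)
      if (length(j)) { assign[i] <- j[1]; next }
    }
    seeds <- rbind(seeds, loc[i, ])
    assign[i] <- nrow(seeds)
  }
  cent <- matrix(0, nrow(seeds), 2)
  for (k in seq_len(nrow(seeds)))
    cent[k, ] <- colMeans(loc[assign == k, , drop = FALSE])
  list(centroids = cent, assign = assign)
}

# Coarse ring of vertices offset outward from the convex hull of `loc`,
# damping boundary effects of the SPDE discretisation.
.extension_ring <- function(loc, offset, spacing) {
  hull <- grDevices::chull(loc)
  hp <- loc[hull, , drop = FALSE]
  ctr <- colMeans(hp)
  dir <- sweep(hp, 2, ctr)
  len <- sqrt(rowSums(dir^2))
  len[len < 1e-12] <- 1
  ring <- hp + dir / len * offset
  # resample the offset polygon at roughly `spacing` intervals
  out <- matrix(0, 0, 2)
  m <- nrow(ring)
  for (i in seq_len(m)) {
    a <- ring[i, ]; b <- ring[if (i == m) 1L else i + 1L, ]
    seg <- sqrt(sum((b - a)^2))
    k <- max(1L, ceiling(seg / spacing))
    tt <- (seq_len(k) - 1L) / k
    out <- rbind(out, cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2])))
  }
  # small deterministic perturbation breaks collinear/cocircular degeneracy
  # among resampled ring points (prevents boundary slivers)
  eps <- offset * 0.02
  out[, 1] <- out[, 1] + eps * sin(seq_len(nrow(out)) * 2.399963)
  out[, 2] <- out[, 2] + eps * cos(seq_len(nrow(out)) * 2.399963)
  out
}

## ---- public surface --------------------------------------------------------

#' Build a triangulated mesh over survey locations
#'
#' Triangulates the data locations (after merging points closer than
#' \code{cutoff}) together with a coarse extension ring outside their convex
#' hull, then refines by longest-edge bisection until no edge exceeds
#' \code{max_edge}. The result carries the piecewise-linear basis of the SPDE
#' finite-element discretisation: one basis function per vertex, equal to 1
#' at that vertex and 0 at all others.
#'
#' @param locations two-column matrix (or data frame) of planar coordinates.
#' @param max_edge maximum allowed triangle edge length (same units as the
#'   coordinates; degrees for lon/lat input).
#' @param cutoff minimum separation: input points closer than this are merged
#'   to a single vertex (cluster centroid) before triangulation.
#' @param extend_offset distance from the data hull to the extension ring;
#'   default \code{1 * max_edge}.
#' @param ring_spacing spacing of ring vertices; default \code{2 * max_edge}
#'   (the ring is deliberately coarser than the interior).
#' @param min_angle_floor quality floor in degrees (default 0.1); skinny
#'   triangles are split at their circumcenter where possible, boundary
#'   slivers are dropped, and a warning is issued if
#'   any triangle falls below it.
#' @return an object of class \code{gmrfish_mesh} with elements \code{loc}
#'   (vertex coordinates), \code{tri} (triangle vertex indices),
#'   \code{boundary} (logical, vertices on the mesh hull), \code{n},
#'   \code{data_index} (vertex row of each merged data cluster) and
#'   \code{data_assign} (cluster id of each input location).
#' @export
build_mesh <- function(locations, max_edge, cutoff = max_edge / 5,
                       extend_offset = max_edge, ring_spacing = 2 * max_edge,
                       min_angle_floor = 0.1) {
  loc <- as.matrix(locations)
  if (ncol(loc) != 2 || !is.numeric(loc) || any(!is.finite(loc)))
    stop("locations must be a numeric two-column matrix of finite coordinates")
  if (!(is.finite(max_edge) && is.finite(cutoff) && max_edge > cutoff && cutoff > 0))
    stop("require max_edge > cutoff > 0")
  mg <- .cutoff_merge(loc, cutoff)
  pts <- mg$centroids
  if (nrow(pts) < 3)
    stop("degenerate domain: fewer than 3 distinct locations after cutoff merging")
  sv <- svd(sweep(pts, 2, colMeans(pts)))$d
  if (sv[2] < 1e-10 * max(sv[1], 1))
    stop("degenerate domain: input locations are collinear")
  ring <- .extension_ring(pts, extend_offset, ring_spacing)
  env <- .bw_init(rbind(pts, ring))
  n_data <- nrow(pts)

  # refinement: bisect edges longer than max_edge (longest first), then
  # split skinny triangles at their circumcenter (only when it lies safely
  # inside the hull), iterating until both criteria settle
  refine_edges <- function() {
    for (pass in 1:60) {
      ex <- .bw_extract(env)
      ed <- .mesh_edges(ex$tri)
      el <- .edge_lengths(ex$loc, ed)
      long <- which(el > max_edge)
      if (!length(long)) break
      if (nrow(env$P) > 25000L)
        stop("mesh refinement exceeded vertex budget; increase max_edge")
      long <- long[order(el[long], decreasing = TRUE)]
      for (e in long)
        .bw_insert(env, (ex$loc[ed[e, 1], ] + ex$loc[ed[e, 2], ]) / 2)
    }
  }
  refine_edges()
  for (round in 1:6) {
    ex <- .bw_extract(env)
    ang <- .min_angles(ex$loc, ex$tri)
    bad <- which(ang < max(min_angle_floor, 1))
    if (!length(bad) || nrow(env$P) > 25000L) break
    hull <- ex$loc[grDevices::chull(ex$loc), , drop = FALSE]
    inserted <- 0L
    for (k in bad) {
      cc <- .circum(ex$loc[ex$tri[k, 1], ], ex$loc[ex$tri[k, 2], ],
                    ex$loc[ex$tri[k, 3], ])
      if (!is.finite(cc[3])) next
      if (.point_in_polygon(cc[1], cc[2], hull) &&
          .dist_to_ring(cc[1], cc[2], hull) > 0.05 * max_edge) {
        .bw_insert(env, cc[1:2]); inserted <- inserted + 1L
      }
    }
    if (!inserted) break
    refine_edges()
  }
  ex <- .bw_extract(env)
  # boundary slivers (nearly collinear chains along the extension ring) are
  # dropped: the ring is sacrificial padding, so a slightly notched outer
  # boundary is harmless, while near-degenerate elements are not
  ang <- .min_angles(ex$loc, ex$tri)
  hull <- grDevices::chull(ex$loc)
  touches_hull <- rowSums(matrix(ex$tri %in% hull, nrow(ex$tri))) > 0
  keep_tri <- !(ang < 1 & touches_hull)
  tri <- ex$tri[keep_tri, , drop = FALSE]
  used <- sort(unique(as.vector(tri)))
  if (length(used) < nrow(ex$loc)) {
    remap <- integer(nrow(ex$loc)); remap[used] <- seq_along(used)
    if (any(remap[seq_len(n_data)] == 0))
      stop("internal error: sliver removal touched a data vertex")
    tri <- matrix(remap[tri], ncol = 3)
    ex$loc <- ex$loc[used, , drop = FALSE]
  }
  ex$tri <- tri
  hull <- grDevices::chull(ex$loc)
  boundary <- rep(FALSE, nrow(ex$loc))
  boundary[hull] <- TRUE
  mesh <- structure(list(
    loc = unname(ex$loc), tri = unname(ex$tri), boundary = boundary,
    n = nrow(ex$loc), data_index = seq_len(n_data), data_assign = mg$assign,
    max_edge = max_edge, cutoff = cutoff,
    min_angle = if (nrow(ex$tri)) min(.min_angles(ex$loc, ex$tri)) else NA_real_),
    class = "gmrfish_mesh")
  if (is.finite(mesh$min_angle) && mesh$min_angle < min_angle_floor)
    warning(sprintf("mesh contains triangles with interior angle %.2f deg (< floor %g)",
                    mesh$min_angle, min_angle_floor))
  mesh
}

#' @export
print.gmrfish_mesh <- function(x, ...) {
  cat(sprintf("gmrfish mesh: %d vertices, %d triangles, min angle %.1f deg\n",
              x$n, nrow(x$tri), x$min_angle))
  cat(sprintf("  max_edge = %g, cutoff = %g, %d data-derived vertices\n",
              x$max_edge, x$cutoff, length(x$data_index)))
  invisible(x)
}

#' Total area covered by a mesh
#' @param mesh a \code{gmrfish_mesh}.
#' @return sum of triangle areas.
#' @export
mesh_area <- function(mesh) sum(.tri_areas(mesh$loc, mesh$tri))

#' Finite-element mass and stiffness matrices
#'
#' Assembles the lumped (diagonal) mass matrix C and the stiffness matrix G
#' of the piecewise-linear basis. These are the building blocks of the SPDE
#' precision \eqn{Q = \tau^2(\kappa^4 C + 2\kappa^2 G + G C^{-1} G)}.
#' The mass matrix is lumped so that \eqn{G C^{-1} G} stays sparse.
#'
#' @param mesh a \code{gmrfish_mesh}.
#' @return list of class \code{gmrfish_fem} with sparse symmetric \code{c0}
#'   (diagonal mass) and \code{g1} (stiffness), each n x n.
#' @export
fem_matrices <- function(mesh) {
  P <- mesh$loc; tri <- mesh$tri
  areas <- .tri_areas(P, tri)
  if (any(areas <= 0) || any(areas < 1e-14 * max(areas)))
    stop("singular element: mesh contains a (near) zero-area triangle")
  n <- mesh$n
  x <- matrix(P[tri, 1], ncol = 3); y <- matrix(P[tri, 2], ncol = 3)
  # gradients of the three barycentric coordinates on each triangle
  b <- cbind(y[, 2] - y[, 3], y[, 3] - y[, 1], y[, 1] - y[, 2]) / (2 * areas)
  cg <- cbind(x[, 3] - x[, 2], x[, 1] - x[, 3], x[, 2] - x[, 1]) / (2 * areas)
  idx <- expand.grid(a = 1:3, b = 1:3)
  ii <- as.vector(tri[, idx$a]); jj <- as.vector(tri[, idx$b])
  xx <- as.vector(vapply(seq_len(9), function(k)
    areas * (b[, idx$a[k]] * b[, idx$b[k]] + cg[, idx$a[k]] * cg[, idx$b[k]]),
    numeric(nrow(tri))))
  cdiag <- as.vector(Matrix::sparseMatrix(i = as.vector(tri),
                                          j = rep(1L, 3L * nrow(tri)),
                                          x = rep(areas / 3, 3), dims = c(n, 1)))
  g1 <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  g1 <- methods::as(Matrix::forceSymmetric((g1 + Matrix::t(g1)) / 2), "CsparseMatrix")
  structure(list(c0 = Matrix::Diagonal(n, cdiag), g1 = g1, n = n),
            class = "gmrfish_fem")
}

#' Projection (interpolation) matrix from mesh vertices to locations
#'
#' Row i holds the barycentric coordinates of location i in its containing
#' triangle, so \code{A \%*\% weights} evaluates the piecewise-linear field at
#' the locations. Rows for locations outside the triangulation are zero and
#' flagged (error unless \code{allow_outside}).
#'
#' @param mesh a \code{gmrfish_mesh}.
#' @param locations two-column coordinate matrix.
#' @param allow_outside if TRUE, out-of-domain rows are zeroed and recorded in
#'   the \code{outside} attribute instead of raising an error.
#' @return sparse matrix (length(locations) x mesh$n) with attribute
#'   \code{outside} (integer row indices).
#' @export
projection_matrix <- function(mesh, locations, allow_outside = FALSE) {
  loc <- as.matrix(locations)
  if (any(!is.finite(loc))) stop("locations must be finite")
  P <- mesh$loc; tri <- mesh$tri
  # precompute barycentric transforms per triangle
  x1 <- P[tri[, 1], 1]; y1 <- P[tri[, 1], 2]
  x2 <- P[tri[, 2], 1]; y2 <- P[tri[, 2], 2]
  x3 <- P[tri[, 3], 1]; y3 <- P[tri[, 3], 2]
  det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
  m <- nrow(loc)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  outside <- integer(0)
  tol <- -1e-9
  for (i in seq_len(m)) {
    px <- loc[i, 1]; py <- loc[i, 2]
    l1 <- ((y2 - y3) * (px - x3) + (x3 - x2) * (py - y3)) / det
    l2 <- ((y3 - y1) * (px - x3) + (x1 - x3) * (py - y3)) / det
    l3 <- 1 - l1 - l2
    k <- which(l1 >= tol & l2 >= tol & l3 >= tol)
    if (!length(k)) { outside <- c(outside, i); next }
    k <- k[1]
    w <- pmax(c(l1[k], l2[k], l3[k]), 0)
    w <- w / sum(w)
    ii <- c(ii, rep(i, 3L)); jj <- c(jj, tri[k, ]); xx <- c(xx, w)
  }
  if (length(outside) && !allow_outside)
    stop("locations outside the triangulation at rows: ",
         paste(utils::head(outside, 20), collapse = ", "))
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(m, mesh$n))
  attr(A, "outside") <- outside
  A
}

#' Serialise a mesh to JSON (plain text)
#' @param mesh a \code{gmrfish_mesh}.
#' @param path output file path.
#' @export
write_mesh_json <- function(mesh, path) {
  obj <- list(vertices = mesh$loc, triangles = mesh$tri,
              boundary = mesh$boundary, data_index = mesh$data_index,
              max_edge = mesh$max_edge, cutoff = mesh$cutoff)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a mesh serialised by \code{write_mesh_json}
#' @param path JSON file path.
#' @return a \code{gmrfish_mesh}.
#' @export
read_mesh_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  loc <- matrix(as.numeric(obj$vertices), ncol = 2)
  tri <- matrix(as.integer(obj$triangles), ncol = 3)
  structure(list(loc = loc, tri = tri, boundary = as.logical(obj$boundary),
                 n = nrow(loc), data_index = as.integer(obj$data_index),
                 data_assign = NULL, max_edge = obj$max_edge,
                 cutoff = obj$cutoff,
                 min_angle = min(.min_angles(loc, tri))),
            class = "gmrfish_mesh")
}
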