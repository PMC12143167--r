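# Structured polar triangulation of the three-region disc.
#
# Nodes sit on concentric rings; the two material interfaces (Rnt, Rvt) are
# exact ring radii so every element lies wholly inside one region. Adjacent
# rings are stitched by an angular zig-zag merge that tolerates different
# node counts per ring. Radial spacing can be graded toward the material
# interfaces (where the pressure has boundary layers) while keeping every
# edge below the requested maximum length.

.spacing_fun <- function(h, interfaces, gmin, Lg) {
  function(r) {
    if (length(interfaces) == 0) return(rep(h, length(r)))
    d <- do.call(pmin, lapply(interfaces, function(ri) abs(r - ri)))
    h * pmin(1, pmax(gmin, d / Lg))
  }
}

# nodes in [ra, rb] equidistributed under density 1/s(r)
.radial_nodes <- function(ra, rb, s) {
  xs <- seq(ra, rb, length.out = 2001)
  w <- 1 / s(xs)
  cum <- c(0, cumsum((w[-1] + w[-length(w)]) / 2 * diff(xs)))
  n <- max(2L, ceiling(cum[length(cum)]))
  stats::approx(cum, xs, xout = seq(0, cum[length(cum)], length.out = n + 1))$y
}

# stitch two concentric rings of node ids (CCW ordered) into triangles
.merge_rings <- function(idxA, angA, idxB, angB) {
  nA <- length(idxA); nB <- length(idxB)
  shift <- which.min((angB - angA[1]) %% (2 * pi))
  ordB <- c(shift:nB, if (shift > 1) 1:(shift - 1))
  idxB <- idxB[ordB]
  angB <- angA[1] + ((angB[ordB] - angA[1]) %% (2 * pi))
  aAng <- c(angA, angA[1] + 2 * pi); bAng <- c(angB, angB[1] + 2 * pi)
  aI <- c(idxA, idxA[1]); bI <- c(idxB, idxB[1])
  tri <- matrix(0L, nA + nB, 3)
  ia <- 1L; ib <- 1L; k <- 0L
  while (ia <= nA || ib <= nB) {
    k <- k + 1L
    if (ib > nB || (ia <= nA && aAng[ia + 1L] <= bAng[ib + 1L])) {
      tri[k, ] <- c(aI[ia], aI[ia + 1L], bI[ib]); ia <- ia + 1L
    } else {
      tri[k, ] <- c(aI[ia], bI[ib + 1L], bI[ib]); ib <- ib + 1L
    }
  }
  tri
}

#' Build a triangulated disc mesh of the three-region tumor
#'
#' Deterministic structured polar triangulation: concentric node rings with
#' the necrotic/viable and viable/healthy interfaces resolved as exact ring
#' radii, stitched ring-to-ring into triangles. Every edge is at most
#' `h_max`; radial spacing is optionally graded finer toward the two
#' material interfaces where the pressure develops boundary layers.
#'
#' @param geom A [tumor_geometry()].
#' @param h_max Maximum element edge length [cm].
#' @param order Element order: 1 (linear, 3 nodes) or 2 (quadratic, 6 nodes
#'   with mid-edge nodes at edge midpoints).
#' @param grade_interfaces Refine radially toward `Rnt` and `Rvt`.
#' @param gmin Minimum grading factor (local spacing `>= gmin * h_max`).
#' @param Lg Grading length scale [cm].
#' @return Object of class `tumor_mesh`: `nodes` (N x 2, cm), `elements`
#'   (nel x 3 or nel x 6 node indices, corners counter-clockwise),
#'   `region` (per-element factor: necrotic/viable/healthy),
#'   `boundary_edges` (outer boundary node pairs), plus bookkeeping.
#' @export
build_disc_mesh <- function(geom, h_max = 0.03, order = 2,
                            grade_interfaces = TRUE, gmin = 1 / 3, Lg = 0.1) {
  stopifnot(h_max > 0, order %in% c(1, 2))
  if (h_max >= geom$Rnt)
    stop("h_max must be smaller than the necrotic radius to resolve the interface")
  interf <- if (grade_interfaces) c(geom$Rnt, geom$Rvt) else numeric(0)
  s <- .spacing_fun(h_max, interf, gmin, Lg)
  radii <- unique(c(
    .radial_nodes(0, geom$Rnt, s),
    .radial_nodes(geom$Rnt, geom$Rvt, s),
    .radial_nodes(geom$Rvt, geom$Rht, s)))
  radii <- radii[radii > 1e-12]
  M <- length(radii)
  nper <- pmax(6L, as.integer(round(2 * pi * radii / s(radii))))
  start <- 1L + c(0L, cumsum(nper))[seq_len(M)] + 1L  # node 1 is the center
  xs <- numeric(1 + sum(nper)); ys <- numeric(1 + sum(nper))
  angs <- vector("list", M)
  for (i in seq_len(M)) {
    th <- 2 * pi * (seq_len(nper[i]) - 1) / nper[i] +
      (i %% 2) * pi / nper[i]
    angs[[i]] <- th
    sel <- start[i]:(start[i] + nper[i] - 1L)
    xs[sel] <- radii[i] * cos(th); ys[sel] <- radii[i] * sin(th)
  }
  # center fan
  ids1 <- start[1]:(start[1] + nper[1] - 1L)
  fan <- cbind(1L, ids1, c(ids1[-1], ids1[1]))
  tris <- list(fan)
  for (i in seq_len(M - 1)) {
    idxA <- start[i]:(start[i] + nper[i] - 1L)
    idxB <- start[i + 1]:(start[i + 1] + nper[i + 1] - 1L)
    tris[[i + 1]] <- .merge_rings(idxA, angs[[i]], idxB, angs[[i + 1]])
  }
  elem <- do.call(rbind, tris)
  # enforce counter-clockwise orientation
  x1 <- xs[elem[, 1]]; y1 <- ys[elem[, 1]]
  sgn <- (xs[elem[, 2]] - x1) * (ys[elem[, 3]] - y1) -
         (xs[elem[, 3]] - x1) * (ys[elem[, 2]] - y1)
  flip <- sgn < 0
  if (any(flip)) elem[flip, 2:3] <- elem[flip, 3:2]
  # region tags from centroid radius, half-open bins [0,Rnt) [Rnt,Rvt) [Rvt,Rht]
  rc <- sqrt(((xs[elem[, 1]] + xs[elem[, 2]] + xs[elem[, 3]]) / 3)^2 +
             ((ys[elem[, 1]] + ys[elem[, 2]] + ys[elem[, 3]]) / 3)^2)
  region <- factor(c("necrotic", "viable", "healthy")[
    findInterval(rc, c(geom$Rnt, geom$Rvt)) + 1L],
    levels = c("necrotic", "viable", "healthy"))
  idxO <- start[M]:(start[M] + nper[M] - 1L)
  boundary_edges <- cbind(idxO, c(idxO[-1], idxO[1]))
  mesh <- structure(list(
    nodes = cbind(x = xs, y = ys), elements = elem, region = region,
    boundary_edges = boundary_edges, h_max = h_max, order = 1L,
    geometry = geom, ring_radii = radii, n_corner = length(xs)),
    class = "tumor_mesh")
  if (order == 2) mesh <- .to_quadratic(mesh)
  mesh
}

# add mid-edge nodes, turning 3-node triangles into 6-node ones
.to_quadratic <- function(mesh) {
  elem <- mesh$elements[, 1:3, drop = FALSE]
  n <- nrow(mesh$nodes)
  e1 <- rbind(elem[, c(1, 2)], elem[, c(2, 3)], elem[, c(3, 1)])
  key <- pmin(e1[, 1], e1[, 2]) * (n + 1) + pmax(e1[, 1], e1[, 2])
  ukey <- unique(key)
  mid_id <- n + match(key, ukey)
  i1 <- as.integer(ukey %/% (n + 1)); i2 <- as.integer(ukey %% (n + 1))
  mids <- (mesh$nodes[i1, , drop = FALSE] + mesh$nodes[i2, , drop = FALSE]) / 2
  nel <- nrow(elem)
  mesh$nodes <- rbind(mesh$nodes, mids)
  mesh$elements <- cbind(elem, matrix(mid_id, nel, 3))
  # boundary edge midpoints
  bk <- pmin(mesh$boundary_edges[, 1], mesh$boundary_edges[, 2]) * (n + 1) +
        pmax(mesh$boundary_edges[, 1], mesh$boundary_edges[, 2])
  mesh$boundary_mid <- n + match(bk, ukey)
  mesh$order <- 2L
  mesh
}

#' Table of successively refined meshes
#'
#' The standard refinement ladder of maximum edge lengths
#' 0.2, 0.1, 0.05, 0.03, 0.01 cm (test cases 1-5); the default working mesh
#' is case 4 (`h_max = 0.03`).
#'
#' @param geom A [tumor_geometry()].
#' @param order Element order.
#' @param h Edge lengths of the ladder.
#' @param ... Passed to [build_disc_mesh()].
#' @return Named list of `tumor_mesh` objects (`h0.2`, ...).
#' @export
refinement_ladder <- function(geom = tumor_geometry(), order = 2,
                              h = c(0.2, 0.1, 0.05, 0.03, 0.01), ...) {
  out <- lapply(h, function(hh) build_disc_mesh(geom, hh, order = order, ...))
  names(out) <- paste0("h", h)
  out
}

#' Signed areas of the (corner) triangles
#' @param mesh A `tumor_mesh`.
#' @return Numeric vector of element areas [cm^2]; positive when
#'   counter-clockwise.
#' @export
element_areas <- function(mesh) {
  el <- mesh$elements; x <- mesh$nodes[, 1]; y <- mesh$nodes[, 2]
  ((x[el[, 2]] - x[el[, 1]]) * (y[el[, 3]] - y[el[, 1]]) -
   (x[el[, 3]] - x[el[, 1]]) * (y[el[, 2]] - y[el[, 1]])) / 2
}

#' Minimum interior angle of the mesh [degrees]
#' @param mesh A `tumor_mesh`.
#' @return Smallest corner angle over all elements.
#' @export
mesh_min_angle <- function(mesh) {
  el <- mesh$elements[, 1:3, drop = FALSE]
  p <- mesh$nodes
  ang <- function(a, b, c) {
    u <- p[b, , drop = FALSE] - p[a, , drop = FALSE]
    v <- p[c, , drop = FALSE] - p[a, , drop = FALSE]
    acos(pmin(1, pmax(-1, rowSums(u * v) /
      sqrt(rowSums(u^2) * rowSums(v^2)))))
  }
  min(ang(el[, 1], el[, 2], el[, 3]), ang(el[, 2], el[, 3], el[, 1]),
      ang(el[, 3], el[, 1], el[, 2])) * 180 / pi
}

#' Rotate a mesh about the tumor center
#' @param mesh A `tumor_mesh`.
#' @param angle Rotation angle [radians].
#' @return The rotated mesh (connectivity and tags unchanged).
#' @export
rotate_mesh <- function(mesh, angle) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  mesh$nodes <- mesh$nodes %*% R
  colnames(mesh$nodes) <- c("x", "y")
  mesh
}

#' @export
print.tumor_mesh <- function(x, ...) {
  cat(sprintf(
    "Triangular disc mesh: %d nodes, %d elements (order %d), h_max = %g cm\n",
    nrow(x$nodes), nrow(x$elements), x$order, x$h_max))
  print(table(x$region))
  invisible(x)
}

# locate query points in the mesh; returns element index and barycentric
# coordinates with respect to the corner nodes
.locate_points <- function(mesh, px, py) {
  el <- mesh$elements; x <- mesh$nodes[, 1]; y <- mesh$nodes[, 2]
  cx <- (x[el[, 1]] + x[el[, 2]] + x[el[, 3]]) / 3
  cy <- (y[el[, 1]] + y[el[, 2]] + y[el[, 3]]) / 3
  crad <- sqrt(cx^2 + cy^2)
  hreach <- 2.5 * mesh$h_max
  n <- length(px)
  eid <- integer(n); bary <- matrix(NA_real_, n, 3)
  prad <- sqrt(px^2 + py^2)
  for (q in seq_len(n)) {
    cand <- which(abs(crad - prad[q]) < hreach)
    cand <- cand[(cx[cand] - px[q])^2 + (cy[cand] - py[q])^2 < hreach^2]
    if (length(cand) == 0) cand <- seq_len(nrow(el))
    x1 <- x[el[cand, 1]]; y1 <- y[el[cand, 1]]
    x2 <- x[el[cand, 2]]; y2 <- y[el[cand, 2]]
    x3 <- x[el[cand, 3]]; y3 <- y[el[cand, 3]]
    det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
    l2 <- ((px[q] - x1) * (y3 - y1) - (py[q] - y1) * (x3 - x1)) / det
    l3 <- ((x2 - x1) * (py[q] - y1) - (y2 - y1) * (px[q] - x1)) / det
    l1 <- 1 - l2 - l3
    tol <- -1e-9
    ok <- which(l1 >= tol & l2 >= tol & l3 >= tol)
    if (length(ok) == 0) ok <- which.max(pmin(l1, l2, l3))
    j <- ok[1]
    eid[q] <- cand[j]; bary[q, ] <- c(l1[j], l2[j], l3[j])
  }
  list(element = eid, bary = bary)
}

#' Interpolate a nodal field at arbitrary points
#'
#' Element-local interpolation (linear or quadratic, matching the mesh
#' order) of a nodal field.
#'
#' @param mesh A `tumor_mesh`.
#' @param values Nodal values (length = number of nodes).
#' @param px,py Query coordinates [cm].
#' @return Interpolated values.
#' @export
interp_field <- function(mesh, values, px, py) {
  loc <- .locate_points(mesh, px, py)
  el <- mesh$elements
  L <- loc$bary
  if (mesh$order == 1L) {
    v <- values[el[loc$element, 1]] * L[, 1] +
         values[el[loc$element, 2]] * L[, 2] +
         values[el[loc$element, 3]] * L[, 3]
  } else {
    N <- cbind(L[, 1] * (2 * L[, 1] - 1), L[, 2] * (2 * L[, 2] - 1),
               L[, 3] * (2 * L[, 3] - 1), 4 * L[, 1] * L[, 2],
               4 * L[, 2] * L[, 3], 4 * L[, 3] * L[, 1])
    v <- rowSums(N * matrix(values[el[loc$element, ]], nrow = length(px)))
  }
  v
}
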