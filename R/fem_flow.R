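# Galerkin FEM for the steady pressure equation on triangular meshes.
#
# Conservative weak form: find P with
#   int K grad P . grad u  +  int sigma P u  =  int sigma PSS u
# for all test functions u, where sigma = Lp S/V + L_PL S_L/V is the total
# filtration conductance (region-wise constant; zero in the necrotic core)
# and K the region hydraulic conductivity. The natural interface condition
# is continuity of the Darcy flux K dP/dn. The pure-Neumann problem is
# well posed because sigma > 0 in the viable and healthy regions.

# quadrature + reference shape functions for linear / quadratic triangles
.fe_rule <- function(order) {
  if (order == 1L) {
    pts <- cbind(c(0.5, 0.5, 0), c(0, 0.5, 0.5))  # edge midpoints, degree 2
    w <- rep(1 / 3, 3)
  } else {
    a1 <- 0.059715871789770; b1 <- 0.470142064105115
    a2 <- 0.797426985353087; b2 <- 0.101286507323456
    pts <- rbind(c(1 / 3, 1 / 3),
                 c(a1, b1), c(b1, a1), c(b1, b1),
                 c(a2, b2), c(b2, a2), c(b2, b2))
    w <- c(0.225, rep(0.132394152788506, 3), rep(0.125939180544827, 3))
  }
  xi <- pts[, 1]; eta <- pts[, 2]; L1 <- 1 - xi - eta
  if (order == 1L) {
    N <- cbind(L1, xi, eta)
    gx <- matrix(rep(c(-1, 1, 0), each = length(w)), ncol = 3)
    gy <- matrix(rep(c(-1, 0, 1), each = length(w)), ncol = 3)
  } else {
    N <- cbind(L1 * (2 * L1 - 1), xi * (2 * xi - 1), eta * (2 * eta - 1),
               4 * L1 * xi, 4 * xi * eta, 4 * eta * L1)
    gx <- cbind(-(4 * L1 - 1), 4 * xi - 1, 0, 4 * (L1 - xi), 4 * eta, -4 * eta)
    gy <- cbind(-(4 * L1 - 1), 0, 4 * eta - 1, -4 * xi, 4 * xi, 4 * (L1 - eta))
  }
  nd <- ncol(N)
  GXX <- t(gx) %*% (w * gx); GYY <- t(gy) %*% (w * gy)
  GXY <- t(gx) %*% (w * gy)
  Mref <- t(N) %*% (w * N) / 2
  list(w = w, pts = pts, N = N, gx = gx, gy = gy, ndof = nd,
       GXX = GXX, GYY = GYY, GXY = GXY, Mref = Mref)
}

# per-mesh geometric factors for affine elements
.fe_context <- function(mesh) {
  rule <- .fe_rule(mesh$order)
  el <- mesh$elements
  x <- mesh$nodes[, 1]; y <- mesh$nodes[, 2]
  a <- x[el[, 2]] - x[el[, 1]]; b <- x[el[, 3]] - x[el[, 1]]
  cc <- y[el[, 2]] - y[el[, 1]]; d <- y[el[, 3]] - y[el[, 1]]
  det <- a * d - b * cc
  if (any(det <= 0)) stop("inverted element in mesh")
  list(rule = rule, elem = el, nel = nrow(el), nn = nrow(mesh$nodes),
       a = a, b = b, c = cc, d = d, det = det,
       # physical gradient: Nx = ( d*gx - c*gy)/det, Ny = (-b*gx + a*gy)/det
       c11 = (d^2 + b^2) / det^2, c12 = -(cc * d + a * b) / det^2,
       c22 = (a^2 + cc^2) / det^2,
       x1 = x[el[, 1]], y1 = y[el[, 1]])
}

# assemble a sparse matrix from per-element dense blocks
# vals: function(a, b) -> numeric(nel) giving entry (a, b) of each element
.assemble <- function(ctx, vals) {
  nd <- ctx$rule$ndof
  nel <- ctx$nel
  ii <- integer(nel * nd * nd); jj <- integer(nel * nd * nd)
  xx <- numeric(nel * nd * nd)
  k <- 0L
  for (A in seq_len(nd)) for (B in seq_len(nd)) {
    idx <- (k * nel + 1L):((k + 1L) * nel)
    ii[idx] <- ctx$elem[, A]; jj[idx] <- ctx$elem[, B]
    xx[idx] <- vals(A, B)
    k <- k + 1L
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ctx$nn, ctx$nn))
}

# stiffness with per-element coefficient kvec: int k grad N_a . grad N_b
.stiffness <- function(ctx, kvec) {
  r <- ctx$rule
  .assemble(ctx, function(A, B) {
    kvec * ctx$det / 2 *
      (ctx$c11 * r$GXX[A, B] + ctx$c22 * r$GYY[A, B] +
       ctx$c12 * (r$GXY[A, B] + r$GXY[B, A]))
  })
}

# mass with per-element coefficient: int c N_a N_b
.mass <- function(ctx, cvec) {
  r <- ctx$rule
  .assemble(ctx, function(A, B) cvec * ctx$det * r$Mref[A, B])
}

# accumulate per-element nodal contributions into a global vector
.accumulate <- function(ctx, idx, vals) {
  as.vector(Matrix::sparseMatrix(i = idx, j = rep(1L, length(idx)),
                                 x = vals, dims = c(ctx$nn, 1L)))
}

# load vector int c N_a with per-element constant c
.load <- function(ctx, cvec) {
  r <- ctx$rule
  wN <- colSums(r$w * r$N) / 2  # int_ref N_a
  f <- numeric(ctx$nn)
  for (A in seq_len(r$ndof))
    f <- f + .accumulate(ctx, ctx$elem[, A], cvec * ctx$det * wN[A])
  f
}

# evaluate nodal field and its gradient at the quadrature points
# returns list of nq x nel matrices... here: per q, vectors over elements
.field_at_quad <- function(ctx, values) {
  r <- ctx$rule
  nq <- length(r$w)
  vq <- matrix(0, ctx$nel, nq)
  for (q in seq_len(nq))
    for (A in seq_len(r$ndof))
      vq[, q] <- vq[, q] + values[ctx$elem[, A]] * r$N[q, A]
  vq
}

.grad_at_quad <- function(ctx, values) {
  r <- ctx$rule
  nq <- length(r$w)
  gxq <- matrix(0, ctx$nel, nq); gyq <- matrix(0, ctx$nel, nq)
  for (q in seq_len(nq)) for (A in seq_len(r$ndof)) {
    v <- values[ctx$elem[, A]]
    gref_x <- r$gx[q, A]; gref_y <- r$gy[q, A]
    gxq[, q] <- gxq[, q] + v * (ctx$d * gref_x - ctx$c * gref_y) / ctx$det
    gyq[, q] <- gyq[, q] + v * (-ctx$b * gref_x + ctx$a * gref_y) / ctx$det
  }
  list(gx = gxq, gy = gyq)
}

.region_vec <- function(mesh, coeffs, field) {
  v <- vapply(coeffs, function(rc) rc[[field]], numeric(1))
  unname(v[as.integer(mesh$region)])
}

#' Assemble the steady pressure system
#'
#' Builds the sparse symmetric positive-definite system of the conservative
#' pressure weak form with region-wise constant coefficients. Gaussian
#' quadrature is exact for the element order (3-point for linear, 7-point
#' for quadratic triangles). The pure-Neumann problem needs no pressure
#' pinning: the filtration term anchors the solution.
#'
#' @param mesh A [build_disc_mesh()] mesh.
#' @param coeffs A [region_coefficients()] object.
#' @return List of class `pressure_system` with the matrix `A`, load `b`,
#'   and references to `mesh` and `coeffs`.
#' @export
assemble_pressure_system <- function(mesh, coeffs) {
  if (anyNA(mesh$region)) stop("untagged element in mesh")
  ctx <- .fe_context(mesh)
  kv <- .region_vec(mesh, coeffs, "K")
  sv <- .region_vec(mesh, coeffs, "sigma")
  pss <- .region_vec(mesh, coeffs, "PSS")
  A <- .stiffness(ctx, kv) + .mass(ctx, sv)
  b <- .load(ctx, sv * pss)
  structure(list(A = A, b = b, mesh = mesh, coeffs = coeffs, ctx = ctx),
            class = "pressure_system")
}

#' Solve the assembled pressure system
#'
#' Sparse Cholesky solve of the SPD pressure system; convergence is checked
#' against the residual/absolute/relative tolerances 1e-4 / 1e-6 / 1e-3.
#'
#' @param system A `pressure_system` from [assemble_pressure_system()].
#' @param tol_residual,tol_abs,tol_rel Convergence tolerances.
#' @return Object of class `fem_pressure`: nodal pressure `P` [mmHg], the
#'   `mesh`, `coeffs`, and solver `diagnostics`.
#' @export
solve_pressure <- function(system, tol_residual = 1e-4, tol_abs = 1e-6,
                           tol_rel = 1e-3) {
  A <- system$A
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), perm = TRUE, LDL = FALSE,
                         super = TRUE)
  P <- as.vector(Matrix::solve(ch, system$b))
  res <- as.vector(A %*% P - system$b)
  rn <- sqrt(sum(res^2)); bn <- sqrt(sum(system$b^2))
  if (!(rn <= tol_residual && (rn <= tol_abs || rn / bn <= tol_rel)))
    stop(sprintf("pressure solve did not converge: |r| = %.3g (|r|/|b| = %.3g)",
                 rn, rn / bn))
  structure(list(P = P, mesh = system$mesh, coeffs = system$coeffs,
                 ctx = system$ctx,
                 diagnostics = list(residual_norm = rn,
                                    relative_residual = rn / bn,
                                    n_dof = length(P))),
            class = "fem_pressure")
}

#' Darcy velocity by consistent-mass L2 projection
#'
#' Projects the elementwise Darcy velocity `-K grad P` onto the nodal finite
#' element space using the consistent mass matrix, one solve per component.
#'
#' @param P An `fem_pressure` object.
#' @return Object of class `fem_velocity` with nodal `U`, `V` [cm/s].
#' @export
project_velocity <- function(P) {
  ctx <- P$ctx
  r <- ctx$rule
  kv <- .region_vec(P$mesh, P$coeffs, "K")
  g <- .grad_at_quad(ctx, P$P)
  M <- .mass(ctx, rep(1, ctx$nel))
  rhs_u <- numeric(ctx$nn); rhs_v <- numeric(ctx$nn)
  for (q in seq_along(r$w)) {
    wq <- r$w[q] / 2
    fu <- -kv * g$gx[, q] * ctx$det * wq
    fv <- -kv * g$gy[, q] * ctx$det * wq
    for (A in seq_len(r$ndof)) {
      rhs_u <- rhs_u + .accumulate(ctx, ctx$elem[, A], fu * r$N[q, A])
      rhs_v <- rhs_v + .accumulate(ctx, ctx$elem[, A], fv * r$N[q, A])
    }
  }
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(M), perm = TRUE, LDL = FALSE,
                         super = TRUE)
  U <- as.vector(Matrix::solve(ch, rhs_u))
  V <- as.vector(Matrix::solve(ch, rhs_v))
  structure(list(U = U, V = V, mesh = P$mesh, ctx = ctx, coeffs = P$coeffs),
            class = "fem_velocity")
}

#' @export
print.fem_pressure <- function(x, ...) {
  cat(sprintf("FEM steady pressure: %d dof, P(0,0) = %.4f mmHg, range [%.4f, %.4f]\n",
              length(x$P), x$P[1], min(x$P), max(x$P)))
  invisible(x)
}

#' @export
summary.fem_pressure <- function(object, ...) {
  vel <- project_velocity(object)
  vmag <- sqrt(vel$U^2 + vel$V^2)
  imax <- which.max(vmag)
  rr <- sqrt(rowSums(object$mesh$nodes^2))
  out <- list(P_center = object$P[1], P_min = min(object$P),
              P_max = max(object$P), v_max = vmag[imax],
              r_at_vmax = rr[imax],
              diagnostics = object$diagnostics)
  class(out) <- "summary.fem_pressure"
  out
}

#' @export
print.summary.fem_pressure <- function(x, ...) {
  cat(sprintf("P_center = %.4f mmHg, P_min = %.4f mmHg, max |v| = %.3g cm/s at r = %.3f cm\n",
              x$P_center, x$P_min, x$v_max, x$r_at_vmax))
  invisible(x)
}

#' @export
plot.fem_pressure <- function(x, n = 200, ...) {
  rr <- seq(0, x$mesh$geometry$Rht, length.out = n)
  pp <- interp_field(x$mesh, x$P, rr, rep(0, n))
  graphics::plot(rr, pp, type = "l", xlab = "r [cm]", ylab = "IFP [mmHg]", ...)
  graphics::abline(v = c(x$mesh$geometry$Rnt, x$mesh$geometry$Rvt), lty = 3)
  invisible(x)
}

#' Compare an FEM pressure field with the radial closed form
#'
#' @param fem An `fem_pressure`.
#' @param oracle A `radial_flow` from [solve_radial_pressure()] (use
#'   cylindrical symmetry for the plane-disc FEM).
#' @return List with `linf_rel` (nodal max error / max |oracle|), `l2`
#'   (quadrature L2 norm of the error [mmHg cm]), `l2_rel`.
#' @export
fem_vs_radial <- function(fem, oracle) {
  rr <- sqrt(rowSums(fem$mesh$nodes^2))
  rr <- pmin(rr, fem$mesh$geometry$Rht)
  Po <- predict(oracle, rr)
  linf <- max(abs(fem$P - Po)) / max(abs(Po))
  ctx <- fem$ctx
  r <- ctx$rule
  Pq <- .field_at_quad(ctx, fem$P)
  l2e <- 0; l2o <- 0
  for (q in seq_along(r$w)) {
    xq <- ctx$x1 + ctx$a * r$pts[q, 1] + ctx$b * r$pts[q, 2]
    yq <- ctx$y1 + ctx$c * r$pts[q, 1] + ctx$d * r$pts[q, 2]
    rq <- pmin(sqrt(xq^2 + yq^2), fem$mesh$geometry$Rht)
    Poq <- predict(oracle, rq)
    l2e <- l2e + sum(r$w[q] / 2 * ctx$det * (Pq[, q] - Poq)^2)
    l2o <- l2o + sum(r$w[q] / 2 * ctx$det * Poq^2)
  }
  list(linf_rel = linf, l2 = sqrt(l2e), l2_rel = sqrt(l2e / l2o))
}

#' Global transvascular/lymphatic flux balance
#'
#' Integrates the Starling source and the lymphatic sink of a solved
#' pressure field over the domain. At steady state with a zero-flux outer
#' boundary the two balance.
#'
#' @param fem An `fem_pressure`.
#' @return List with `inflow` (int phi_VS dOmega), `outflow`
#'   (int phi_LS dOmega) [cm^2/s per unit thickness], and `imbalance_rel`.
#' @export
flux_balance <- function(fem) {
  ctx <- fem$ctx
  r <- ctx$rule
  Pq <- .field_at_quad(ctx, fem$P)
  # phiVS = a - b P ; phiLS = a + b P  (per-element linear coefficients)
  aV <- vapply(fem$coeffs, function(rc) rc$phiVS_linear["a"], numeric(1))[
    as.integer(fem$mesh$region)]
  bV <- vapply(fem$coeffs, function(rc) rc$phiVS_linear["b"], numeric(1))[
    as.integer(fem$mesh$region)]
  aL <- vapply(fem$coeffs, function(rc) rc$phiLS_linear["a"], numeric(1))[
    as.integer(fem$mesh$region)]
  bL <- vapply(fem$coeffs, function(rc) rc$phiLS_linear["b"], numeric(1))[
    as.integer(fem$mesh$region)]
  qin <- 0; qout <- 0
  for (q in seq_along(r$w)) {
    wdet <- r$w[q] / 2 * ctx$det
    qin <- qin + sum(wdet * (aV - bV * Pq[, q]))
    qout <- qout + sum(wdet * (aL + bL * Pq[, q]))
  }
  list(inflow = qin, outflow = qout,
       imbalance_rel = abs(qin - qout) / max(abs(qin), abs(qout)))
}
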