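# Closed-form piecewise radial solution of the steady pressure problem.
#
# In each region the pressure obeys P'' + (nu/r) P' = beta^2 (P - PSS).
# Homogeneous solutions: spherical (nu = 2) {sinh(beta r)/r, cosh(beta r)/r},
# cylindrical (nu = 1) modified Bessel {I0(beta r), K0(beta r)}; a beta = 0
# region is Laplace's equation ({1, 1/r} or {1, log r}). To stay finite at
# beta*r ~ 40 the basis is scaled by exponentials anchored at the region's
# own radii, so every basis value is O(1) inside its region.

.radial_basis <- function(K, beta2, r0, r1, nu, innermost) {
  beta <- sqrt(beta2)
  if (beta2 == 0) {
    if (innermost) {
      f  <- function(r) cbind(rep(1, length(r)), rep(0, length(r)))
      fp <- function(r) cbind(rep(0, length(r)), rep(0, length(r)))
    } else if (nu == 2) {
      f  <- function(r) cbind(rep(1, length(r)), 1 / r)
      fp <- function(r) cbind(rep(0, length(r)), -1 / r^2)
    } else {
      f  <- function(r) cbind(rep(1, length(r)), log(r))
      fp <- function(r) cbind(rep(0, length(r)), 1 / r)
    }
    return(list(f = f, fp = fp))
  }
  if (nu == 2) {
    if (innermost) {
      # sinh(beta r)/(beta r) scaled by exp(-beta r1); value 1e-18..1 in region
      f <- function(r) {
        v1 <- ifelse(r == 0, exp(-beta * r1),
                     (exp(beta * (r - r1)) - exp(-beta * (r + r1))) / (2 * beta * r))
        cbind(v1, rep(0, length(r)))
      }
      fp <- function(r) {
        v1 <- ifelse(r == 0, 0,
          (exp(beta * (r - r1)) * (beta * r - 1) +
           exp(-beta * (r + r1)) * (beta * r + 1)) / (2 * beta * r^2))
        cbind(v1, rep(0, length(r)))
      }
    } else {
      f <- function(r) cbind(exp(beta * (r - r1)) / r,
                             exp(-beta * (r - r0)) / r)
      fp <- function(r) cbind(exp(beta * (r - r1)) * (beta * r - 1) / r^2,
                              -exp(-beta * (r - r0)) * (beta * r + 1) / r^2)
    }
  } else {
    if (innermost) {
      f <- function(r) cbind(besselI(beta * r, 0, expon.scaled = TRUE) *
                               exp(beta * (r - r1)), rep(0, length(r)))
      fp <- function(r) cbind(beta * besselI(beta * r, 1, expon.scaled = TRUE) *
                                exp(beta * (r - r1)), rep(0, length(r)))
    } else {
      f <- function(r) cbind(
        besselI(beta * r, 0, expon.scaled = TRUE) * exp(beta * (r - r1)),
        besselK(beta * r, 0, expon.scaled = TRUE) * exp(-beta * (r - r0)))
      fp <- function(r) cbind(
        beta * besselI(beta * r, 1, expon.scaled = TRUE) * exp(beta * (r - r1)),
        -beta * besselK(beta * r, 1, expon.scaled = TRUE) * exp(-beta * (r - r0)))
    }
  }
  list(f = f, fp = fp)
}

#' Closed-form radial steady pressure solution
#'
#' Solves the piecewise modified-Helmholtz pressure problem on the three
#' concentric regions under radial symmetry, matching pressure and flux
#' `K dP/dr` at the interfaces, with regularity at the center and zero flux
#' at the outer boundary. The default `"cylindrical"` symmetry (`nu = 1`)
#' matches the unweighted plane-disc finite-element formulation; use
#' `"spherical"` (`nu = 2`) for the fully three-dimensional spherical
#' interpretation. The necrotic plateau value is insensitive to the choice.
#'
#' @param geom A [tumor_geometry()].
#' @param coeffs A [region_coefficients()] object (or anything with per-region
#'   `K`, `beta2`, `PSS` in order necrotic, viable, healthy).
#' @param symmetry `"cylindrical"` or `"spherical"`.
#' @return An object of class `radial_flow` with an evaluator for P(r) and
#'   v(r); see [predict.radial_flow()], [center_pressure()],
#'   [radial_velocity()].
#' @export
solve_radial_pressure <- function(geom, coeffs,
                                  symmetry = c("cylindrical", "spherical")) {
  symmetry <- match.arg(symmetry)
  nu <- if (symmetry == "spherical") 2 else 1
  radii <- c(0, geom$Rnt, geom$Rvt, geom$Rht)
  regs <- lapply(seq_along(coeffs), function(i) {
    rc <- coeffs[[i]]
    stopifnot(is.finite(rc$K), is.finite(rc$beta2), is.finite(rc$PSS))
    c(list(r0 = radii[i], r1 = radii[i + 1]), rc,
      .radial_basis(rc$K, rc$beta2, radii[i], radii[i + 1], nu, i == 1))
  })
  m <- length(regs)
  A <- matrix(0, 2 * m, 2 * m)
  rhs <- numeric(2 * m)
  row <- 1
  # regularity at the center: second coefficient of region 1 unused
  A[row, 2] <- 1; row <- row + 1
  for (i in seq_len(m - 1)) {
    ri <- regs[[i]]$r1
    ci <- 2 * i - 1; cj <- 2 * i + 1
    fi <- regs[[i]]$f(ri);  fj <- regs[[i + 1]]$f(ri)
    di <- regs[[i]]$fp(ri); dj <- regs[[i + 1]]$fp(ri)
    # pressure continuity
    A[row, ci:(ci + 1)] <- fi
    A[row, cj:(cj + 1)] <- -fj
    rhs[row] <- regs[[i + 1]]$PSS - regs[[i]]$PSS
    row <- row + 1
    # flux continuity K dP/dr
    A[row, ci:(ci + 1)] <- regs[[i]]$K * di
    A[row, cj:(cj + 1)] <- -regs[[i + 1]]$K * dj
    row <- row + 1
  }
  # outer zero flux
  A[row, (2 * m - 1):(2 * m)] <- regs[[m]]$fp(regs[[m]]$r1)
  coef <- tryCatch(solve(A, rhs), error = function(e)
    stop(sprintf("singular interface matching system (radii %s): %s",
                 paste(signif(radii, 4), collapse = ", "), conditionMessage(e))))
  for (i in seq_len(m)) regs[[i]]$ab <- coef[(2 * i - 1):(2 * i)]
  structure(list(geometry = geom, symmetry = symmetry, nu = nu,
                 regions = regs, coef = coef),
            class = "radial_flow")
}

.radial_region_index <- function(sol, r) {
  brk <- vapply(sol$regions, function(g) g$r1, numeric(1))
  findInterval(r, c(-Inf, brk[-length(brk)]), left.open = TRUE)
}

#' Evaluate a radial pressure solution
#'
#' @param object A `radial_flow` object.
#' @param r Radii [cm] in `[0, Rht]`.
#' @param what `"pressure"` [mmHg], `"velocity"` [cm/s], or `"both"`.
#' @param ... Unused.
#' @return Numeric vector, or data frame for `"both"`.
#' @export
predict.radial_flow <- function(object, r, what = c("pressure", "velocity", "both"),
                                ...) {
  what <- match.arg(what)
  if (any(r < 0 | r > object$geometry$Rht + 1e-12))
    stop("radius outside the domain [0, Rht]")
  idx <- .radial_region_index(object, r)
  P <- numeric(length(r)); v <- numeric(length(r))
  for (i in unique(idx)) {
    sel <- idx == i
    g <- object$regions[[i]]
    P[sel] <- g$PSS + as.vector(g$f(r[sel]) %*% g$ab)
    v[sel] <- -g$K * as.vector(g$fp(r[sel]) %*% g$ab)
  }
  switch(what, pressure = P, velocity = v,
         both = data.frame(r = r, pressure_mmHg = P, velocity_cm_s = v))
}

#' Darcy velocity of a radial solution
#'
#' `v(r) = -K(r) dP/dr`; piecewise smooth, discontinuous only where K jumps.
#'
#' @param sol A `radial_flow` object.
#' @param r Radii [cm].
#' @return Velocity [cm/s].
#' @export
radial_velocity <- function(sol, r) predict(sol, r, what = "velocity")

#' Pressure at the tumor center
#'
#' @param sol A `radial_flow` object.
#' @return P(0), the necrotic plateau pressure [mmHg].
#' @export
center_pressure <- function(sol) predict(sol, 0, what = "pressure")

#' @export
print.radial_flow <- function(x, ...) {
  rr <- seq(0, x$geometry$Rht, by = 1e-3)
  pv <- predict(x, rr, what = "both")
  cat(sprintf("Radial steady pressure solution (%s symmetry)\n", x$symmetry))
  cat(sprintf("  radii: Rnt=%g Rvt=%g Rht=%g cm\n",
              x$geometry$Rnt, x$geometry$Rvt, x$geometry$Rht))
  cat(sprintf("  P(0) = %.4f mmHg (%.1f Pa), min P = %.4f mmHg\n",
              pv$pressure_mmHg[1], pv$pressure_mmHg[1] * MMHG_PA,
              min(pv$pressure_mmHg)))
  imax <- which.max(abs(pv$velocity_cm_s))
  cat(sprintf("  max |v| = %.3g cm/s at r = %.3f cm\n",
              abs(pv$velocity_cm_s[imax]), rr[imax]))
  invisible(x)
}

#' @export
summary.radial_flow <- function(object, dr = 1e-3, ...) {
  rr <- seq(0, object$geometry$Rht, by = dr)
  pv <- predict(object, rr, what = "both")
  imax <- which.max(abs(pv$velocity_cm_s))
  out <- list(center_pressure = pv$pressure_mmHg[1],
              min_pressure = min(pv$pressure_mmHg),
              max_pressure = max(pv$pressure_mmHg),
              max_velocity = abs(pv$velocity_cm_s[imax]),
              argmax_radius = rr[imax])
  class(out) <- "summary.radial_flow"
  out
}

#' @export
print.summary.radial_flow <- function(x, ...) {
  cat(sprintf(paste0("center P = %.4f mmHg, min P = %.4f mmHg, ",
                     "max |v| = %.3g cm/s at r = %.3f cm\n"),
              x$center_pressure, x$min_pressure, x$max_velocity,
              x$argmax_radius))
  invisible(x)
}

#' @export
plot.radial_flow <- function(x, dr = 1e-3, ...) {
  rr <- seq(0, x$geometry$Rht, by = dr)
  pv <- predict(x, rr, what = "both")
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::plot(rr, pv$pressure_mmHg, type = "l", xlab = "r [cm]",
                 ylab = "IFP [mmHg]", ...)
  graphics::abline(v = c(x$geometry$Rnt, x$geometry$Rvt), lty = 3)
  graphics::plot(rr, pv$velocity_cm_s, type = "l", xlab = "r [cm]",
                 ylab = "IFV [cm/s]", ...)
  graphics::abline(v = c(x$geometry$Rnt, x$geometry$Rvt), lty = 3)
  invisible(x)
}

#' Critical necrotic radius
#'
#' Sweeps the necrotic core radius (holding the viable and healthy radii
#' fixed) and returns the largest radius at which the center pressure still
#' sits on its plateau, operationalized as
#' `P(0) >= (1 - criterion) * PEF_viable`.
#'
#' @param geom A [tumor_geometry()] providing `Rvt` and `Rht`.
#' @param coeffs A [region_coefficients()] object.
#' @param criterion Relative plateau-drop tolerance (default 0.01).
#' @param grid Candidate necrotic radii [cm]; default 0.05 to `Rvt - 0.01`
#'   in steps of 0.01.
#' @param symmetry Passed to [solve_radial_pressure()].
#' @return List with `R_CN` [cm], the sweep `table` (Rnt, P0), and
#'   `criterion_met` (FALSE when even the smallest radius fails, in which
#'   case the smallest grid value is returned with a warning).
#' @export
critical_necrotic_radius <- function(geom, coeffs, criterion = 0.01,
                                     grid = NULL,
                                     symmetry = "cylindrical") {
  stopifnot(criterion > 0, criterion < 1)
  if (is.null(grid)) grid <- seq(0.05, geom$Rvt - 0.01, by = 0.01)
  p0 <- vapply(grid, function(rn) {
    g <- tumor_geometry(Rnt = rn, Rvt = geom$Rvt, Rht = geom$Rht)
    center_pressure(solve_radial_pressure(g, coeffs, symmetry))
  }, numeric(1))
  thr <- (1 - criterion) * coeffs$viable$PEF
  ok <- p0 >= thr
  if (!any(ok)) {
    warning("plateau criterion never met; returning smallest grid radius")
    return(list(R_CN = grid[1], table = data.frame(Rnt = grid, P0 = p0),
                criterion_met = FALSE))
  }
  list(R_CN = max(grid[ok]), table = data.frame(Rnt = grid, P0 = p0),
       criterion_met = TRUE)
}
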