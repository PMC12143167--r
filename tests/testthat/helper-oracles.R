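# Independent numerical oracles, deliberately different discretizations from
# the package's solvers.

# Conservative finite-volume radial solve with Richardson extrapolation
# (two grids, effective 4th order). Independent of the closed-form basis
# and of the FEM.
fd_radial_pressure <- function(geom, co, nu = 1, n_per = 800) {
  solve_fv <- function(nref) {
    brks <- c(0, geom$Rnt, geom$Rvt, geom$Rht)
    r <- unique(unlist(lapply(1:3, function(i)
      seq(brks[i], brks[i + 1], length.out = nref + 1))))
    N <- length(r)
    K <- sapply(co, function(rc) rc$K)
    sig <- sapply(co, function(rc) rc$sigma)
    pss <- sapply(co, function(rc) rc$PSS)
    mid <- (r[-1] + r[-N]) / 2
    reg <- findInterval(mid, c(geom$Rnt, geom$Rvt)) + 1
    fluxcoef <- K[reg] * mid^nu / diff(r)
    vol_up <- (mid^(nu + 1) - r[-N]^(nu + 1)) / (nu + 1)
    vol_dn <- (r[-1]^(nu + 1) - mid^(nu + 1)) / (nu + 1)
    aii <- numeric(N); rhs <- numeric(N)
    sup <- numeric(N - 1); sub <- numeric(N - 1)
    for (j in 1:(N - 1)) {
      aii[j] <- aii[j] + fluxcoef[j] + sig[reg[j]] * vol_up[j]
      rhs[j] <- rhs[j] + sig[reg[j]] * pss[reg[j]] * vol_up[j]
      sup[j] <- -fluxcoef[j]
      aii[j + 1] <- aii[j + 1] + fluxcoef[j] + sig[reg[j]] * vol_dn[j]
      rhs[j + 1] <- rhs[j + 1] + sig[reg[j]] * pss[reg[j]] * vol_dn[j]
      sub[j] <- -fluxcoef[j]
    }
    A <- Matrix::bandSparse(N, N, k = -1:1,
                            diagonals = list(sub, aii, sup))
    list(r = r, P = as.vector(Matrix::solve(A, rhs)))
  }
  c1 <- solve_fv(n_per); c2 <- solve_fv(2 * n_per)
  idx <- match(round(c1$r, 12), round(c2$r, 12))
  list(r = c1$r, P = (4 * c2$P[idx] - c1$P) / 3)
}

# Free-space 2D diffusion of a uniform disc source (radius r0, value C0):
# C(r,t) = C0/(2Dt) int_0^r0 exp(-(r^2+rho^2)/(4Dt)) I0(r rho / (2Dt)) rho drho,
# evaluated with exponent-scaled Bessel I0 for stability. Valid while the
# solution has not felt the outer boundary.
disc_diffusion_exact <- function(r, t, D, r0, C0 = 1) {
  vapply(r, function(ri) {
    f <- function(rho) {
      z <- ri * rho / (2 * D * t)
      exp(-(ri - rho)^2 / (4 * D * t)) * besselI(z, 0, expon.scaled = TRUE) *
        rho
    }
    C0 / (2 * D * t) * stats::integrate(f, 0, r0, rel.tol = 1e-10)$value
  }, numeric(1))
}
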