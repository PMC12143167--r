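# Transient Galerkin FEM for the solute convection-diffusion-reaction
# equation after intratumoral injection.
#
#   dC/dt = div(D_EF grad C) - v . grad C
#           - [div v + P(S/V) Pe/(e^Pe - 1) + phi_LS + tau_deg] C
#
# with a zero-flux outer boundary and C_PL = 0. The velocity divergence is
# taken from the projected discrete Darcy field; the transvascular
# extraction coefficient depends on the local pressure through the
# transcapillary Peclet number. Implicit time stepping (backward Euler by
# default, Crank-Nicolson optionally) with a fixed step; the system matrix
# is factorized once.

#' Intratumoral injection specification
#'
#' @param target `"necrotic_region"` (uniform dose over the necrotic core,
#'   the default protocol) or `"ball"` (uniform dose inside a disc).
#' @param C0 Injected interstitial concentration [mg/cc].
#' @param center,radius Ball center [cm] and radius [cm] when
#'   `target = "ball"`.
#' @return Object of class `injection_spec`.
#' @export
injection_spec <- function(target = c("necrotic_region", "ball"), C0 = 4,
                           center = c(0, 0), radius = 0.3) {
  target <- match.arg(target)
  stopifnot(C0 >= 0, radius > 0)
  structure(list(target = target, C0 = C0, center = center, radius = radius),
            class = "injection_spec")
}

#' Initial nodal concentration after injection
#'
#' `C = C0` at nodes inside the target, 0 outside; nodes exactly on the
#' target boundary take the inside value.
#'
#' @param mesh A `tumor_mesh`.
#' @param inj An [injection_spec()].
#' @return Nodal concentration vector [mg/cc].
#' @export
build_initial_concentration <- function(mesh, inj) {
  rr <- sqrt(rowSums(mesh$nodes^2))
  tol <- 1e-9
  if (inj$target == "necrotic_region") {
    inside <- rr <= mesh$geometry$Rnt + tol
  } else {
    d <- sqrt((mesh$nodes[, 1] - inj$center[1])^2 +
              (mesh$nodes[, 2] - inj$center[2])^2)
    if (sqrt(sum(inj$center^2)) - inj$radius > mesh$geometry$Rht)
      stop("injection target lies outside the domain")
    inside <- d <= inj$radius + tol
  }
  if (!any(inside)) stop("injection target contains no mesh nodes")
  ifelse(inside, inj$C0, 0)
}

#' Assemble the transport operators
#'
#' Builds the mass, diffusion-stiffness, convection and reaction matrices of
#' the solute equation on the same mesh as a solved flow problem. The
#' reaction coefficient groups the divergence of the projected velocity
#' field, the pressure-dependent transvascular extraction, the lymphatic
#' drainage, and first-order degradation; each part is also kept separately
#' for the mass ledger.
#'
#' @param mesh A `tumor_mesh`.
#' @param pressure An `fem_pressure` on the same mesh.
#' @param velocity An `fem_velocity` on the same mesh (from
#'   [project_velocity()]).
#' @param params Named list of `region_parameters`.
#' @param solute A [solute_spec()] or [carrier_spec()].
#' @param lumped_mass Use the row-sum lumped mass matrix (better positivity
#'   for the sharp injection front); consistent mass otherwise.
#' @param divergence `"projected"` (literal div of the discrete velocity) or
#'   `"analytic"` (the continuum identity div v = phi_VS - phi_LS).
#' @return List of class `transport_operators`.
#' @export
assemble_transport_operators <- function(mesh, pressure, velocity, params,
                                         solute = solute_spec(),
                                         lumped_mass = TRUE,
                                         divergence = c("projected", "analytic")) {
  divergence <- match.arg(divergence)
  if (!identical(dim(mesh$nodes), dim(pressure$mesh$nodes)) ||
      !identical(dim(mesh$nodes), dim(velocity$mesh$nodes)))
    stop("pressure/velocity fields live on a different mesh")
  ctx <- pressure$ctx
  r <- ctx$rule
  coeffs <- pressure$coeffs
  sc <- solute_region_coefficients(params, solute)
  Dv <- unname(sc$D[as.character(mesh$region)])
  tauv <- unname(sc$tau[as.character(mesh$region)])
  reg <- as.integer(mesh$region)  # 1 necrotic, 2 viable, 3 healthy
  aV <- vapply(coeffs, function(rc) rc$phiVS_linear[["a"]], numeric(1))[reg]
  bV <- vapply(coeffs, function(rc) rc$phiVS_linear[["b"]], numeric(1))[reg]
  aL <- vapply(coeffs, function(rc) rc$phiLS_linear[["a"]], numeric(1))[reg]
  bL <- vapply(coeffs, function(rc) rc$phiLS_linear[["b"]], numeric(1))[reg]
  PSV <- vapply(coeffs, function(rc) rc$Pperm_SV, numeric(1))[reg]

  M <- .mass(ctx, rep(1, ctx$nel))
  if (lumped_mass)
    M <- Matrix::Diagonal(x = as.vector(M %*% rep(1, ctx$nn)))
  A_D <- .stiffness(ctx, Dv)

  Pq <- .field_at_quad(ctx, pressure$P)
  Uq <- .field_at_quad(ctx, velocity$U)
  Vq <- .field_at_quad(ctx, velocity$V)
  gU <- .grad_at_quad(ctx, velocity$U)
  gV <- .grad_at_quad(ctx, velocity$V)

  nd <- r$ndof; nel <- ctx$nel
  cv <- matrix(0, nel, nd * nd)   # convection v . grad C
  rx <- matrix(0, nel, nd * nd)   # extraction reaction
  rl <- matrix(0, nel, nd * nd)   # lymphatic reaction
  rd <- matrix(0, nel, nd * nd)   # degradation reaction
  rv <- matrix(0, nel, nd * nd)   # velocity-divergence reaction
  for (q in seq_along(r$w)) {
    wdet <- r$w[q] / 2 * ctx$det
    phiVS_q <- aV - bV * Pq[, q]
    Pe_q <- phiVS_q * (1 - solute$sigma_rc) / pmax(PSV, 1e-300)
    extr_q <- ifelse(PSV > 0, PSV * peclet_factor(Pe_q), 0)
    lym_q <- aL + bL * Pq[, q]
    div_q <- if (divergence == "projected")
      gU$gx[, q] + gV$gy[, q]
    else phiVS_q - lym_q
    k <- 0L
    for (A in seq_len(nd)) for (B in seq_len(nd)) {
      k <- k + 1L
      NaNb <- r$N[q, A] * r$N[q, B]
      # physical gradient of basis B at this quadrature point
      Nbx <- (ctx$d * r$gx[q, B] - ctx$c * r$gy[q, B]) / ctx$det
      Nby <- (-ctx$b * r$gx[q, B] + ctx$a * r$gy[q, B]) / ctx$det
      cv[, k] <- cv[, k] + wdet * r$N[q, A] * (Uq[, q] * Nbx + Vq[, q] * Nby)
      rx[, k] <- rx[, k] + wdet * NaNb * extr_q
      rl[, k] <- rl[, k] + wdet * NaNb * lym_q
      rd[, k] <- rd[, k] + wdet * NaNb * tauv
      rv[, k] <- rv[, k] + wdet * NaNb * div_q
    }
  }
  tosparse <- function(vals) {
    k <- 0L
    ii <- integer(nel * nd * nd); jj <- integer(nel * nd * nd)
    xx <- numeric(nel * nd * nd)
    for (A in seq_len(nd)) for (B in seq_len(nd)) {
      idx <- (k * nel + 1L):((k + 1L) * nel)
      ii[idx] <- ctx$elem[, A]; jj[idx] <- ctx$elem[, B]
      xx[idx] <- vals[, (A - 1L) * nd + B]
      k <- k + 1L
    }
    Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ctx$nn, ctx$nn))
  }
  structure(list(M = M, A_D = A_D, Cv = tosparse(cv),
                 R_extraction = tosparse(rx), R_lymphatic = tosparse(rl),
                 R_degradation = tosparse(rd), R_divergence = tosparse(rv),
                 mesh = mesh, ctx = ctx, solute = solute,
                 lumped_mass = lumped_mass),
            class = "transport_operators")
}

#' Run the transient transport simulation
#'
#' Implicit fixed-step time integration of the assembled solute operators
#' from an initial nodal concentration. The system matrix is factorized
#' once; each step is a sparse triangular solve. A per-step mass ledger
#' tracks where the injected dose goes (transvascular extraction, lymphatic
#' drainage, degradation, and net advective boundary exchange).
#'
#' @param ops A `transport_operators` object.
#' @param C0 Initial nodal concentration (e.g.
#'   [build_initial_concentration()]).
#' @param dt Time step [s].
#' @param horizon Final time [s].
#' @param store_times Times [s] at which to store snapshots (defaults to
#'   6 h, 24 h, 48 h, 72 h intersected with the horizon; 0 and the horizon
#'   are always stored).
#' @param scheme `"backward_euler"` or `"crank_nicolson"`.
#' @return Object of class `tumor_transport`: snapshot matrix `C` (nodes x
#'   stored times), `times`, the mass `ledger` data frame, and bookkeeping.
#' @export
run_transport <- function(ops, C0, dt = 60, horizon = 72 * 3600,
                          store_times = NULL,
                          scheme = c("backward_euler", "crank_nicolson")) {
  scheme <- match.arg(scheme)
  stopifnot(dt > 0, horizon >= dt)
  theta <- if (scheme == "backward_euler") 1 else 0.5
  nsteps <- ceiling(horizon / dt)
  if (is.null(store_times))
    store_times <- c(6, 24, 48, 72) * 3600
  store_times <- sort(unique(c(0, store_times[store_times <= horizon],
                               nsteps * dt)))
  store_steps <- unique(round(store_times / dt))
  store_times <- store_steps * dt
  L <- ops$A_D + ops$Cv + ops$R_extraction + ops$R_lymphatic +
       ops$R_degradation + ops$R_divergence
  Sys <- ops$M / dt + theta * L
  lu <- Matrix::lu(Sys)
  mvec <- as.vector(Matrix::t(ops$M) %*% rep(1, length(C0)))
  Cn <- C0
  snaps <- matrix(NA_real_, length(C0), length(store_steps))
  colnames(snaps) <- paste0("t", store_times)
  ledger <- data.frame(time = numeric(nsteps + 1), mass = NA_real_,
                       loss_transvascular = 0, loss_lymphatic = 0,
                       loss_degradation = 0, loss_advective = 0)
  ledger$time <- (0:nsteps) * dt
  ledger$mass[1] <- sum(mvec * Cn)
  cum <- c(tv = 0, ly = 0, dg = 0, ad = 0)
  si <- 1L
  if (store_steps[1] == 0L) { snaps[, 1] <- Cn; si <- 2L }
  ones <- rep(1, length(C0))
  for (n in seq_len(nsteps)) {
    rhs <- ops$M %*% Cn / dt
    if (theta < 1) rhs <- rhs - (1 - theta) * (L %*% Cn)
    Cnp <- as.vector(Matrix::solve(lu, rhs))
    if (any(!is.finite(Cnp)))
      stop(sprintf("linear solve failed at step %d", n))
    Cm <- theta * Cnp + (1 - theta) * Cn
    cum["tv"] <- cum["tv"] + dt * sum(ones * (ops$R_extraction %*% Cm))
    cum["ly"] <- cum["ly"] + dt * sum(ones * (ops$R_lymphatic %*% Cm))
    cum["dg"] <- cum["dg"] + dt * sum(ones * (ops$R_degradation %*% Cm))
    cum["ad"] <- cum["ad"] + dt * sum(ones * ((ops$Cv + ops$R_divergence) %*% Cm))
    Cn <- Cnp
    ledger$mass[n + 1] <- sum(mvec * Cn)
    ledger$loss_transvascular[n + 1] <- cum["tv"]
    ledger$loss_lymphatic[n + 1] <- cum["ly"]
    ledger$loss_degradation[n + 1] <- cum["dg"]
    ledger$loss_advective[n + 1] <- cum["ad"]
    if (si <= length(store_steps) && n == store_steps[si]) {
      snaps[, si] <- Cn; si <- si + 1L
    }
  }
  structure(list(C = snaps, times = store_times, ledger = ledger,
                 mesh = ops$mesh, solute = ops$solute, dt = dt,
                 scheme = scheme, mvec = mvec),
            class = "tumor_transport")
}

#' Concentration at the tumor center
#' @param series A `tumor_transport`.
#' @param time Time [s]; nearest stored snapshot is used.
#' @return Concentration [mg/cc].
#' @export
center_concentration <- function(series, time) {
  i <- which.min(abs(series$times - time))
  unname(series$C[1, i])
}

#' Radial concentration profile
#'
#' Samples the concentration along the +x transverse line by element-local
#' interpolation at the stored snapshot closest to `time`.
#'
#' @param series A `tumor_transport`.
#' @param time Requested time [s].
#' @param dr Sampling step [cm].
#' @return Data frame (r, C, time); attribute `snapped` is TRUE when the
#'   requested time was not stored exactly.
#' @export
radial_profile <- function(series, time, dr = 1e-3) {
  if (time > max(series$times) + series$dt)
    stop("time beyond the simulated horizon")
  i <- which.min(abs(series$times - time))
  snapped <- abs(series$times[i] - time) > series$dt / 2
  if (snapped)
    warning(sprintf("time %g s not stored; using nearest snapshot %g s",
                    time, series$times[i]))
  rr <- seq(0, series$mesh$geometry$Rht, by = dr)
  cc <- interp_field(series$mesh, series$C[, i], rr, rep(0, length(rr)))
  out <- data.frame(r = rr, C = cc, time = series$times[i])
  attr(out, "snapped") <- snapped
  out
}

#' @export
print.tumor_transport <- function(x, ...) {
  cat(sprintf("Transport series (%s, dt = %g s): %s\n", x$scheme, x$dt,
              x$solute$label))
  m0 <- x$ledger$mass[1]; mend <- x$ledger$mass[nrow(x$ledger)]
  cat(sprintf("  stored times [h]: %s\n  mass: %.4g -> %.4g mg/cm (%.1f%% retained)\n",
              paste(signif(x$times / 3600, 3), collapse = ", "),
              m0, mend, 100 * mend / m0))
  invisible(x)
}

#' Relative closure error of the mass ledger
#'
#' `mass(t) + sum(losses(t))` should equal the injected mass at all times.
#'
#' @param series A `tumor_transport`.
#' @return Maximum relative closure error over the run.
#' @export
ledger_closure_error <- function(series) {
  lg <- series$ledger
  tot <- lg$mass + lg$loss_transvascular + lg$loss_lymphatic +
         lg$loss_degradation + lg$loss_advective
  max(abs(tot - lg$mass[1])) / lg$mass[1]
}
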