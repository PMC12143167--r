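#' Region-wise coefficients of the pressure equation
#'
#' Reduces the physiology of each region to the coefficients actually used
#' by the solvers. In each region the steady pressure satisfies the modified
#' Helmholtz equation `laplacian(P) = beta2 * (P - PSS)` with
#' `beta2 = (Lp S/V + L_PL S_L/V) / K`; flux continuity `K dP/dn` couples the
#' regions. The Starling source and lymphatic sink are kept in the linear
#' form `phi = a - b * P` for assembly.
#'
#' @param params Named list of `region_parameters`
#'   (`necrotic`, `viable`, `healthy`), e.g. from [baseline_parameters()].
#' @param lymph A `lymphatic_parameters` object.
#' @param R_ref Reference length [cm] used only to report alpha.
#' @return A list of class `region_coefficients`, one entry per region with
#'   fields `K`, `beta2`, `PSS`, `PEF`, `alpha`, `sigma` (total filtration
#'   conductance `Lp S/V + L_PL S_L/V` [1/(mmHg s)]), `phiVS_linear = c(a, b)`
#'   such that `phi_VS = a - b P`, and `phiLS_linear = c(a, b)` such that
#'   `phi_LS = a + b P`.
#' @export
region_coefficients <- function(params, lymph = lymphatic_parameters(),
                                R_ref = 1) {
  stopifnot(all(c("necrotic", "viable", "healthy") %in% names(params)))
  out <- lapply(params, function(rp) {
    lpl <- if (rp$name == "healthy") lymph$LPL_SLV else 0
    pl  <- if (rp$name == "healthy") lymph$PL else 0
    sig <- rp$Lp * rp$SV + lpl
    pef <- effective_pressure(rp)
    list(
      name = rp$name,
      K = rp$K,
      sigma = sig,
      beta2 = if (rp$name == "necrotic") 0 else sig / rp$K,
      PEF = pef,
      PSS = steady_state_pressure(rp, lymph),
      alpha = flow_resistance_alpha(rp, lymph, R = R_ref),
      xi = rp$xi,
      phiVS_linear = if (rp$name == "necrotic") c(a = 0, b = 0)
                     else c(a = rp$Lp * rp$SV * pef, b = rp$Lp * rp$SV),
      phiLS_linear = c(a = -lpl * pl, b = lpl),
      Pperm_SV = rp$Pperm * rp$SV,
      sigma_rc_region = NA_real_  # filled from solute spec when needed
    )
  })
  structure(out, class = "region_coefficients", R_ref = R_ref)
}

#' @export
print.region_coefficients <- function(x, ...) {
  cat("Region coefficients (cm-s-mmHg units):\n")
  for (rc in x) {
    cat(sprintf(
      "  %-8s K=%.3g  beta2=%.4g 1/cm^2  PSS=%.4f mmHg  PEF=%.4f mmHg  alpha(R=%g)=%.4g\n",
      rc$name, rc$K, rc$beta2, rc$PSS, rc$PEF, attr(x, "R_ref"), rc$alpha))
  }
  invisible(x)
}

#' Per-region effective diffusivity and degradation of a solute
#'
#' Resolves a `solute_spec` into the three regional effective diffusivities
#' [cm^2/s] and degradation rates [1/s]. Size-parameterized solutes go
#' through Stokes-Einstein and the regional void fractions; carrier presets
#' use their tabulated per-tissue (tumor/normal) overrides.
#'
#' @param params Named list of `region_parameters`.
#' @param ss A `solute_spec`.
#' @return List with numeric vectors `D` and `tau`, named by region.
#' @export
solute_region_coefficients <- function(params, ss) {
  regs <- c("necrotic", "viable", "healthy")
  if (!is.null(ss$D_override)) {
    D <- c(necrotic = unname(ss$D_override["tumor"]),
           viable   = unname(ss$D_override["tumor"]),
           healthy  = unname(ss$D_override["normal"]))
  } else {
    Ddis <- stokes_einstein_diffusivity(ss)
    D <- vapply(regs, function(r) effective_diffusivity(Ddis, params[[r]]$xi),
                numeric(1))
  }
  if (!is.null(ss$tau_override)) {
    tau <- c(necrotic = unname(ss$tau_override["tumor"]),
             viable   = unname(ss$tau_override["tumor"]),
             healthy  = unname(ss$tau_override["normal"]))
  } else {
    tau <- c(necrotic = ss$tau_deg, viable = ss$tau_deg, healthy = ss$tau_deg)
  }
  list(D = D, tau = tau)
}

#' Globally rescale hydraulic conductivity to a target resistance
#'
#' The alpha sweeps vary the tumor fluid-flow resistance parameter by
#' scaling `K` in all three regions by `(alpha_base / alpha_target)^2`,
#' which multiplies every regional `beta` by the same factor while leaving
#' the steady-state pressures untouched.
#'
#' @param params Named list of `region_parameters`.
#' @param alpha_target Desired viable-region alpha at `R = 1` cm.
#' @param lymph Lymphatic parameters (for the reference alpha).
#' @return Modified parameter list.
#' @export
scale_to_alpha <- function(params, alpha_target,
                           lymph = lymphatic_parameters()) {
  a0 <- flow_resistance_alpha(params$viable, lymph, R = 1)
  fac <- (a0 / alpha_target)^2
  for (r in names(params)) params[[r]]$K <- params[[r]]$K * fac
  params
}
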