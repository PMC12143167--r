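#' Per-region tissue and vasculature physiology
#'
#' Bundles the physiological constants of one tissue region (necrotic core,
#' viable tumor rim, or surrounding healthy tissue). Units follow the
#' package's internal cm-s-mmHg system.
#'
#' @param name Region name, one of `"necrotic"`, `"viable"`, `"healthy"`.
#' @param Lp Microvascular wall hydraulic conductivity [cm/(mmHg s)].
#' @param K Interstitial tissue hydraulic conductivity [cm^2/(mmHg s)].
#' @param SV Vascular density S/V [1/cm]; 0 in the necrotic core.
#' @param sigma_s Osmotic reflection coefficient (0..1).
#' @param piV Capillary oncotic pressure [mmHg].
#' @param piIS Interstitial oncotic pressure [mmHg].
#' @param PV Microvascular pressure [mmHg].
#' @param Pperm Vascular permeability of the solute [cm/s].
#' @param xi Interstitium void fraction (0..1).
#' @return An object of class `region_parameters`.
#' @export
region_parameters <- function(name, Lp, K, SV, sigma_s, piV, piIS, PV,
                              Pperm, xi) {
  name <- match.arg(name, c("necrotic", "viable", "healthy"))
  stopifnot(sigma_s >= 0, sigma_s <= 1, xi > 0, xi < 1,
            Lp >= 0, K >= 0, SV >= 0)
  if (name == "necrotic" && SV != 0)
    stop("necrotic region has no vasculature: SV must be 0")
  structure(list(name = name, Lp = Lp, K = K, SV = SV, sigma_s = sigma_s,
                 piV = piV, piIS = piIS, PV = PV, Pperm = Pperm, xi = xi),
            class = "region_parameters")
}

#' Lymphatic drainage parameters (healthy region only)
#'
#' @param LPL_SLV Lymphatic filtration coefficient L_PL * S_L/V [1/(mmHg s)].
#' @param PL Lymphatic hydrostatic pressure [mmHg]. `PL = 0` models the
#'   absence of functional lymphatic dynamics; `PL = -4` mmHg the complete
#'   functional case.
#' @param functional Logical; if `FALSE`, `PL` is forced to 0.
#' @return An object of class `lymphatic_parameters`.
#' @export
lymphatic_parameters <- function(LPL_SLV = 1.1e-5, PL = 0, functional = (PL != 0)) {
  stopifnot(LPL_SLV >= 0)
  if (!functional) PL <- 0
  structure(list(LPL_SLV = LPL_SLV, PL = PL, functional = functional),
            class = "lymphatic_parameters")
}

#' Concentric three-region tumor geometry
#'
#' @param Rnt,Rvt,Rht Outer radii [cm] of the necrotic core, viable tumor,
#'   and healthy tissue; must satisfy `0 < Rnt < Rvt < Rht`.
#' @return An object of class `tumor_geometry`.
#' @export
tumor_geometry <- function(Rnt = 0.5, Rvt = 1, Rht = 2) {
  stopifnot(Rnt > 0, Rnt < Rvt, Rvt < Rht)
  structure(list(Rnt = Rnt, Rvt = Rvt, Rht = Rht), class = "tumor_geometry")
}

#' Solute / nanoparticle specification
#'
#' Describes the transported species: hydrodynamic particle radius for the
#' Stokes-Einstein diffusivity, first-order degradation rate (nano-bio
#' uptake, e.g. by tumor-associated macrophages), and the solute filtration
#' reflection coefficient of the vessel wall. For literature carriers whose
#' effective diffusivity and degradation are tabulated directly, per-tissue
#' overrides replace the Stokes-Einstein route (`tumor` applies to the
#' necrotic + viable regions, `normal` to healthy tissue).
#'
#' @param nr Particle radius [m]; may be `NA` when `D_override` is given.
#' @param tau_deg Degradation rate constant [1/s].
#' @param sigma_rc Solute filtration reflection coefficient (0..1).
#' @param CPL Plasma concentration [mg/cc]; the intratumoral-injection model
#'   takes it as 0.
#' @param kB Boltzmann constant [J/K].
#' @param T Absolute temperature [K].
#' @param mu Interstitial fluid viscosity [Pa s].
#' @param D_override Optional named vector `c(tumor=, normal=)` of effective
#'   diffusivities [cm^2/s] replacing the Stokes-Einstein/void-fraction model.
#' @param tau_override Optional named vector `c(tumor=, normal=)` of
#'   degradation rates [1/s].
#' @param label Optional display label.
#' @return An object of class `solute_spec`.
#' @export
solute_spec <- function(nr = 5e-9, tau_deg = 5.8e-6, sigma_rc = 0.5,
                        CPL = 0, kB = 1.38e-23, T = 310, mu = 1e-3,
                        D_override = NULL, tau_override = NULL,
                        label = NULL) {
  if (is.null(D_override)) stopifnot(nr > 0)
  stopifnot(tau_deg >= 0, sigma_rc >= 0, sigma_rc <= 1)
  if (!is.null(D_override))
    stopifnot(all(c("tumor", "normal") %in% names(D_override)))
  if (!is.null(tau_override))
    stopifnot(all(c("tumor", "normal") %in% names(tau_override)))
  structure(list(nr = nr, tau_deg = tau_deg, sigma_rc = sigma_rc, CPL = CPL,
                 kB = kB, T = T, mu = mu, D_override = D_override,
                 tau_override = tau_override,
                 label = label %||% sprintf("particle %g nm", 2 * nr * 1e9)),
            class = "solute_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mmHg -> Pa conversion, used only for reporting
MMHG_PA <- 133.322

#' Baseline tissue parameter set
#'
#' The reference physiology of the three regions: a fully avascular necrotic
#' core, a leaky highly vascularized viable rim without lymphatics, and
#' healthy tissue with lower permeability and functional lymphatic capillaries.
#'
#' @return Named list of three `region_parameters` objects
#'   (`necrotic`, `viable`, `healthy`).
#' @export
baseline_parameters <- function() {
  list(
    necrotic = region_parameters("necrotic", Lp = 2.8e-7, K = 4.13e-8,
                                 SV = 0, sigma_s = 0.82, piV = 20, piIS = 15,
                                 PV = 15.6, Pperm = 5.73e-9, xi = 0.6),
    viable   = region_parameters("viable", Lp = 2.8e-7, K = 4.13e-8,
                                 SV = 200, sigma_s = 0.82, piV = 20, piIS = 15,
                                 PV = 15.6, Pperm = 5.73e-9, xi = 0.4),
    healthy  = region_parameters("healthy", Lp = 3.6e-8, K = 8.53e-9,
                                 SV = 70, sigma_s = 0.91, piV = 20, piIS = 10,
                                 PV = 15.6, Pperm = 0.73e-9, xi = 0.26)
  )
}

#' Vascular-normalization parameter sets
#'
#' Anti-angiogenic vascular normalization remodels the viable-rim
#' vasculature toward healthy-tissue values. The 0% level is the baseline;
#' 50% and 100% interpolate/replace the viable-region hydraulic conductivity
#' `K`, wall conductivity `Lp`, vascular density `S/V` and reflection
#' coefficient `sigma_s`. The tumor interstitial `K` is normalized jointly
#' (the necrotic core inherits the tumor `K`).
#'
#' @param level One of 0, 50, 100 (percent normalization).
#' @return Named list of three `region_parameters` objects.
#' @export
vn_parameters <- function(level = 0) {
  stopifnot(level %in% c(0, 50, 100))
  tab <- list(
    `0`   = list(K = 4.13e-8, Lp = 2.8e-7,   SV = 200, sigma_s = 0.82),
    `50`  = list(K = 2.49e-8, Lp = 1.585e-7, SV = 135, sigma_s = 0.865),
    `100` = list(K = 8.53e-9, Lp = 3.6e-8,   SV = 70,  sigma_s = 0.91)
  )[[as.character(level)]]
  pp <- baseline_parameters()
  pp$viable$K <- tab$K; pp$viable$Lp <- tab$Lp
  pp$viable$SV <- tab$SV; pp$viable$sigma_s <- tab$sigma_s
  pp$necrotic$K <- tab$K; pp$necrotic$Lp <- tab$Lp
  pp$necrotic$sigma_s <- tab$sigma_s
  pp
}

#' Literature nanodrug carrier presets
#'
#' Tabulated effective interstitial diffusivities and degradation rates for
#' conventional doxorubicin and four nanocarriers, given separately for
#' tumor (necrotic + viable) and normal (healthy) tissue.
#'
#' @param name One of `"doxorubicin"`, `"dextran"`, `"liposomal"`,
#'   `"peg_gold"`, `"magnetic"`.
#' @return A `solute_spec` with per-tissue overrides.
#' @export
carrier_spec <- function(name = c("doxorubicin", "dextran", "liposomal",
                                  "peg_gold", "magnetic")) {
  name <- match.arg(name)
  tab <- list(
    doxorubicin = list(D = c(tumor = 3.4e-6,  normal = 1.58e-6),
                       tau = c(tumor = 2.69e-3, normal = 2.689e-3)),
    dextran     = list(D = c(tumor = 1.4e-7,  normal = 5e-9),
                       tau = c(tumor = 4.17e-4, normal = 2.085e-4)),
    liposomal   = list(D = c(tumor = 3.35e-7, normal = 2.4e-9),
                       tau = c(tumor = 1.16e-5, normal = 1.157e-5)),
    peg_gold    = list(D = c(tumor = 4.40e-8, normal = 1.2e-8),
                       tau = c(tumor = 2.08e-5, normal = 2.083e-5)),
    magnetic    = list(D = c(tumor = 8.89e-8, normal = 4.17e-8),
                       tau = c(tumor = 3e-16,  normal = 3e-16))
  )[[name]]
  solute_spec(nr = NA, D_override = tab$D, tau_override = tab$tau,
              label = name)
}

#' Effective (filtration-stop) pressure
#'
#' The interstitial pressure at which transvascular filtration vanishes:
#' `PEF = PV - sigma_s * (piV - piIS)`.
#'
#' @param rp A `region_parameters` object.
#' @return Pressure [mmHg].
#' @export
effective_pressure <- function(rp) {
  rp$PV - rp$sigma_s * (rp$piV - rp$piIS)
}

#' Steady-state (far-field equilibrium) pressure
#'
#' Conductance-weighted average of the effective pressure and the lymphatic
#' hydrostatic pressure. In the necrotic core (no vasculature) it is 0 by
#' convention; in the viable rim (no lymphatics) it reduces to the effective
#' pressure.
#'
#' @param rp A `region_parameters` object.
#' @param lp A `lymphatic_parameters` object; ignored outside the healthy
#'   region.
#' @return Pressure [mmHg].
#' @export
steady_state_pressure <- function(rp, lp = lymphatic_parameters()) {
  if (rp$name == "necrotic") return(0)
  lpl <- if (rp$name == "healthy") lp$LPL_SLV else 0
  pl  <- if (rp$name == "healthy") lp$PL else 0
  den <- rp$Lp * rp$SV + lpl
  if (den <= 0)
    stop("zero filtration conductance outside the necrotic region")
  (rp$Lp * rp$SV * effective_pressure(rp) + lpl * pl) / den
}

#' Dimensionless fluid-flow resistance parameter
#'
#' `alpha = R * sqrt((Lp S/V + L_PL S_L/V) / K)`: the ratio of interstitial
#' to vascular flow resistance over a reference length `R`. The lymphatic
#' term applies in the healthy region only; the necrotic core has alpha = 0.
#'
#' @param rp A `region_parameters` object.
#' @param lp A `lymphatic_parameters` object.
#' @param R Reference length [cm], by convention the viable tumor radius.
#' @return Dimensionless resistance.
#' @export
flow_resistance_alpha <- function(rp, lp = lymphatic_parameters(), R = 1) {
  if (rp$name == "necrotic") return(0)
  if (rp$K <= 0) stop("hydraulic conductivity must be positive")
  lpl <- if (rp$name == "healthy") lp$LPL_SLV else 0
  R * sqrt((rp$Lp * rp$SV + lpl) / rp$K)
}

#' Starling transvascular fluid source
#'
#' Volumetric filtration rate out of the blood vessels per unit tissue
#' volume: `phi_VS = Lp (S/V) (PV - P_IS - sigma_s (piV - piIS))`. Zero in
#' the necrotic core.
#'
#' @param rp A `region_parameters` object.
#' @param P_IS Interstitial fluid pressure [mmHg] (vectorized).
#' @return Rate [1/s].
#' @export
vascular_source_phiVS <- function(rp, P_IS) {
  if (rp$name == "necrotic") return(rep(0, length(P_IS)))
  rp$Lp * rp$SV * (effective_pressure(rp) - P_IS)
}

#' Lymphatic fluid sink
#'
#' Volumetric drainage rate into lymphatic capillaries per unit tissue
#' volume: `phi_LS = L_PL (S_L/V) (P_IS - P_L)`. Applies in the healthy
#' region only.
#'
#' @param lp A `lymphatic_parameters` object.
#' @param P_IS Interstitial fluid pressure [mmHg] (vectorized).
#' @param region Region name; the sink is zero outside `"healthy"`.
#' @return Rate [1/s].
#' @export
lymphatic_sink_phiLS <- function(lp, P_IS, region = "healthy") {
  if (region != "healthy") return(rep(0, length(P_IS)))
  lp$LPL_SLV * (P_IS - lp$PL)
}

#' Stokes-Einstein diffusivity in free interstitial fluid
#'
#' `D = kB T / (6 pi mu nr)`, computed in SI and returned in cm^2/s.
#'
#' @param ss A `solute_spec` object.
#' @return Diffusivity [cm^2/s].
#' @export
stokes_einstein_diffusivity <- function(ss) {
  if (!is.finite(ss$nr) || ss$nr <= 0)
    stop("particle radius must be positive for the Stokes-Einstein model")
  if (ss$mu <= 0) stop("viscosity must be positive")
  ss$kB * ss$T / (6 * pi * ss$mu * ss$nr) * 1e4  # m^2/s -> cm^2/s
}

#' Hindered effective diffusivity in porous tissue
#'
#' Tortuosity correction `D_EF = (2 xi / (3 - xi)) D_DIS` via the
#' interstitial void fraction `xi`.
#'
#' @param D_DIS Free-fluid diffusivity [cm^2/s].
#' @param xi Void fraction in (0, 1]; `xi = 1` recovers the free solution.
#' @return Diffusivity [cm^2/s].
#' @export
effective_diffusivity <- function(D_DIS, xi) {
  if (any(xi <= 0 | xi > 1)) stop("void fraction must lie in (0, 1]")
  (2 * xi / (3 - xi)) * D_DIS
}

#' Peclet factor Pe / (e^Pe - 1)
#'
#' Smooth evaluation of the transcapillary Peclet factor, with a Bernoulli
#' series for |Pe| < 1e-6 and guards against overflow for large |Pe|.
#'
#' @param Pe Transcapillary Peclet number (vectorized).
#' @return `Pe / (exp(Pe) - 1)`, continuous through `Pe = 0`.
#' @export
peclet_factor <- function(Pe) {
  out <- numeric(length(Pe))
  small <- abs(Pe) < 1e-6
  out[small] <- 1 - Pe[small] / 2 + Pe[small]^2 / 12
  big_pos <- !small & Pe > 500
  out[big_pos] <- Pe[big_pos] * exp(-Pe[big_pos])
  big_neg <- !small & Pe < -500
  out[big_neg] <- -Pe[big_neg]
  mid <- !small & !big_pos & !big_neg
  out[mid] <- Pe[mid] / expm1(Pe[mid])
  out
}

#' Transvascular solute extraction coefficient
#'
#' With negligible plasma concentration the transvascular solute exchange
#' reduces to a first-order sink `Phi_BV = -coef * C_IS` with
#' `coef = P (S/V) Pe / (e^Pe - 1)` and
#' `Pe = phi_VS (1 - sigma_rc) / (P S/V)`. Zero in the necrotic core. Where
#' fluid filters outward (`Pe >> 0`) the coefficient vanishes; where fluid
#' is resorbed (`Pe << 0`) it tends to the solvent-drag limit
#' `|phi_VS| (1 - sigma_rc)`.
#'
#' @param rp A `region_parameters` object.
#' @param ss A `solute_spec` object.
#' @param phiVS Transvascular fluid source rate [1/s] (vectorized), e.g.
#'   from [vascular_source_phiVS()].
#' @return Rate coefficient [1/s].
#' @export
transvascular_extraction <- function(rp, ss, phiVS) {
  if (rp$name == "necrotic") return(rep(0, length(phiVS)))
  PSV <- rp$Pperm * rp$SV
  if (PSV <= 0)
    stop("vanishing permeability-area product outside the necrotic region")
  Pe <- phiVS * (1 - ss$sigma_rc) / PSV
  PSV * peclet_factor(Pe)
}
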