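# Configuration-driven scenario runner: chains parameters -> mesh -> flow ->
# transport for the studies in the results program (alpha sweeps, vascular
# normalization, necrotic-radius and microvascular-pressure sweeps, particle
# sizes, carriers, degradation x diffusivity grids).

#' Scenario configuration
#'
#' A fully serializable description of one simulation scenario. Physical
#' keys carry unit suffixes. Re-running an identical configuration
#' reproduces identical summaries (the solvers are direct).
#'
#' @param preset Parameter preset: `"baseline"`, `"vn50"`, `"vn100"`.
#' @param Rnt_cm,Rvt_cm,Rht_cm Region radii [cm].
#' @param PL_mmHg Lymphatic hydrostatic pressure [mmHg] (0 = absent
#'   functional lymphatic dynamics).
#' @param alpha_target Optional viable-region alpha to rescale all hydraulic
#'   conductivities to (NULL = leave preset values).
#' @param PV_mmHg Optional microvascular pressure override [mmHg], applied
#'   in the viable and healthy regions.
#' @param h_max_cm Mesh resolution [cm].
#' @param order Element order (1 or 2).
#' @param symmetry Radial-oracle symmetry (`"cylindrical"` matches the
#'   plane-disc FEM).
#' @param size_nm Particle size (diameter) [nm]; radius `nr = size/2`.
#' @param carrier Optional carrier preset name (overrides `size_nm`).
#' @param C0_mg_cc Injected concentration [mg/cc].
#' @param dt_s Time step [s].
#' @param horizon_h Transport horizon [h].
#' @param store_h Snapshot times [h].
#' @param sweep Optional list `list(variable=, values=)`; see [run_sweep()].
#' @param outdir Optional output directory for VTK/CSV/JSON artifacts.
#' @param seed Integer seed (the solvers are deterministic; kept for
#'   reproducibility bookkeeping of any downstream sampling).
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(preset = "baseline",
                            Rnt_cm = 0.5, Rvt_cm = 1, Rht_cm = 2,
                            PL_mmHg = 0, alpha_target = NULL, PV_mmHg = NULL,
                            h_max_cm = 0.03, order = 2,
                            symmetry = "cylindrical",
                            size_nm = 10, carrier = NULL, C0_mg_cc = 4,
                            dt_s = 60, horizon_h = 72,
                            store_h = c(6, 24, 48, 72),
                            sweep = NULL, outdir = NULL, seed = 1L) {
  structure(as.list(environment()), class = "scenario_config")
}

#' Read / write a scenario configuration as YAML
#' @param cfg A `scenario_config`.
#' @param path File path.
#' @return `read_scenario_config` returns a `scenario_config`.
#' @export
write_scenario_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(scenario_config, vals[!vapply(vals, is.null, logical(1))])
}

.cfg_parameters <- function(cfg) {
  pp <- switch(cfg$preset,
               baseline = baseline_parameters(),
               vn50 = vn_parameters(50),
               vn100 = vn_parameters(100),
               stop("unknown preset: ", cfg$preset))
  lymph <- lymphatic_parameters(PL = cfg$PL_mmHg)
  if (!is.null(cfg$alpha_target))
    pp <- scale_to_alpha(pp, cfg$alpha_target, lymph)
  if (!is.null(cfg$PV_mmHg))
    for (r in c("viable", "healthy")) pp[[r]]$PV <- cfg$PV_mmHg
  list(params = pp, lymph = lymph)
}

.cfg_solute <- function(cfg) {
  if (!is.null(cfg$carrier)) carrier_spec(cfg$carrier)
  else solute_spec(nr = cfg$size_nm / 2 * 1e-9)
}

#' Run a steady flow scenario
#'
#' Solves the radial closed form and the FEM on the configured mesh,
#' cross-checks them, and (optionally) writes fields, profiles and a JSON
#' summary to `cfg$outdir`.
#'
#' @param cfg A [scenario_config()].
#' @return Named list summary: center/minimum pressure [mmHg], velocity
#'   argmax [cm], regional alpha values, oracle-FEM relative discrepancy,
#'   and a `mesh_too_coarse` flag when the discrepancy exceeds 2%.
#' @export
run_flow_scenario <- function(cfg) {
  set.seed(cfg$seed)
  pl <- .cfg_parameters(cfg)
  geom <- tumor_geometry(cfg$Rnt_cm, cfg$Rvt_cm, cfg$Rht_cm)
  co <- region_coefficients(pl$params, pl$lymph, R_ref = cfg$Rvt_cm)
  oracle <- solve_radial_pressure(geom, co, cfg$symmetry)
  mesh <- build_disc_mesh(geom, cfg$h_max_cm, order = cfg$order)
  fem <- solve_pressure(assemble_pressure_system(mesh, co))
  vel <- project_velocity(fem)
  vmag <- sqrt(vel$U^2 + vel$V^2)
  imax <- which.max(vmag)
  osum <- summary(oracle)
  disc <- abs(fem$P[1] - osum$center_pressure) /
    max(abs(osum$center_pressure), 1e-12)
  out <- list(
    preset = cfg$preset, PL_mmHg = cfg$PL_mmHg,
    P_center_mmHg = fem$P[1], P_center_oracle_mmHg = osum$center_pressure,
    P_min_mmHg = min(fem$P), P_min_oracle_mmHg = osum$min_pressure,
    v_max_cm_s = vmag[imax],
    r_at_vmax_cm = sqrt(sum(mesh$nodes[imax, ]^2)),
    alpha = vapply(co, function(rc) rc$alpha, numeric(1)),
    oracle_fem_discrepancy = disc,
    mesh_too_coarse = disc > 0.02,
    n_dof = length(fem$P))
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    write_mesh_vtk(mesh, file.path(cfg$outdir, "flow.vtk"),
                   point_data = list(pressure_mmHg = fem$P,
                                     velocity_u_cm_s = vel$U,
                                     velocity_v_cm_s = vel$V))
    write_radial_profile(oracle, file.path(cfg$outdir, "radial_profile.csv"))
    write_summary_json(out, file.path(cfg$outdir, "flow_summary.json"))
  }
  out
}

#' Run a transient transport scenario
#'
#' Solves flow then transport on the configured mesh with the configured
#' solute and injection.
#'
#' @param cfg A [scenario_config()].
#' @return List with the `tumor_transport` series and a summary (center
#'   concentrations at stored times, ledger closure).
#' @export
run_transport_scenario <- function(cfg) {
  set.seed(cfg$seed)
  pl <- .cfg_parameters(cfg)
  geom <- tumor_geometry(cfg$Rnt_cm, cfg$Rvt_cm, cfg$Rht_cm)
  co <- region_coefficients(pl$params, pl$lymph, R_ref = cfg$Rvt_cm)
  mesh <- build_disc_mesh(geom, cfg$h_max_cm, order = cfg$order)
  fem <- solve_pressure(assemble_pressure_system(mesh, co))
  vel <- project_velocity(fem)
  ss <- .cfg_solute(cfg)
  ops <- assemble_transport_operators(mesh, fem, vel, pl$params, ss)
  Ci <- build_initial_concentration(mesh, injection_spec(C0 = cfg$C0_mg_cc))
  series <- run_transport(ops, Ci, dt = cfg$dt_s,
                          horizon = cfg$horizon_h * 3600,
                          store_times = cfg$store_h * 3600)
  summary <- list(
    solute = ss$label,
    center_mg_cc = stats::setNames(series$C[1, ],
                                   paste0("h", series$times / 3600)),
    ledger_closure = ledger_closure_error(series),
    retained_fraction = series$ledger$mass[nrow(series$ledger)] /
      series$ledger$mass[1])
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(series$times))
      write_mesh_vtk(mesh,
        file.path(cfg$outdir, sprintf("concentration_t%gh.vtk",
                                      series$times[i] / 3600)),
        point_data = list(concentration_mg_cc = series$C[, i]))
    utils::write.csv(series$ledger,
                     file.path(cfg$outdir, "mass_ledger.csv"),
                     row.names = FALSE)
    write_summary_json(summary,
                       file.path(cfg$outdir, "transport_summary.json"))
  }
  list(series = series, summary = summary)
}

#' Parameter sweeps
#'
#' Runs a family of scenarios varying one factor and tabulates the
#' summaries. Supported variables: `"alpha"` (global-K rescaling to target
#' resistance values), `"VN"` (presets baseline/vn50/vn100), `"Rnt"`
#' (necrotic radius; also reports the critical necrotic radius), `"PV"`
#' (microvascular pressure), `"size"` (particle diameter [nm]), `"carrier"`
#' (carrier presets), `"deg_diff"` (degradation-rate x diffusivity grid;
#' `values` is a list with `tau_1_s` and `D_cm2_s`). Flow sweeps use the
#' radial closed form (fast, exact); transport sweeps run the FEM chain.
#'
#' @param cfg A [scenario_config()] whose `sweep` field is
#'   `list(variable =, values =)`.
#' @return A data frame, one row per sweep value; for `"Rnt"` the critical
#'   necrotic radius is attached as attribute `R_CN`.
#' @export
run_sweep <- function(cfg) {
  stopifnot(!is.null(cfg$sweep))
  var <- cfg$sweep$variable; vals <- cfg$sweep$values
  geom <- tumor_geometry(cfg$Rnt_cm, cfg$Rvt_cm, cfg$Rht_cm)
  flow_row <- function(cfg1) {
    pl <- .cfg_parameters(cfg1)
    g <- tumor_geometry(cfg1$Rnt_cm, cfg1$Rvt_cm, cfg1$Rht_cm)
    co <- region_coefficients(pl$params, pl$lymph, R_ref = cfg1$Rvt_cm)
    s <- summary(solve_radial_pressure(g, co, cfg1$symmetry))
    data.frame(P_center_mmHg = s$center_pressure,
               P_min_mmHg = s$min_pressure,
               v_max_cm_s = s$max_velocity,
               r_at_vmax_cm = s$argmax_radius,
               alpha_viable = co$viable$alpha)
  }
  if (var == "alpha") {
    rows <- lapply(vals, function(a) {
      cfg1 <- cfg; cfg1$alpha_target <- a
      cbind(alpha = a, flow_row(cfg1))
    })
    return(do.call(rbind, rows))
  }
  if (var == "VN") {
    rows <- lapply(vals, function(p) {
      cfg1 <- cfg; cfg1$preset <- p
      cbind(preset = p, flow_row(cfg1))
    })
    return(do.call(rbind, rows))
  }
  if (var == "Rnt") {
    rows <- lapply(vals, function(rn) {
      cfg1 <- cfg; cfg1$Rnt_cm <- rn
      cbind(Rnt_cm = rn, flow_row(cfg1))
    })
    out <- do.call(rbind, rows)
    pl <- .cfg_parameters(cfg)
    co <- region_coefficients(pl$params, pl$lymph, R_ref = cfg$Rvt_cm)
    attr(out, "R_CN") <- critical_necrotic_radius(geom, co,
                                                  symmetry = cfg$symmetry)$R_CN
    return(out)
  }
  if (var == "PV") {
    rows <- lapply(vals, function(pv) {
      cfg1 <- cfg; cfg1$PV_mmHg <- pv
      cbind(PV_mmHg = pv, flow_row(cfg1))
    })
    return(do.call(rbind, rows))
  }
  if (var == "size") {
    rows <- lapply(vals, function(sz) {
      cfg1 <- cfg; cfg1$size_nm <- sz; cfg1$carrier <- NULL
      res <- run_transport_scenario(cfg1)
      data.frame(size_nm = sz,
                 C_center_24h = center_concentration(res$series, 24 * 3600),
                 retained = res$summary$retained_fraction)
    })
    return(do.call(rbind, rows))
  }
  if (var == "carrier") {
    rows <- lapply(vals, function(nm) {
      cfg1 <- cfg; cfg1$carrier <- nm
      res <- run_transport_scenario(cfg1)
      data.frame(carrier = nm,
                 C_center_3h = center_concentration(res$series, 3 * 3600),
                 C_center_24h = center_concentration(res$series, 24 * 3600),
                 retained = res$summary$retained_fraction)
    })
    return(do.call(rbind, rows))
  }
  if (var == "deg_diff") {
    grid <- expand.grid(tau_1_s = vals$tau_1_s, D_cm2_s = vals$D_cm2_s)
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      cfg1 <- cfg
      cfg1$carrier <- NULL
      res <- local({
        pl <- .cfg_parameters(cfg1)
        g <- tumor_geometry(cfg1$Rnt_cm, cfg1$Rvt_cm, cfg1$Rht_cm)
        co <- region_coefficients(pl$params, pl$lymph)
        mesh <- build_disc_mesh(g, cfg1$h_max_cm, order = cfg1$order)
        fem <- solve_pressure(assemble_pressure_system(mesh, co))
        vel <- project_velocity(fem)
        ss <- solute_spec(nr = NA,
          D_override = c(tumor = grid$D_cm2_s[i], normal = grid$D_cm2_s[i]),
          tau_override = c(tumor = grid$tau_1_s[i], normal = grid$tau_1_s[i]),
          label = sprintf("tau=%g D=%g", grid$tau_1_s[i], grid$D_cm2_s[i]))
        ops <- assemble_transport_operators(mesh, fem, vel, pl$params, ss)
        Ci <- build_initial_concentration(mesh,
                                          injection_spec(C0 = cfg1$C0_mg_cc))
        run_transport(ops, Ci, dt = cfg1$dt_s,
                      horizon = cfg1$horizon_h * 3600,
                      store_times = cfg1$store_h * 3600)
      })
      data.frame(tau_1_s = grid$tau_1_s[i], D_cm2_s = grid$D_cm2_s[i],
                 C_center_24h = center_concentration(res, 24 * 3600))
    })
    return(do.call(rbind, rows))
  }
  stop("unknown sweep variable: ", var)
}

#' Mesh-independence study
#'
#' Runs the flow solve on the refinement ladder and tabulates center
#' pressures and successive L2 profile differences against the closed-form
#' radial solution.
#'
#' @param cfg A [scenario_config()].
#' @param h Ladder of maximum edge lengths [cm].
#' @return Data frame with one row per mesh (h, elements, nodes, P_center,
#'   l2 error vs oracle, successive center-pressure difference).
#' @export
mesh_independence <- function(cfg = scenario_config(),
                              h = c(0.2, 0.1, 0.05, 0.03, 0.01)) {
  pl <- .cfg_parameters(cfg)
  geom <- tumor_geometry(cfg$Rnt_cm, cfg$Rvt_cm, cfg$Rht_cm)
  co <- region_coefficients(pl$params, pl$lymph, R_ref = cfg$Rvt_cm)
  oracle <- solve_radial_pressure(geom, co, cfg$symmetry)
  rows <- lapply(h, function(hh) {
    mesh <- build_disc_mesh(geom, hh, order = cfg$order)
    fem <- solve_pressure(assemble_pressure_system(mesh, co))
    cmpo <- fem_vs_radial(fem, oracle)
    data.frame(h_cm = hh, elements = nrow(mesh$elements),
               nodes = nrow(mesh$nodes), P_center_mmHg = fem$P[1],
               l2_rel_vs_oracle = cmpo$l2_rel, linf_rel = cmpo$linf_rel)
  })
  out <- do.call(rbind, rows)
  out$dP_center_rel <- c(NA, abs(diff(out$P_center_mmHg)) /
                              out$P_center_mmHg[-nrow(out)])
  out
}

#' Named scenario presets for the result studies
#'
#' Each study in the results program has a named preset configuration:
#' `fig07_alpha` (resistance sweep), `fig09_vn` (vascular-normalization
#' levels with/without lymphatic dynamics), `fig14_rnt_pv` (necrotic-radius
#' and microvascular-pressure sweeps), `fig16_sizes` (particle-size sweep),
#' `fig18_carriers` (carrier comparison at 100 mg/cc), `fig20_deg_diff`
#' (degradation x diffusivity grid).
#'
#' @param name Preset name.
#' @return A [scenario_config()] with its `sweep` filled in.
#' @export
scenario_preset <- function(name = c("fig07_alpha", "fig09_vn",
                                     "fig14_rnt_pv", "fig16_sizes",
                                     "fig18_carriers", "fig20_deg_diff")) {
  name <- match.arg(name)
  switch(name,
    fig07_alpha = scenario_config(
      sweep = list(variable = "alpha",
                   values = c(36.8, 15, 10, 5, 2, 1))),
    fig09_vn = scenario_config(
      sweep = list(variable = "VN",
                   values = c("baseline", "vn50", "vn100"))),
    fig14_rnt_pv = scenario_config(
      sweep = list(variable = "Rnt",
                   values = seq(0.1, 0.9, by = 0.1))),
    fig16_sizes = scenario_config(h_max_cm = 0.1, order = 1, dt_s = 300,
      horizon_h = 24,
      sweep = list(variable = "size", values = c(10, 20, 30, 50, 100))),
    fig18_carriers = scenario_config(h_max_cm = 0.1, order = 1, dt_s = 300,
      horizon_h = 24, C0_mg_cc = 100, store_h = c(1, 3, 6, 24),
      sweep = list(variable = "carrier",
                   values = c("doxorubicin", "dextran", "liposomal",
                              "peg_gold", "magnetic"))),
    fig20_deg_diff = scenario_config(h_max_cm = 0.1, order = 1, dt_s = 300,
      horizon_h = 24,
      sweep = list(variable = "deg_diff",
                   values = list(tau_1_s = c(5.8e-4, 5.8e-6, 5.8e-8),
                                 D_cm2_s = c(2.3e-8, 2.3e-7, 2.3e-6)))))
}
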