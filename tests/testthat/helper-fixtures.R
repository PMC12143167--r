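# Shared fixtures, memoized so expensive meshes/solves are built once per run.

.fix <- new.env(parent = emptyenv())

.memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

fix_geom <- function() tumor_geometry()

fix_mesh <- function(h = 0.1, order = 1) {
  .memo(sprintf("mesh_%g_%d", h, order),
        build_disc_mesh(fix_geom(), h, order = order))
}

fix_coeffs <- function(preset = "baseline", PL = 0) {
  params <- switch(preset, baseline = baseline_parameters(),
                   vn50 = vn_parameters(50), vn100 = vn_parameters(100))
  region_coefficients(params, lymphatic_parameters(PL = PL))
}

fix_flow <- function(h = 0.1, order = 1, preset = "baseline", PL = 0) {
  .memo(sprintf("flow_%g_%d_%s_%g", h, order, preset, PL), {
    sys <- assemble_pressure_system(fix_mesh(h, order),
                                    fix_coeffs(preset, PL))
    solve_pressure(sys)
  })
}

fix_velocity <- function(h = 0.1, order = 1, preset = "baseline", PL = 0) {
  .memo(sprintf("vel_%g_%d_%s_%g", h, order, preset, PL),
        project_velocity(fix_flow(h, order, preset, PL)))
}

# a velocity field that is identically zero (for pure-diffusion/reaction runs)
zero_velocity <- function(flow) {
  v <- project_velocity(flow)
  v$U[] <- 0; v$V[] <- 0
  v
}

# reuse a solved flow but strip the solute exchange pathways: vascular
# permeability and lymphatic filtration set to zero (neither affects the
# already-solved pressure/velocity we pair it with in these tests)
flow_no_exchange <- function(flow) {
  pp <- baseline_parameters()
  for (r in names(pp)) pp[[r]]$Pperm <- 0
  flow$coeffs <- region_coefficients(pp,
    lymphatic_parameters(LPL_SLV = 0, PL = 0, functional = FALSE))
  flow
}
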