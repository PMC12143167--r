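test_that("effective pressure reproduces the regional filtration-stop values", {
  bp <- baseline_parameters()
  expect_equal(effective_pressure(bp$viable), 11.5)
  expect_equal(effective_pressure(bp$healthy), 6.5)
  # osmosis off: PEF collapses to the microvascular pressure
  rp <- bp$viable; rp$sigma_s <- 0
  expect_equal(effective_pressure(rp), rp$PV)
})

test_that("steady-state pressure is the conductance-weighted average", {
  bp <- baseline_parameters()
  expect_identical(steady_state_pressure(bp$necrotic), 0)
  expect_equal(steady_state_pressure(bp$viable), 11.5)
  expect_equal(steady_state_pressure(bp$healthy, lymphatic_parameters(PL = 0)),
               1.2115385, tolerance = 1e-6)
  expect_equal(steady_state_pressure(bp$healthy, lymphatic_parameters(PL = -4)),
               -2.0428994, tolerance = 1e-6)
  # invariance under joint rescaling of both conductances
  rp <- bp$healthy; lp <- lymphatic_parameters(PL = -2)
  ref <- steady_state_pressure(rp, lp)
  rp$Lp <- rp$Lp * 7; lp$LPL_SLV <- lp$LPL_SLV * 7
  expect_equal(steady_state_pressure(rp, lp), ref)
  # degenerate conductance outside the necrotic core is a configuration error
  rp$Lp <- 0; rp$SV <- 0; lp$LPL_SLV <- 0
  expect_error(steady_state_pressure(rp, lp), "conductance")
})

test_that("flow resistance alpha matches the printed normalization series", {
  lp0 <- lymphatic_parameters(PL = 0)
  expect_equal(flow_resistance_alpha(vn_parameters(0)$viable, lp0, R = 1),
               36.8, tolerance = 1e-3)
  expect_equal(flow_resistance_alpha(vn_parameters(50)$viable, lp0, R = 1),
               29.3, tolerance = 1e-3)
  expect_equal(flow_resistance_alpha(vn_parameters(100)$viable, lp0, R = 1),
               17.18, tolerance = 1e-3)
  expect_identical(flow_resistance_alpha(baseline_parameters()$necrotic), 0)
  # alpha is monotone: increasing in Lp*S/V, decreasing in K, -> 0 as K -> Inf
  rp <- baseline_parameters()$viable
  a0 <- flow_resistance_alpha(rp)
  rp2 <- rp; rp2$Lp <- rp$Lp * 2
  expect_gt(flow_resistance_alpha(rp2), a0)
  rp3 <- rp; rp3$K <- rp$K * 1e12
  expect_lt(flow_resistance_alpha(rp3), 1e-3)
  rp4 <- rp; rp4$K <- 0
  expect_error(flow_resistance_alpha(rp4), "positive")
})

test_that("Starling source and lymphatic sink evaluate the frozen rates", {
  bp <- baseline_parameters()
  expect_equal(vascular_source_phiVS(bp$viable, 11.5), 0)
  expect_equal(vascular_source_phiVS(bp$viable, 0), 6.44e-4, tolerance = 1e-10)
  expect_equal(vascular_source_phiVS(bp$necrotic, 3), 0)
  lp <- lymphatic_parameters(PL = 0)
  expect_equal(lymphatic_sink_phiLS(lp, lp$PL), 0)
  expect_equal(lymphatic_sink_phiLS(lp, 1.2116), 1.33276e-5, tolerance = 1e-5)
  expect_equal(lymphatic_sink_phiLS(lp, 5, region = "viable"), 0)
})

test_that("Stokes-Einstein and hindered diffusivity follow the size scaling", {
  d10 <- stokes_einstein_diffusivity(solute_spec(nr = 5e-9))
  expect_equal(d10, 4.539e-7, tolerance = 1e-3)
  expect_equal(stokes_einstein_diffusivity(solute_spec(nr = 1e-8)), d10 / 2)
  expect_equal(stokes_einstein_diffusivity(solute_spec(nr = 5e-8)), d10 / 10)
  expect_error(stokes_einstein_diffusivity(solute_spec(nr = NA,
    D_override = c(tumor = 1e-7, normal = 1e-7))), "positive")
  expect_equal(effective_diffusivity(1, 0.6), 0.5)
  expect_equal(effective_diffusivity(1, 1), 1)
  expect_equal(effective_diffusivity(1, 0.4), 0.8 / 2.6)
  expect_error(effective_diffusivity(1, 1.2), "void fraction")
})

test_that("Peclet factor is positive, smooth through 0 and monotone", {
  expect_equal(peclet_factor(0), 1)
  pe <- c(-30, -5, -1e-7, 0, 1e-7, 1, 5, 30, 300)
  f <- peclet_factor(pe)
  expect_true(all(f > 0))
  expect_true(all(diff(f) < 0))            # monotone decreasing
  expect_equal(peclet_factor(1e-6), peclet_factor(1.0000001e-6),
               tolerance = 1e-6)           # continuous at the series switch
})

test_that("transvascular extraction has the right limits and magnitudes", {
  bp <- baseline_parameters(); ss <- solute_spec()
  PSV <- bp$viable$Pperm * bp$viable$SV
  # Pe -> 0: coefficient -> P * S/V
  expect_equal(transvascular_extraction(bp$viable, ss, 0 * PSV), PSV)
  # viable baseline at P_IS = 0: Pe ~ 281 (outward filtration), coef ~ 0
  phi <- vascular_source_phiVS(bp$viable, 0)
  pe <- phi * (1 - ss$sigma_rc) / PSV
  expect_equal(pe, 281, tolerance = 1e-3)
  # resorption side: solvent-drag limit |phi_VS| (1 - sigma_rc)
  phi_neg <- -1e-3
  expect_equal(transvascular_extraction(bp$viable, ss, phi_neg),
               abs(phi_neg) * (1 - ss$sigma_rc), tolerance = 1e-6)
  expect_equal(transvascular_extraction(bp$necrotic, ss, 1e-3), 0)
})

test_that("all tabulated parameter rows give finite coefficients; 0% VN is the baseline", {
  for (lvl in c(0, 50, 100)) for (pl in c(0, -4)) {
    co <- region_coefficients(vn_parameters(lvl), lymphatic_parameters(PL = pl))
    vals <- unlist(lapply(co, function(rc)
      c(rc$K, rc$beta2, rc$PSS, rc$PEF, rc$alpha, rc$sigma)))
    expect_true(all(is.finite(vals)))
    expect_identical(co$necrotic$beta2, 0)
    expect_identical(co$necrotic$PSS, 0)
    expect_equal(co$viable$alpha^2, co$viable$beta2)  # R_ref = 1 cm
  }
  expect_equal(vn_parameters(0), baseline_parameters())
  for (nm in c("doxorubicin", "dextran", "liposomal", "peg_gold", "magnetic")) {
    sc <- solute_region_coefficients(baseline_parameters(), carrier_spec(nm))
    expect_true(all(is.finite(c(sc$D, sc$tau))))
    expect_identical(unname(sc$D["necrotic"]), unname(sc$D["viable"]))
  }
})
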