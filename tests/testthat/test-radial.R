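test_that("closed form matches the finite-volume oracle on the baseline problem", {
  geom <- fix_geom()
  for (sym in c("cylindrical", "spherical")) {
    co <- fix_coeffs("baseline")
    sol <- solve_radial_pressure(geom, co, sym)
    fd <- fd_radial_pressure(geom, co, nu = if (sym == "spherical") 2 else 1)
    err <- max(abs(fd$P - predict(sol, fd$r))) / max(abs(fd$P))
    expect_lt(err, 1e-6)
  }
})

test_that("closed form matches the finite-volume oracle on randomized physiologies", {
  set.seed(7)
  geom <- fix_geom()
  worst <- 0
  for (k in 1:20) {
    pp <- baseline_parameters()
    f <- function() runif(1, 0.3, 3)
    pp$viable$Lp <- pp$viable$Lp * f(); pp$viable$K <- pp$viable$K * f()
    pp$viable$SV <- pp$viable$SV * f()
    pp$healthy$Lp <- pp$healthy$Lp * f(); pp$healthy$K <- pp$healthy$K * f()
    pp$necrotic$K <- pp$viable$K
    lp <- lymphatic_parameters(LPL_SLV = 1.1e-5 * f(), PL = runif(1, -4, 0))
    co <- region_coefficients(pp, lp)
    nu <- sample(1:2, 1)
    sol <- solve_radial_pressure(geom, co,
                                 if (nu == 2) "spherical" else "cylindrical")
    fd <- fd_radial_pressure(geom, co, nu = nu)
    worst <- max(worst, max(abs(fd$P - predict(sol, fd$r))) / max(abs(fd$P)))
  }
  expect_lt(worst, 1e-6)
})

test_that("a single homogeneous region with zero-flux boundary is constant at PSS", {
  geom <- fix_geom()
  co <- fix_coeffs("baseline")
  # make all three regions identical to the viable one
  co$necrotic <- co$viable; co$necrotic$name <- "necrotic"
  co$healthy <- co$viable;  co$healthy$name <- "healthy"
  for (sym in c("cylindrical", "spherical")) {
    sol <- solve_radial_pressure(geom, co, sym)
    rr <- seq(0, geom$Rht, by = 0.01)
    expect_equal(predict(sol, rr), rep(co$viable$PSS, length(rr)),
                 tolerance = 1e-9)
    expect_equal(radial_velocity(sol, rr), rep(0, length(rr)),
                 tolerance = 1e-12)
  }
})

test_that("center pressure reproduces the vascular-normalization series", {
  geom <- fix_geom()
  expect_equal(center_pressure(solve_radial_pressure(geom, fix_coeffs("baseline"))),
               11.5, tolerance = 1e-4)
  expect_equal(center_pressure(solve_radial_pressure(geom, fix_coeffs("vn50"))),
               11.275, tolerance = 1e-4)
  expect_equal(center_pressure(solve_radial_pressure(geom,
                 fix_coeffs("vn100", PL = -4))),
               11.048, tolerance = 1e-3)
})

test_that("radial velocity vanishes at the center and outer boundary and peaks at the rim", {
  geom <- fix_geom()
  sol <- solve_radial_pressure(geom, fix_coeffs("baseline"))
  expect_equal(radial_velocity(sol, 0), 0, tolerance = 1e-12)
  expect_lt(abs(radial_velocity(sol, geom$Rht)),
            1e-6 * summary(sol)$max_velocity)
  s <- summary(sol)
  expect_gte(s$argmax_radius, 0.95)
  expect_lte(s$argmax_radius, 1.05)
  expect_error(radial_velocity(sol, 2.5), "outside")
})

test_that("pressure respects the maximum principle and decreases with necrotic size", {
  geom <- fix_geom()
  co <- fix_coeffs("baseline")
  sol <- solve_radial_pressure(geom, co)
  rr <- seq(0, geom$Rht, by = 1e-3)
  P <- predict(sol, rr)
  expect_gte(min(P), co$healthy$PSS - 1e-9)
  expect_lte(max(P), co$viable$PEF + 1e-9)
  p0 <- vapply(seq(0.1, 0.95, by = 0.05), function(rn)
    center_pressure(solve_radial_pressure(
      tumor_geometry(rn, geom$Rvt, geom$Rht), co)), numeric(1))
  expect_true(all(diff(p0) <= 1e-9))
})

test_that("spherical and cylindrical plateaus agree in the thick-rim limit", {
  geom <- fix_geom()
  co <- fix_coeffs("baseline")  # beta * (Rvt - Rnt) ~ 18: deep plateau
  p1 <- center_pressure(solve_radial_pressure(geom, co, "cylindrical"))
  p2 <- center_pressure(solve_radial_pressure(geom, co, "spherical"))
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("critical necrotic radius is ~0.9 cm at baseline and shrinks with alpha", {
  geom <- fix_geom()
  cn <- critical_necrotic_radius(geom, fix_coeffs("baseline"))
  expect_true(cn$criterion_met)
  expect_equal(cn$R_CN, 0.9, tolerance = 0.012)
  co5 <- region_coefficients(scale_to_alpha(baseline_parameters(), 5),
                             lymphatic_parameters())
  cn5 <- critical_necrotic_radius(geom, co5)
  expect_lt(cn5$R_CN, cn$R_CN)
  # an (almost) infinitely stiff viable rim pushes R_CN to the last grid point
  co_inf <- region_coefficients(scale_to_alpha(baseline_parameters(), 2000),
                                lymphatic_parameters())
  cn_inf <- critical_necrotic_radius(geom, co_inf)
  expect_equal(cn_inf$R_CN, geom$Rvt - 0.01, tolerance = 1e-9)
})
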