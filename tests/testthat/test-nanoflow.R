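test_that("no-slip pore flow matches direct arithmetic and quartic scaling", {
  fl <- fluid_state(viscosity = 1e-3)
  m <- fx_membrane(tortuosity = 1.2)
  expect_equal(hagen_poiseuille_pore_flow(0, m, fl), 0)
  q <- hagen_poiseuille_pore_flow(1e5, m, fl)
  oracle <- pi * 1e5 / (8 * 1e-3 * 1.2 * 50e-6) * (1.7e-9 / 2)^4
  expect_equal(q, oracle, tolerance = 1e-12)
  expect_equal(q, 3.42e-25, tolerance = 2e-3)
  m2 <- fx_membrane(pore_diameter = 3.4e-9)
  expect_equal(hagen_poiseuille_pore_flow(1e5, m2, fl) / q, 16,
               tolerance = 1e-12)
  expect_error(hagen_poiseuille_pore_flow(-1, m, fl),
               class = "poreforce_domain_error")
})

test_that("slip-corrected flow reduces to no-slip at b = 0 and grows with b", {
  fl <- fluid_state(viscosity = 1e-3)
  m <- fx_membrane()
  q_hp <- hagen_poiseuille_pore_flow(1e5, m, fl)
  expect_equal(slip_pore_flow(1e5, m, 0, fl), q_hp, tolerance = 1e-15)
  q_slip <- slip_pore_flow(1e5, m, 100e-9, fl)
  expect_equal(q_slip, q_hp * (1 + 4 * 100e-9 / (1.7e-9 / 2)),
               tolerance = 1e-12)
  expect_equal(q_slip, 1.61e-22, tolerance = 2e-3)
  b <- seq(0, 500e-9, length.out = 20)
  expect_true(all(diff(slip_pore_flow(1e5, m, b, fl)) > 0))
  expect_error(slip_pore_flow(1e5, m, -1e-9, fl),
               class = "poreforce_domain_error")
})

test_that("enhancement factor equals 1 + 8b/d and round-trips exactly", {
  expect_equal(enhancement_factor(0, 1.7e-9), 1)
  expect_equal(enhancement_factor(100e-9, 1.7e-9), 1 + 800 / 1.7,
               tolerance = 1e-12)
  set.seed(7)
  for (i in 1:25) {
    b <- stats::runif(1, 0, 1e-6)
    d <- stats::runif(1, 1e-9, 5e-9)
    ef <- enhancement_factor(b, d)
    expect_equal(slip_length_from_enhancement(ef, d), b, tolerance = 1e-12)
  }
  expect_error(slip_length_from_enhancement(0.5, 1.7e-9),
               class = "poreforce_domain_error")
})

test_that("flow ratio Q_slip/Q_HP equals the enhancement factor identically", {
  set.seed(42)
  fl <- fluid_state()
  for (i in 1:1000) {
    d <- stats::runif(1, 0.5e-9, 5e-9)
    b <- stats::runif(1, 0, 1e-6)
    m <- membrane_spec("r", d, stats::runif(1, 1e-5, 1e-4),
                       porosity = stats::runif(1, 0.01, 0.2),
                       tortuosity = stats::runif(1, 1, 2))
    dp <- stats::runif(1, 1e3, 5e5)
    ratio <- slip_pore_flow(dp, m, b, fl) / hagen_poiseuille_pore_flow(dp, m, fl)
    if (abs(ratio - enhancement_factor(b, d)) > 1e-12 * ratio) {
      fail(sprintf("ratio mismatch at draw %d", i))
    }
  }
  succeed()
})

test_that("permeability normalises pressure to bar", {
  expect_equal(permeability(60, 1e5), 60)
  expect_equal(permeability(8, 1e5), 8)
  expect_equal(permeability(30, 2e5), 15)
  expect_error(permeability(30, 0), class = "poreforce_domain_error")
})

test_that("pore velocity reproduces the reported nominal velocities", {
  expect_equal(flux_to_pore_velocity(27, 0.034), 2.2e-4, tolerance = 5e-3)
  expect_equal(flux_to_pore_velocity(0, 0.034), 0)
  expect_equal(flux_to_pore_velocity(60, 0.034), 4.90e-4, tolerance = 1e-3)
  # 3.3 nm membrane: lower porosity raises the velocity at matched flux
  expect_equal(flux_to_pore_velocity(27, 0.019), 3.9e-4, tolerance = 2e-2)
  expect_error(flux_to_pore_velocity(27, 1.5), class = "poreforce_domain_error")
})

test_that("porosity from pore density follows the area formula", {
  expect_equal(porosity_from_pore_density(0, 1.7e-9), 0)
  expect_equal(porosity_from_pore_density(1.5e16, 1.7e-9), 0.034,
               tolerance = 2e-2)
  # quadratic in diameter
  expect_equal(porosity_from_pore_density(1e15, 2e-9) /
                 porosity_from_pore_density(1e15, 1e-9), 4, tolerance = 1e-12)
  expect_error(porosity_from_pore_density(1e20, 1e-7),
               class = "poreforce_consistency_error")
})

test_that("Peclet number and residence time follow their definitions", {
  expect_equal(peclet_number(0, 50e-6, 2.3e-9), 0)
  expect_equal(peclet_number(2.2e-4, 50e-6, 2.3e-9), 4.78, tolerance = 1e-3)
  expect_equal(peclet_number(10 * 1e-4, 50e-6, 2.3e-9) /
                 peclet_number(1e-4, 50e-6, 2.3e-9), 10, tolerance = 1e-12)
  m <- fx_membrane(thickness = 69e-6, tortuosity = 1.1)
  tau <- hydraulic_residence_time(m, 2.2e-4)
  expect_equal(tau, 0.345, tolerance = 2e-3)
  expect_gt(tau, 0.05); expect_lt(tau, 0.4)
  expect_equal(hydraulic_residence_time(m, 4.4e-4), tau / 2, tolerance = 1e-12)
  expect_error(hydraulic_residence_time(m, 0), class = "poreforce_domain_error")
  # advection dominates at all studied fluxes on the thick membranes
  v <- flux_to_pore_velocity(c(6, 15, 30, 38, 57, 60), 0.034)
  expect_true(all(peclet_number(v, 47e-6, 2.3e-9) > 1))
})

test_that("Stokes-Einstein diffusivity matches arithmetic and inverts", {
  fl <- fluid_state()
  d_e2 <- stokes_einstein_diffusivity(0.8e-9, fl)
  expect_equal(d_e2, 1.380649e-23 * 296.15 / (3 * pi * fl$viscosity * 0.8e-9),
               tolerance = 1e-12)
  expect_equal(d_e2, 5.8e-10, tolerance = 1e-2)
  expect_equal(diameter_from_diffusivity(d_e2, fl), 0.8e-9, tolerance = 1e-12)
  expect_error(stokes_einstein_diffusivity(0), class = "poreforce_domain_error")
})

test_that("diffusion time uses the 1-D mean-square-displacement convention", {
  expect_equal(diffusion_time(0, 1e-9), 0)
  expect_equal(diffusion_time(0.45e-9, 5.8e-10), 1.746e-10, tolerance = 1e-3)
  expect_equal(diffusion_time(2e-9, 1e-9) / diffusion_time(1e-9, 1e-9), 4,
               tolerance = 1e-12)
  expect_error(diffusion_time(1e-9, 0), class = "poreforce_domain_error")
})

test_that("reported enhancement range maps to slip lengths of order 150-1300 nm", {
  # documented consistency check: the reported EF band, inverted through
  # EF = 1 + 8b/d on the 1.7 nm pores, gives b in [153, 1317] nm (larger
  # than the separately reported slip-length band, which derives from
  # different measured permeabilities)
  b <- slip_length_from_enhancement(c(720, 6200), 1.7e-9)
  expect_equal(b * 1e9, c(152.8, 1317.3), tolerance = 1e-3)
})

test_that("slip length inverts from permeability and clamps sub-no-slip input", {
  fl <- fluid_state()
  dens <- 0.034 / (pi * (1.7e-9)^2 / 4)
  m <- membrane_spec("m", 1.7e-9, 50e-6, porosity = 0.034,
                     pore_areal_density = dens, tortuosity = 1.2)
  b_true <- 200e-9
  lp <- si_to_flux(slip_pore_flow(1e5, m, b_true, fl) * dens)
  expect_equal(slip_length_from_permeability(lp, m, fl), b_true,
               tolerance = 1e-10)
  lp_low <- si_to_flux(hagen_poiseuille_pore_flow(1e5, m, fl) * dens) / 2
  expect_warning(b0 <- slip_length_from_permeability(lp_low, m, fl))
  expect_equal(b0, 0)
})

test_that("flow solution assembles consistent per-pore and membrane quantities", {
  fl <- fluid_state()
  m <- fx_membrane()
  sol <- flow_solution(1e5, m, 100e-9, fl)
  expect_gte(sol$q_slip, sol$q_hp)
  expect_equal(sol$enhancement_factor, sol$q_slip / sol$q_hp, tolerance = 1e-12)
  expect_gt(sol$permeability, 0)
})

test_that("timescale report combines Peclet, residence and diffusion times", {
  m <- fx_membrane()
  op <- operating_point(27, m)
  ts <- timescale_report(op, fx_e2())
  expect_gt(ts$peclet, 1)
  expect_true(ts$residence_time > 0.05 && ts$residence_time < 0.4)
  expect_lt(ts$wall_diffusion_time, 1e-9)
  expect_equal(ts$solute_diffusivity, 5.8e-10, tolerance = 1e-2)
})
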