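test_that("drag force is the Stokes expression, linear in each factor", {
  e2 <- fx_e2()
  expect_equal(drag_force(0, e2), 0)
  fl <- fluid_state()
  f <- drag_force(6e-5, e2, fl)
  expect_equal(f, 3 * pi * fl$viscosity * 0.8e-9 * 6e-5, tolerance = 1e-12)
  expect_equal(f * 1e12, 4.2e-4, tolerance = 1e-2)
  set.seed(3)
  for (i in 1:50) {
    mu <- stats::runif(1, 5e-4, 2e-3)
    d <- stats::runif(1, 0.3e-9, 2e-9)
    v <- stats::runif(1, 1e-6, 1e-3)
    s <- fx_e2(hydrodynamic_diameter = d)
    flv <- fluid_state(viscosity = mu)
    expect_equal(drag_force(v, s, flv), 3 * pi * mu * d * v, tolerance = 1e-12)
  }
  expect_error(drag_force(-1, e2), class = "poreforce_domain_error")
})

test_that("adhesive force hits ~110 pN at contact and decays quartically", {
  e2 <- fx_e2()
  expect_equal(adhesive_force(e2) * 1e12, 110, tolerance = 1e-2)
  expect_equal(adhesive_force(fx_e2(hamaker_constant = 0)), 0)
  g <- c(0.3e-9, 3e-9)
  fa <- adhesive_force(e2, g)
  expect_equal(fa[1] / fa[2], 1e4, tolerance = 1e-12)
  expect_true(all(diff(adhesive_force(e2, seq(0.1e-9, 2e-9, length.out = 40))) < 0))
  expect_error(adhesive_force(e2, 0), class = "poreforce_domain_error")
})

test_that("repulsion balances adhesion at the contact gap and decays as g^-10", {
  e2 <- fx_e2()
  g0 <- e2$contact_gap
  expect_equal(repulsive_force(e2, g0), adhesive_force(e2, g0),
               tolerance = 1e-12)
  expect_equal(repulsive_force(e2, 2 * g0) / repulsive_force(e2, g0), 2^-10,
               tolerance = 1e-12)
  # net radial force pulls toward the wall outside the contact gap
  g <- seq(1.01 * g0, 10 * g0, length.out = 50)
  expect_true(all(adhesive_force(e2, g) - repulsive_force(e2, g) > 0))
  # and pushes away inside it
  expect_lt(adhesive_force(e2, 0.8 * g0) - repulsive_force(e2, 0.8 * g0), 0)
})

test_that("equilibrium gap recovers the contact gap across solutes", {
  expect_equal(equilibrium_gap(fx_e2()), 0.3e-9, tolerance = 1e-4)
  expect_equal(equilibrium_gap(fx_e2(contact_gap = 0.32e-9)), 0.32e-9,
               tolerance = 1e-4)
  set.seed(17)
  for (i in 1:100) {
    s <- fx_e2(hamaker_constant = stats::runif(1, 1e-21, 1e-19))
    expect_equal(equilibrium_gap(s), s$contact_gap, tolerance = 1e-3)
  }
})

test_that("friction threshold calibrates to the observed drag threshold", {
  e2 <- fx_e2()
  tm <- threshold_model()
  # velocity anchor: threshold is the drag at 3.0e-4 m/s, ~2.2e-3 pN
  expect_equal(tm$drag_threshold * 1e12, 2.2e-3, tolerance = 5e-2)
  expect_equal(friction_threshold(e2, tm), tm$drag_threshold, tolerance = 1e-12)
  # force anchor reproduces the reported threshold exactly
  tmf <- threshold_model(anchor = "force")
  expect_equal(friction_threshold(e2, tmf), 2.2e-15, tolerance = 1e-12)
  # friction scales linearly with the Hamaker constant
  s2 <- fx_e2(hamaker_constant = 2 * e2$hamaker_constant)
  expect_equal(friction_threshold(s2, tm), 2 * friction_threshold(e2, tm),
               tolerance = 1e-12)
})

test_that("regime classification is monotone in velocity", {
  expect_equal(classify_regime(0, 1e-15), "adsorptive")
  e2 <- fx_e2()
  tm <- threshold_model()
  fl <- fluid_state()
  v <- seq(0, 1e-3, length.out = 200)
  reg <- classify_regime(drag_force(v, e2, fl), friction_threshold(e2, tm))
  flips <- sum(diff(reg == "adsorptive") != 0)
  expect_lte(flips, 1)
  expect_equal(reg[1], "adsorptive")
  expect_equal(reg[length(reg)], "advective-clearance")
})

test_that("E2 regimes at the studied fluxes match the observed adsorption pattern", {
  m <- fx_membrane()
  e2 <- fx_e2()
  prof <- force_profile(m, e2, c(6, 15, 30, 38, 57))
  expect_equal(prof$regime[prof$flux <= 30], rep("adsorptive", 3))
  expect_equal(prof$regime[prof$flux >= 38], rep("advective-clearance", 2))
})

test_that("transition flux for E2 on the 1.7 nm membrane lies between 30 and 38", {
  m <- fx_membrane()
  e2 <- fx_e2()
  fstar <- regime_transition_flux(m, e2)
  expect_gt(fstar, 30)
  expect_lt(fstar, 38)
  # closed form agrees with a bisection over classified profiles
  lo <- 10; hi <- 80
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (force_profile(m, e2, mid)$regime == "adsorptive") lo <- mid else hi <- mid
  }
  expect_equal((lo + hi) / 2, fstar, tolerance = 1e-6)
})

test_that("force profile reports the five-orders adhesion/drag separation", {
  prof <- force_profile(fx_membrane(), fx_e2(), 27)
  expect_equal(prof$adhesion_drag_ratio, 7e4, tolerance = 5e-2)
  expect_equal(prof$f_adhesive, prof$f_repulsive, tolerance = 1e-6)
  zero <- force_profile(fx_membrane(), fx_e2(), 0)
  expect_equal(zero$f_drag, 0)
  expect_equal(zero$regime, "adsorptive")
})

test_that("regime is unchanged across the studied pore diameters at matched flux", {
  e2 <- fx_e2()
  for (fx in c(6, 27, 57)) {
    regs <- vapply(default_membranes(), function(m) {
      force_profile(m, e2, fx)$regime
    }, character(1))
    expect_lte(length(unique(regs[c("vacnt_1p7", "vacnt_2p6")])), 1)
  }
})

test_that("adhesion ranking follows hormone diameter under a uniform Hamaker constant", {
  ranked <- rank_by_adhesion(fx_hormones())
  expect_equal(ranked$solute, c("P", "T", "E2", "E1"))
  expect_true(all(diff(ranked$f_adhesive) < 0))
  two <- rank_by_adhesion(list(
    a = solute_spec("a", 100, 1e-9), b = solute_spec("b", 100, 2e-9)
  ))
  expect_equal(two$f_adhesive[two$solute == "b"] /
                 two$f_adhesive[two$solute == "a"], 8, tolerance = 1e-12)
  one <- rank_by_adhesion(fx_hormones()["E2"])
  expect_equal(nrow(one), 1)
  expect_error(rank_by_adhesion(list(x = "not a solute")),
               class = "poreforce_domain_error")
})
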