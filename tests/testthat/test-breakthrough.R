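test_that("curve construction validates volumes, concentrations and consistency", {
  expect_error(fx_curve(c(0, 10, 10), c(0, 0.5, 1)), "row 3",
               class = "poreforce_parse_error")
  expect_error(fx_curve(c(0, 20, 10), c(0, 0.5, 1)),
               class = "poreforce_parse_error")
  expect_error(fx_curve(c(0, 10), c(-0.1, 0.5)),
               class = "poreforce_parse_error")
  expect_error(
    breakthrough_curve(data.frame(volume_mL = c(0, 10)),
                       feed_concentration = 100, membrane_area = 2),
    class = "poreforce_parse_error"
  )
  # absolute concentrations imply the relative ones
  bt <- breakthrough_curve(
    data.frame(volume_mL = c(0, 10, 20), c_ngL = c(10, 50, 100)),
    feed_concentration = 100, membrane_area = 2
  )
  expect_equal(bt$c_over_c0, c(0.1, 0.5, 1))
  # inconsistent dual columns are rejected
  expect_error(
    breakthrough_curve(
      data.frame(volume_mL = c(0, 10), c_over_c0 = c(0.1, 0.5),
                 c_ngL = c(10, 60)),
      feed_concentration = 100, membrane_area = 2
    ),
    class = "poreforce_parse_error"
  )
})

test_that("values below the detection limit are floored and flagged", {
  bt <- breakthrough_curve(
    data.frame(volume_mL = c(0, 10, 20), c_ngL = c(0.05, 0.2, 50)),
    feed_concentration = 100, membrane_area = 2
  )
  expect_equal(bt$c_ngL[1], 0.2)
  expect_equal(bt$below_detection, c(TRUE, FALSE, FALSE))
})

test_that("file round trip preserves data and metadata", {
  path <- withr::local_tempfile(fileext = ".csv")
  bt <- fx_curve(c(0, 10, 20, 30), c(0, 0.4, 0.8, 1), flux = 27,
                 label = "roundtrip")
  write_breakthrough(bt, path)
  back <- read_breakthrough(path)
  expect_equal(back$volume_mL, bt$volume_mL)
  expect_equal(back$c_over_c0, bt$c_over_c0, tolerance = 1e-12)
  expect_equal(attr(back, "feed_concentration"), 100)
  expect_equal(attr(back, "flux"), 27)
  expect_equal(attr(back, "label"), "roundtrip")
  # byte-identical rewrite (deterministic output contract)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_breakthrough(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("reading requires metadata and a concentration column", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("volume_mL,c_over_c0", "0,0", "10,0.5"), path)
  expect_error(read_breakthrough(path), class = "poreforce_parse_error")
  bt <- read_breakthrough(path, feed_concentration = 100, membrane_area = 2)
  expect_equal(nrow(bt), 2)
  expect_error(read_breakthrough("no/file.csv"), class = "poreforce_io_error")
})

test_that("adsorbed mass matches closed-form areas for piecewise-linear curves", {
  # full capture for 10 mL then instant breakthrough: 0.1 ng/mL * 10 mL / 2 cm2
  step <- fx_curve(c(0, 10, 10.000001, 40), c(0, 0, 1, 1))
  expect_equal(specific_adsorbed_mass(step)$q_ads_A, 0.5, tolerance = 1e-6)
  # linear rise 0 -> 1 over 20 mL: triangle area
  tri <- fx_curve(c(0, 20), c(0, 1))
  expect_equal(specific_adsorbed_mass(tri)$q_ads_A, 0.5, tolerance = 1e-12)
  # no deficit, no mass
  flat <- fx_curve(c(0, 10, 30), c(1, 1, 1))
  expect_equal(specific_adsorbed_mass(flat)$q_ads_A, 0)
  # randomised piecewise-linear oracle equivalence
  set.seed(23)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    v <- sort(stats::runif(n, 0, 100))
    r <- stats::runif(n, 0, 1.2)
    q <- specific_adsorbed_mass(fx_curve(v, r))$q_ads_A
    expect_equal(q, fx_pwl_mass(v, r), tolerance = 1e-12)
  }
})

test_that("evaluation volume interpolates and is bounded by the data", {
  bt <- fx_curve(c(0, 20, 40), c(0, 0.5, 1))
  # at 10 mL the linear curve is exactly interpolable
  expect_equal(specific_adsorbed_mass(bt, 10)$q_ads_A,
               fx_pwl_mass(c(0, 10), c(0, 0.25)), tolerance = 1e-12)
  expect_error(specific_adsorbed_mass(bt, 50), class = "poreforce_domain_error")
  expect_error(specific_adsorbed_mass(fx_curve(c(0, 10), c(0, 1))[1, ]),
               class = "poreforce_domain_error")
})

test_that("adsorbed mass is additive over contiguous volume intervals", {
  set.seed(5)
  v <- sort(stats::runif(9, 0, 90)); v <- c(0, v, 100)
  r <- stats::runif(11, 0, 1)
  bt <- fx_curve(v, r)
  q_all <- specific_adsorbed_mass(bt, 100)$q_ads_A
  q_a <- specific_adsorbed_mass(bt, 47)$q_ads_A
  # integral over [47, 100] recomputed from a shifted curve
  keep <- v >= 47
  v2 <- c(47, v[keep]); r2 <- c(stats::approx(v, r, 47)$y, r[keep])
  q_b <- specific_adsorbed_mass(fx_curve(v2, r2), 100)$q_ads_A
  expect_equal(q_a + q_b, q_all, tolerance = 1e-12)
})

test_that("doubling the membrane area halves the specific mass", {
  v <- c(0, 10, 30, 60); r <- c(0, 0.3, 0.7, 1)
  q1 <- specific_adsorbed_mass(fx_curve(v, r, area = 2))$q_ads_A
  q2 <- specific_adsorbed_mass(fx_curve(v, r, area = 4))$q_ads_A
  expect_equal(q1, 2 * q2, tolerance = 1e-12)
})

test_that("support subtraction differences masses and propagates uncertainty", {
  mk <- function(q_target, flux = 27) {
    # linear rise ending at c/c0 = 1, scaled to integrate to q_target:
    # q = c0_mL * V * (1 - r0) / (2 A) with c0_mL = 0.1, V = 65, A = 2
    r0 <- 1 - 2 * q_target * 2 / (0.1 * 65)
    specific_adsorbed_mass(fx_curve(c(0, 65), c(r0, 1), flux = flux), 65)
  }
  q_tot <- mk(0.60)
  q_sup <- mk(0.22)
  expect_equal(q_tot$q_ads_A, 0.60, tolerance = 1e-12)
  diff <- subtract_support(q_tot, q_sup)
  expect_equal(diff$q_ads_A, 0.38, tolerance = 1e-12)
  expect_equal(diff$sigma, sqrt(q_tot$sigma^2 + q_sup$sigma^2),
               tolerance = 1e-12)
  # subtracting a curve from itself gives zero, flagged insignificant
  zero <- subtract_support(q_tot, mk(0.60))
  expect_equal(zero$q_ads_A, 0, tolerance = 1e-12)
  expect_false(zero$significant)
  expect_match(attr(zero, "note"), "insignificant")
  # mismatched evaluation volumes and fluxes are rejected
  bad_vol <- specific_adsorbed_mass(fx_curve(c(0, 65), c(0.5, 1)), 50)
  expect_error(subtract_support(q_tot, bad_vol),
               class = "poreforce_domain_error")
  expect_error(subtract_support(q_tot, mk(0.22, flux = 50)),
               class = "poreforce_domain_error")
})

test_that("uncertainties add in quadrature for equal per-point sigmas", {
  bt <- fx_curve(c(0, 65), c(0.4, 0.8))
  a <- specific_adsorbed_mass(bt, 65)
  b <- specific_adsorbed_mass(bt, 65)
  d <- subtract_support(a, b)
  expect_equal(d$sigma, sqrt(2) * a$sigma, tolerance = 1e-12)
})

test_that("saturation plateau classifies retention, breakthrough and unsaturated tails", {
  v <- seq(0, 100, length.out = 15)
  ret <- fx_curve(v, pmin(0.4, 0.4 * v / 20))
  pr <- saturation_plateau(ret)
  expect_equal(pr$classification, "retention")
  expect_equal(pr$retention, 0.6, tolerance = 1e-6)
  full <- fx_curve(v, pmin(1, v / 30))
  expect_equal(saturation_plateau(full)$classification, "full-breakthrough")
  rising <- fx_curve(v, 0.7 * v / 100)
  expect_equal(saturation_plateau(rising)$classification, "unsaturated")
  expect_error(saturation_plateau(fx_curve(c(0, 10), c(0, 1))),
               class = "poreforce_domain_error")
})

test_that("regime table joins forces and flags the q-versus-drag trend", {
  m <- fx_membrane(); e2 <- fx_e2()
  # adsorbed mass declining with flux, as observed
  res <- tibble::tibble(
    flux = c(6, 15, 30, 38, 57),
    q_ads_A = c(0.60, 0.45, 0.25, 0.05, 0.02),
    sigma = 0.02
  )
  tab <- regime_table(res, m, e2)
  expect_equal(tab$flux, sort(res$flux))
  expect_true(all(diff(tab$f_drag) > 0))
  expect_lte(cor(tab$q_ads_A, tab$f_drag, method = "spearman"), 0)
  expect_equal(tab$regime[tab$flux <= 30], rep("adsorptive", 3))
  expect_equal(tab$significant, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  one <- regime_table(res[1, ], m, e2)
  expect_equal(nrow(one), 1)
  expect_error(regime_table(res[0, ], m, e2), class = "poreforce_domain_error")
})
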