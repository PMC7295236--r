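test_that("TTI increments follow the piecewise branch coefficients", {
  # zero excess at the baseline, zero below the lowest branch
  expect_identical(tti_increment(37, 37, dt = 10), 0)
  expect_identical(tti_increment(10, 37, dt = 10), 0)
  # mid branch: 0.3011 * 13 K * 10 s
  expect_equal(tti_increment(50, 37, dt = 10), 0.3011 * 13 * 10,
               tolerance = 1e-12)
  # branch edges: coefficient switches above 12, 44.1 and 102.1 degC
  expect_equal(tti_increment(44.1, 37, dt = 1), 0.1573 * 7.1, tolerance = 1e-12)
  expect_equal(tti_increment(44.2, 37, dt = 1), 0.3011 * 7.2, tolerance = 1e-12)
  expect_equal(tti_increment(103, 37, dt = 1), 0.54163 * 66, tolerance = 1e-12)
  # sub-baseline temperatures never decrease the dose
  expect_identical(tti_increment(20, 37, dt = 5), 0)
  expect_true(all(tti_increment(seq(0, 150, 0.5), 37, dt = 1) >= 0))
})

test_that("thermal-expansion coefficient follows the TTI power law", {
  expect_identical(as.numeric(alpha_t(0, 310, T_in_kelvin = TRUE)), 0)
  a <- alpha_t(39.14, 310, T_in_kelvin = TRUE)
  expect_equal(as.numeric(a), -0.03 * 39.14^0.4684 / (310 - 285),
               tolerance = 1e-12)
  expect_equal(as.numeric(a), -6.69e-3, tolerance = 1e-2)
  # celsius input converts to kelvin internally
  expect_equal(as.numeric(alpha_t(39.14, 310 - 273.15)), as.numeric(a),
               tolerance = 1e-12)
  # monotone nonincreasing in dose at fixed temperature, always <= 0
  tt <- seq(0, 500, 25)
  av <- as.numeric(alpha_t(tt, 330, T_in_kelvin = TRUE))
  expect_true(all(diff(av) <= 0))
  expect_true(all(av <= 0))
  expect_error(alpha_t(10, 285, T_in_kelvin = TRUE), "denominator")
  # the alternative parsing is labeled
  expect_identical(attr(alpha_t(10, 310, parsing = "plain"), "parsing"),
                   "plain")
})

test_that("thermal strain and volumetric contraction are consistent", {
  expect_identical(thermal_strain(-0.005, 37, 37), 0)
  expect_equal(thermal_strain(-0.005, 77, 37), -0.2, tolerance = 1e-15)
  # heating with a negative coefficient contracts
  expect_lt(thermal_strain(-0.01, 60, 37), 0)

  w <- rep(1, 5)
  expect_identical(volumetric_contraction(rep(0, 5), w), 0)
  expect_equal(volumetric_contraction(rep(-0.2, 5), w), 0.8^3 - 1,
               tolerance = 1e-12)
  # strains at or below -1 clamp at total collapse
  expect_equal(volumetric_contraction(c(-1.5, 0), c(1, 0)), -1,
               tolerance = 1e-12)

  # spatially varying field against a Monte-Carlo volume integral
  mesh <- tissue_block_mesh(0.02, 0.04, 40, 80)
  RC <- matrix(mesh$rc, mesh$nr, mesh$nz)
  ZC <- matrix(mesh$zc, mesh$nr, mesh$nz, byrow = TRUE)
  Ef <- -0.3 * exp(-((RC / 0.01)^2 + ((ZC - 0.02) / 0.015)^2))
  got <- volumetric_contraction(Ef, mesh$vol)
  set.seed(99)
  n <- 1e6
  # uniform in volume: r ~ sqrt(U) * R
  pr <- sqrt(runif(n)) * 0.02
  pz <- runif(n, 0, 0.04)
  Emc <- -0.3 * exp(-((pr / 0.01)^2 + ((pz - 0.02) / 0.015)^2))
  ref <- mean((1 + Emc)^3 - 1)
  expect_lt(abs(got - ref) / abs(ref), 0.005)
})

test_that("shrinkage state accumulates dose monotonically and additively", {
  st <- shrinkage_state(3, T0_baseline = 37, T_ref = 37)
  prog <- temperature_program("step", duration = 120, T0 = 37, T1 = 60,
                              t_step = 60)
  ttis <- matrix(0, 120, 3)
  for (i in 1:120) {
    st <- shrinkage_step(st, rep(prog(i - 0.5), 3), 1)
    ttis[i, ] <- st$TTI
  }
  expect_true(all(diff(ttis[, 1]) >= 0))
  # dose is zero until the step, then linear: slope changes exactly at 60 s
  expect_identical(ttis[60, 1], 0)
  expect_equal(ttis[120, 1], 0.3011 * 23 * 60, tolerance = 1e-9)

  # additivity over interval concatenation
  st1 <- shrinkage_state(1, 37, 37)
  for (i in 1:50) st1 <- shrinkage_step(st1, 55, 1)
  st2 <- shrinkage_state(1, 37, 37)
  for (i in 1:25) st2 <- shrinkage_step(st2, 55, 1)
  for (i in 1:25) st2 <- shrinkage_step(st2, 55, 1)
  expect_equal(st1$TTI, st2$TTI, tolerance = 1e-12)

  # zero-heating trajectory: zero dose, strain and contraction
  st0 <- shrinkage_state(4, 37, 37)
  for (i in 1:20) st0 <- shrinkage_step(st0, rep(37, 4), 1)
  rep0 <- shrinkage_report(st0, rep(37, 4), rep(1, 4))
  expect_identical(rep0$TTI, rep(0, 4))
  expect_identical(rep0$contraction, 0)

  # contraction magnitude grows with exposure time at fixed hot hold
  st <- shrinkage_state(1, 37, 37)
  cons <- numeric(0)
  for (i in 1:30) {
    st <- shrinkage_step(st, 80, 10)
    cons <- c(cons, shrinkage_report(st, 80, 1)$contraction)
  }
  expect_true(all(diff(cons) <= 1e-12))
})
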