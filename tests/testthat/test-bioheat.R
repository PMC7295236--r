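test_that("uniform equilibrium is preserved without sources", {
  mesh <- tissue_block_mesh(0.01, 0.02, 8, 12)
  mat <- default_materials() # Tb = T0 = 37
  tp <- mwablate:::bioheat_template(mesh)
  st <- thermal_state(mesh, 37)
  Q0 <- matrix(0, mesh$nr, mesh$nz)
  for (i in 1:100) st <- step_temperature(st, Q0, 0.1, mesh, mat,
                                          template = tp)
  expect_lt(max(abs(st$T - 37)), 1e-10)
  expect_identical(max(abs(evaporation_sink(st))), 0)
})

test_that("manufactured solution converges at second order in space", {
  mat <- default_materials()
  errs <- sapply(c(20, 40, 80), function(n) {
    mesh <- tissue_block_mesh(0.02, 0.04, n, 2 * n)
    mp <- make_manufactured("cosine", mesh, mat)
    tp <- mwablate:::bioheat_template(mesh)
    st <- thermal_state(mesh, mp$T_exact(0))
    ctrl <- bioheat_control(perfusion = FALSE, evaporation = FALSE,
                            k_coupling = FALSE)
    for (s in 1:3) {
      g <- mp$robin_g(s)
      st <- step_temperature(st, mp$forcing(s), 1, mesh, mat, ctrl, tp,
                             bc_flux = c(g$r_outer, g$z_bottom, g$z_top))
    }
    sqrt(sum((st$T - mp$T_exact(3))^2 * mesh$vol) / sum(mesh$vol))
  })
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_gt(orders[2], 1.9)
  expect_gt(orders[1], 1.5)
})

test_that("1-D slab with constant source and Robin faces matches the quadratic closed form", {
  # tall thin block, adiabatic outer radius, Robin top/bottom
  mesh <- tissue_block_mesh(0.004, 0.04, 4, 80)
  mat <- default_materials()
  mat$ambient <- ambient_params(h = 200, T0 = 20)
  tp <- mwablate:::bioheat_template(mesh)
  ctrl <- bioheat_control(perfusion = FALSE, evaporation = FALSE,
                          k_coupling = FALSE,
                          robin_sides = c("bottom", "top"))
  qv <- 5e4 # W/m^3
  st <- thermal_state(mesh, 20)
  Q <- matrix(qv, mesh$nr, mesh$nz)
  for (i in 1:40) st <- step_temperature(st, Q, 1e5, mesh, mat,
                                         ctrl, tp)
  k <- mat$healthy$k0; h <- 200; H <- 0.04
  Tref <- 20 + qv * H / (2 * h) + qv / (2 * k) * mesh$zc * (H - mesh$zc)
  prof <- st$T[2, ]
  expect_lt(max(abs(prof - Tref) / (Tref - 20)), 0.005)
  # no radial variation
  expect_lt(max(abs(st$T[1, ] - st$T[4, ])), 1e-8)
})

test_that("energy is conserved step by step under strong heating", {
  mesh <- tissue_block_mesh(0.02, 0.04, 20, 40)
  mat <- default_materials()
  tp <- mwablate:::bioheat_template(mesh)
  st <- thermal_state(mesh, 37)
  Q <- make_sar("teardrop", mesh, 40)
  for (i in 1:60) {
    st <- step_temperature(st, Q, 1, mesh, mat, template = tp)
    b <- st$balance
    scale <- max(abs(b$source), abs(b$sensible))
    expect_lt(abs(b$residual) / scale, 0.005)
  }
  expect_gt(max(st$T), 100) # the run crossed the vaporization band
})

test_that("evaporation sink absorbs exactly the water enthalpy budget", {
  # adiabatic uniform block heated uniformly: temperatures plateau inside
  # the band until w rho L_vap is consumed, then resume full-rate heating
  mesh <- tissue_block_mesh(0.004, 0.004, 3, 3)
  mat <- default_materials()
  mat$ambient$h <- 0
  tp <- mwablate:::bioheat_template(mesh)
  ctrl <- bioheat_control(perfusion = FALSE)
  p <- mat$healthy
  qv <- 5e7
  st <- thermal_state(mesh, 95)
  below <- TRUE; consumed_tot <- 0
  nsteps <- 0
  while (max(st$T) < 120 && nsteps < 3000) {
    st <- step_temperature(st, matrix(qv, 3, 3), 0.1, mesh, mat, ctrl, tp)
    consumed_tot <- consumed_tot + st$balance$evaporation
    nsteps <- nsteps + 1
  }
  cap_total <- p$water_fraction * p$density * mat$ambient$latent_heat *
    sum(mesh$vol)
  expect_equal(consumed_tot, cap_total, tolerance = 0.01)
  # post-exhaustion heating rate matches the sink-free rate within 1%
  st2 <- st
  st2 <- step_temperature(st2, matrix(qv, 3, 3), 0.1, mesh, mat, ctrl, tp)
  rate_after <- (max(st2$T) - max(st$T)) / 0.1
  ctrl0 <- bioheat_control(perfusion = FALSE, evaporation = FALSE)
  stn <- thermal_state(mesh, 110)
  stn <- step_temperature(stn, matrix(qv, 3, 3), 0.1, mesh, mat, ctrl0, tp)
  rate_free <- (max(stn$T) - 110) / 0.1
  expect_equal(rate_after, rate_free, tolerance = 0.01)
  # below the band there is no sink at all
  stc <- thermal_state(mesh, 60)
  stc <- step_temperature(stc, matrix(0, 3, 3), 1, mesh, mat, ctrl, tp)
  expect_identical(max(abs(evaporation_sink(stc))), 0)
})

test_that("temperatures are nondecreasing under nonnegative sources", {
  mesh <- tissue_block_mesh(0.015, 0.03, 12, 24)
  mat <- default_materials()
  tp <- mwablate:::bioheat_template(mesh)
  st <- thermal_state(mesh, 37) # Tb = T0 = T_init
  Q <- make_sar("axial_gaussian", mesh, 10)
  for (i in 1:30) {
    Tprev <- st$T
    st <- step_temperature(st, Q, 1, mesh, mat, template = tp)
    expect_gte(min(st$T - Tprev), -1e-9)
  }
  # discrete maximum principle: never below the common baseline
  expect_gte(min(st$T), 37 - 0.5)
})

test_that("temperature rise is linear in power when couplings are frozen", {
  mesh <- tissue_block_mesh(0.015, 0.03, 10, 20)
  mat <- default_materials()
  tp <- mwablate:::bioheat_template(mesh)
  ctrl <- bioheat_control(perfusion = FALSE, evaporation = FALSE,
                          k_coupling = FALSE)
  run <- function(P) {
    st <- thermal_state(mesh, 37)
    Q <- make_sar("axial_gaussian", mesh, P)
    for (i in 1:20) st <- step_temperature(st, Q, 1, mesh, mat, ctrl, tp)
    st$T - 37
  }
  d1 <- run(5); d2 <- run(10)
  expect_equal(max(abs(d2 - 2 * d1)) / max(d1), 0, tolerance = 1e-8)
})

test_that("coupled loop stays inert at zero power and refines in dt", {
  mesh <- tissue_block_mesh(0.015, 0.03, 10, 20,
                            tumor = make_tumor("sphere", 0.004))
  mat <- default_materials()
  run0 <- run_coupled(mesh, mat, P_in = 0, f = 2.45e9, t_end = 20, dt = 1,
                      T_init = 37)
  expect_lt(max(abs(run0$thermal$T - 37)), 1e-9)
  expect_lt(max(run0$cells$D), 1e-4) # only the baseline 37 degC drift
  expect_identical(run0$stop_reason, "cap_reached")

  # halving dt moves the final mean tumor temperature by < 0.5%
  Q <- make_sar("teardrop", mesh, 8, center_z = 0.015)
  w <- mesh$frac_tumor
  runs <- lapply(c(1, 0.5), function(dt)
    run_coupled(mesh, mat, P_in = 8, f = 2.45e9, t_end = 60, dt = dt,
                T_init = 37, Q_fixed = Q))
  m1 <- region_mean(runs[[1]]$thermal$T, w, mesh$vol)
  m2 <- region_mean(runs[[2]]$thermal$T, w, mesh$vol)
  expect_lt(abs(m1 - m2) / m2, 0.005)
})

test_that("heating lowers the dielectric properties relative to the frozen case", {
  mesh <- tissue_block_mesh(0.015, 0.03, 10, 20)
  mat <- default_materials()
  Q <- make_sar("teardrop", mesh, 30, center_z = 0.015)
  run <- run_coupled(mesh, mat, P_in = 30, f = 2.45e9, t_end = 60, dt = 1,
                     T_init = 37, Q_fixed = Q)
  hot <- run$thermal$T > 60
  expect_gt(sum(hot), 0)
  dl_cold <- dielectric_fields(mesh, matrix(37, mesh$nr, mesh$nz), mat)
  dl_hot <- dielectric_fields(mesh, run$thermal$T, mat)
  expect_true(all(dl_cold$eps_r[hot] > dl_hot$eps_r[hot]))
  expect_true(all(dl_cold$sigma[hot] > dl_hot$sigma[hot]))
})

test_that("Picard failure reports diagnostics", {
  mesh <- tissue_block_mesh(0.01, 0.02, 6, 8)
  mat <- default_materials()
  ctrl <- bioheat_control(picard_max = 1, picard_tol = 1e-14)
  st <- thermal_state(mesh, 37)
  Q <- make_sar("axial_gaussian", mesh, 50)
  expect_error(step_temperature(st, Q, 10, mesh, mat, ctrl),
               "Picard")
})
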