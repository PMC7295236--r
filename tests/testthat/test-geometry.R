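test_that("equal-volume tumor construction gives the documented semi-axes", {
  # prolate: minor shrinks by lambda^(-1/3), major grows by lambda^(2/3)
  tp <- make_tumor("prolate", 0.005, 2)
  expect_equal(tp$a, 0.005 * 2^(-1 / 3), tolerance = 1e-12)
  expect_equal(tp$b, 0.005 * 2^(2 / 3), tolerance = 1e-12)
  expect_equal(tp$a * 100, 0.3969, tolerance = 1e-3)
  expect_equal(tp$b * 100, 0.7937, tolerance = 1e-3)
  expect_identical(tp$semi_z, tp$b) # major axis along the antenna

  to <- make_tumor("oblate", 0.005, 5)
  expect_equal(to$semi_r * 100, 0.8550, tolerance = 1e-3)
  expect_equal(to$semi_z * 100, 0.1710, tolerance = 1e-3)

  ts <- make_tumor("sphere", 0.01, 7)
  expect_identical(ts$a, 0.01)
  expect_identical(ts$b, 0.01)

  # analytic equal-volume invariant across shapes and aspect ratios
  for (kind in c("prolate", "oblate")) for (l in c(1, 2, 5, 9.5)) {
    t <- make_tumor(kind, 0.005, l)
    v <- 4 / 3 * pi * t$semi_r^2 * t$semi_z
    expect_equal(v, 4 / 3 * pi * 0.005^3, tolerance = 1e-12)
  }
  expect_error(make_tumor("prolate", 0.005, 0.5), "lambda")
})

test_that("lambda = 1 collapses prolate and oblate onto the sphere", {
  a <- make_tumor("prolate", 0.007, 1)
  b <- make_tumor("oblate", 0.007, 1)
  expect_equal(a$semi_r, 0.007, tolerance = 1e-15)
  expect_equal(a[c("a", "b", "semi_r", "semi_z")],
               b[c("a", "b", "semi_r", "semi_z")], tolerance = 1e-15)
})

test_that("mesh region labels agree with analytic membership", {
  tumor <- make_tumor("sphere", 0.005)
  mesh <- build_mesh(tumor, antenna_layout(), domain_spec())
  # meshed tumor volume within 1% of (4/3) pi r^3
  tv <- mesh$region_volumes$volume_m3[mesh$region_volumes$region == "tumor"]
  expect_lt(abs(tv - tumor$volume) / tumor$volume, 0.01)

  # random probes classified by containing cell vs analytic membership
  set.seed(7)
  n <- 1e4
  pr <- runif(n, 0, mesh$domain$radius)
  pz <- runif(n, 0, mesh$domain$height)
  ic <- findInterval(pr, mesh$rf, rightmost.closed = TRUE)
  jc <- findInterval(pz, mesh$zf, rightmost.closed = TRUE)
  lab <- mesh$region[cbind(ic, jc)]
  z_c <- mesh$z_center
  analytic <- (pr / tumor$semi_r)^2 + ((pz - z_c) / tumor$semi_z)^2 <= 1
  in_antenna <- lab > 2
  mis <- (lab == 2) != analytic
  expect_lt(mean(mis[!in_antenna]), 0.005)

  # refinement shrinks the region volume error
  mesh2 <- build_mesh(tumor, antenna_layout(), domain_spec(), res = 2)
  tv2 <- mesh2$region_volumes$volume_m3[mesh2$region_volumes$region == "tumor"]
  expect_lt(abs(tv2 - tumor$volume), abs(tv - tumor$volume))
})

test_that("double-slot layout places both slots inside a prolate tumor", {
  tumor <- make_tumor("prolate", 0.005, 5)
  ant <- antenna_layout("double_slot", L = tumor$semi_z)
  mesh <- build_mesh(tumor, ant, domain_spec())
  expect_length(mesh$z_slots, 2)
  expect_equal(mesh$z_slots[1], mesh$z_center - tumor$semi_z / 2,
               tolerance = 1e-12)
  expect_equal(diff(mesh$z_slots), tumor$semi_z, tolerance = 1e-12)
  expect_true(all(mesh$z_slots > mesh$z_center - tumor$semi_z &
                    mesh$z_slots < mesh$z_center + tumor$semi_z))
  expect_error(antenna_layout("double_slot"), "L")
})

test_that("meshed tumor volumes stay equal across shapes at fixed r_eq", {
  vols <- sapply(list(make_tumor("sphere", 0.005),
                      make_tumor("prolate", 0.005, 5),
                      make_tumor("oblate", 0.005, 2)), function(t) {
    m <- build_mesh(t, antenna_layout(), domain_spec())
    m$region_volumes$volume_m3[m$region_volumes$region == "tumor"]
  })
  expect_lt(diff(range(vols)) / mean(vols), 0.02)
})

test_that("monitor shell has eight tumor volumes and the point sits 2.5 mm out", {
  tumor <- make_tumor("sphere", 0.005)
  mesh <- build_mesh(tumor, antenna_layout(), domain_spec())
  mon <- monitor_regions(mesh)
  shell_v <- sum(mon$frac_shell * mesh$vol)
  tv <- sum(mesh$frac_tumor * mesh$vol)
  expect_lt(abs(shell_v - 8 * tv) / (8 * tv), 0.02)
  # outer equivalent radius of the shell: 0.5 cm * 9^(1/3)
  expect_equal((3 * (shell_v + tv) / (4 * pi))^(1 / 3),
               0.005 * 9^(1 / 3), tolerance = 0.02)
  # nearest cell center: within half a local cell of the exact point
  expect_lt(abs(mon$point_r - (tumor$semi_r + 2.5e-3)), 6e-4)
  expect_lt(abs(mon$point_z - mesh$z_center), 6e-4)

  # lambda = 1 prolate and oblate shells are identical
  mp <- build_mesh(make_tumor("prolate", 0.005, 1), antenna_layout())
  mo <- build_mesh(make_tumor("oblate", 0.005, 1), antenna_layout())
  expect_identical(monitor_regions(mp)$frac_shell,
                   monitor_regions(mo)$frac_shell)

  # shell outgrowing the domain is a geometry error
  big <- build_mesh(make_tumor("sphere", 0.02), antenna_layout())
  expect_error(monitor_regions(big), "domain")
})

test_that("oversized tumors and misplaced slots are geometry errors", {
  expect_error(build_mesh(make_tumor("sphere", 0.05), antenna_layout()),
               "fit")
  expect_error(build_mesh(make_tumor("prolate", 0.005, 5),
                          antenna_layout("double_slot", L = 0.2)), "slot")
})
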