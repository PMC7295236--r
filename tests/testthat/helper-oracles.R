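# Independent oracles used across the suite. These re-derive expected
# values by direct means (closed forms, brute-force fine-step integration,
# Monte-Carlo quadrature) without touching the implementation paths they
# check.

# brute-force scalar three-state integrator: classical RK4 at a fine fixed
# step, written independently of step_cell_state
oracle_cell_ode <- function(A0, D0, T_of_t, t_end, p, h = 1e-3) {
  A <- A0; D <- D0; t <- 0
  rhs <- function(A, D, T) {
    kf <- p$kf_bar * exp(T / p$Tk) * (1 - A)
    V <- 1 - A - D
    c(-kf * A + p$kb * V, kf * V)
  }
  n <- ceiling(t_end / h)
  for (i in seq_len(n)) {
    T1 <- T_of_t(t); T2 <- T_of_t(t + h / 2); T3 <- T_of_t(t + h)
    k1 <- rhs(A, D, T1)
    k2 <- rhs(A + h / 2 * k1[1], D + h / 2 * k1[2], T2)
    k3 <- rhs(A + h / 2 * k2[1], D + h / 2 * k2[2], T2)
    k4 <- rhs(A + h * k3[1], D + h * k3[2], T3)
    A <- A + h / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
    D <- D + h / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
    t <- t + h
  }
  c(A = A, D = D)
}

# straight coaxial line filled with a lossless dielectric, conductors as
# PEC rings, matched port on top, absorbing bottom: the TEM closed form
# H_phi = A/r is exact in r
coax_test_mesh <- function(nr_diel = 12, nz = 40, length_m = 0.02) {
  ri <- 0.135e-3; rd <- 0.47e-3; ro <- 0.595e-3
  rf <- c(seq(0, ri, length.out = 4),
          ri + seq_len(nr_diel) / nr_diel * (rd - ri),
          rd + seq_len(2) / 2 * (ro - rd))
  zf <- seq(0, length_m, length.out = nz + 1)
  nr <- length(rf) - 1
  rc <- (rf[-1] + rf[-length(rf)]) / 2
  zc <- (zf[-1] + zf[-length(zf)]) / 2
  region <- matrix(mwablate:::REG[["dielectric"]], nr, nz)
  region[rc < ri, ] <- mwablate:::REG[["conductor"]]
  region[rc > rd, ] <- mwablate:::REG[["conductor"]]
  vol <- outer(pi * (rf[-1]^2 - rf[-length(rf)]^2), diff(zf))
  mesh <- structure(list(rf = rf, zf = zf, rc = rc, zc = zc,
                         dr = diff(rf), dz = diff(zf), nr = nr, nz = nz,
                         region = region, vol = vol,
                         frac_tumor = matrix(0, nr, nz), tumor = NULL,
                         antenna = antenna_layout(),
                         domain = domain_spec(ro, length_m),
                         z_slots = length_m / 2, z_tip = 0,
                         z_center = length_m / 2), class = "axi_mesh")
  mesh$region_volumes <- region_volume_table(mesh)
  mesh
}

coax_diel_cells <- function(mesh) {
  which(mesh$rc > 0.135e-3 & mesh$rc < 0.47e-3)
}
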