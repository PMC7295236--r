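#' Per-cell dielectric property fields
#'
#' Evaluates the temperature-dependent relative permittivity and electrical
#' conductivity on every mesh cell: tissue cells use the sigmoid laws of the
#' material model (tumor vs healthy row), antenna dielectric/slot and
#' catheter cells use their fixed layout permittivities with zero
#' conductivity, conductor cells are placeholders (excluded from the solve).
#'
#' @param mesh An [build_mesh()] mesh.
#' @param T_field Per-cell temperature (deg C), matrix or vector of length
#'   `nr * nz`.
#' @param materials A [material_model()].
#' @param T_max Clamp applied to the temperature before evaluating the
#'   sigmoid laws (deg C). The fitted laws decay toward zero far outside
#'   their measurement range, which would turn fully desiccated cells into
#'   lossless capacitive gaps that focus unbounded dissipation; above the
#'   clamp the properties hold at their desiccated plateau.
#' @return List of `eps_r` and `sigma` matrices (nr x nz).
#' @export
dielectric_fields <- function(mesh, T_field, materials, T_max = 160) {
  T_field <- pmin(matrix(T_field, mesh$nr, mesh$nz), T_max)
  eps <- matrix(1, mesh$nr, mesh$nz)
  sig <- matrix(0, mesh$nr, mesh$nz)
  reg <- mesh$region
  hl <- reg == REG[["healthy"]]; tm <- reg == REG[["tumor"]]
  eps[hl] <- relative_permittivity(T_field[hl], materials$healthy)
  sig[hl] <- electrical_conductivity(T_field[hl], materials$healthy)
  eps[tm] <- relative_permittivity(T_field[tm], materials$tumor)
  sig[tm] <- electrical_conductivity(T_field[tm], materials$tumor)
  dl <- reg == REG[["dielectric"]] | reg == REG[["slot"]]
  eps[dl] <- mesh$antenna$eps_dielectric
  eps[reg == REG[["catheter"]]] <- mesh$antenna$eps_catheter
  list(eps_r = eps, sigma = sig)
}

MU0 <- 4e-7 * pi

#' Solve the axisymmetric frequency-domain wave problem
#'
#' Scalar TM0 formulation in the azimuthal magnetic field H_phi: for a
#' rotationally symmetric coaxial antenna the full vector wave equation
#' reduces exactly to
#' \deqn{\partial_z(\tilde\epsilon^{-1}\partial_z u) +
#'       \partial_r(\tilde\epsilon^{-1} r^{-1}\partial_r(r u)) +
#'       \omega^2\mu u = 0}
#' with complex permittivity
#' \eqn{\tilde\epsilon = \epsilon_0\epsilon_r - j\sigma/\omega}. Conductor
#' surfaces are perfect electric conductors (zero tangential E = zero flux),
#' the coax feed is excited with the TEM mode through a first-order matched
#' port at the top boundary, outer boundaries carry a first-order absorbing
#' condition, and the axis uses the regularity condition u(0) = 0. The
#' returned field is scaled so the net time-averaged power entering the port
#' equals `P_in` (measured by the discrete Poynting integral over the port
#' plane).
#'
#' @param mesh An [build_mesh()] mesh.
#' @param eps_r,sigma Per-cell relative permittivity and conductivity
#'   (nr x nz), e.g. from [dielectric_fields()].
#' @param f Operating frequency (Hz), > 0.
#' @param P_in Delivered port power (W), > 0.
#' @param eps0 Vacuum permittivity (F/m).
#' @param mu_r Relative permeability.
#' @return An object of class `em_field`: complex `H_phi`, `E_r`, `E_z`
#'   matrices (V/m, A/m), `f`, `omega`, `P_in`, power diagnostics and the
#'   mesh.
#' @export
solve_em <- function(mesh, eps_r, sigma, f, P_in,
                     eps0 = 8.854e-12, mu_r = 1) {
  if (f <= 0) stop("frequency must be positive", call. = FALSE)
  stopifnot(P_in > 0, all(eps_r >= 0), all(sigma >= 0))
  nr <- mesh$nr; nz <- mesh$nz; N <- nr * nz
  omega <- 2 * pi * f
  mu <- MU0 * mu_r
  epsc <- eps0 * eps_r - 1i * sigma / omega          # complex permittivity
  active <- mesh$region != REG[["conductor"]]
  idx <- matrix(0L, nr, nz); idx[active] <- seq_len(sum(active))
  na <- sum(active)

  # the coax is short-circuited at the antenna tip: a PEC plate closes the
  # antenna footprint at z_tip, so radiation leaves through the slot(s) only
  conn_n <- active & cbind(active[, -1], FALSE)
  if (!is.null(mesh$antenna) && mesh$z_tip > mesh$zf[1]) {
    jt <- which(abs(mesh$zf - mesh$z_tip) < 1e-12) - 1L # cell row below tip
    if (length(jt) == 1 && jt >= 1 && jt < nz) {
      rcath <- mesh$antenna$r_catheter
      conn_n[mesh$rc < rcath, jt] <- FALSE
    }
  }

  rc <- mesh$rc; zc <- mesh$zc; dr <- mesh$dr; dz <- mesh$dz
  rf <- mesh$rf
  kcell <- omega * sqrt(mu * epsc)                   # Im <= 0 branch
  kcell <- ifelse(Im(kcell) > 0, -kcell, kcell)

  ii <- integer(0); jj <- integer(0); vv <- complex(0)
  diag_v <- complex(na)
  b <- complex(na)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); vv <<- c(vv, v)
  }

  # port geometry: dielectric annulus cells in the top row
  ant <- mesh$antenna
  port_cells <- which(active[, nz] &
                        mesh$region[, nz] == REG[["dielectric"]])
  eps_d <- eps0 * ant$eps_dielectric
  k_port <- omega * sqrt(mu * eps_d)
  eta_d <- sqrt(mu / eps_d)
  A_inc <- sqrt(P_in / (pi * eta_d * log(ant$r_dielectric / ant$r_inner)))

  I <- matrix(seq_len(nr), nr, nz); J <- matrix(seq_len(nz), nr, nz, byrow = TRUE)
  cells <- which(active)
  ci <- I[cells]; cj <- J[cells]; cid <- idx[cells]

  # radial fluxes F = (1/eps r) d(ru)/dr ; divergence (F_e - F_w)/dr
  e_c <- epsc[cells]
  # east face
  has_e <- ci < nr
  en <- cells + 1L
  act_e <- has_e & active[pmin(cells + 1L, N)]
  w <- which(act_e)
  if (length(w)) {
    i <- ci[w]; j <- cj[w]
    d1 <- dr[i] / 2; d2 <- dr[i + 1] / 2
    cf <- (d1 + d2) / (d1 * epsc[cells[w]] + d2 * epsc[en[w]])
    geo <- cf / (rf[i + 1] * (rc[i + 1] - rc[i])) / dr[i]
    add(cid[w], cid[w], -geo * rc[i])
    add(cid[w], idx[en[w]], geo * rc[i + 1])
  }
  # west face (interior): mirror of east handled once as west for neighbor
  has_w <- ci > 1
  wn <- cells - 1L
  act_w <- has_w & active[pmax(cells - 1L, 1L)]
  w <- which(act_w)
  if (length(w)) {
    i <- ci[w]; j <- cj[w]
    d1 <- dr[i] / 2; d2 <- dr[i - 1] / 2
    cf <- (d1 + d2) / (d1 * epsc[cells[w]] + d2 * epsc[wn[w]])
    geo <- cf / (rf[i] * (rc[i] - rc[i - 1])) / dr[i]
    add(cid[w], cid[w], -geo * rc[i])
    add(cid[w], idx[wn[w]], geo * rc[i - 1])
  }
  # axis face for first radial cells: F_axis = (1/eps) 2 u / rc
  w <- which(ci == 1)
  if (length(w)) {
    geo <- 2 / (e_c[w] * rc[1]) / dr[1]
    add(cid[w], cid[w], -geo)
  }
  # outer radial boundary: first-order absorbing, F_R = (1/eps)(-jk + 1/(2R)) u
  w <- which(ci == nr)
  if (length(w)) {
    kb <- kcell[cells[w]]
    geo <- (1i * -kb + 1 / (2 * mesh$rf[nr + 1])) / e_c[w] / dr[nr]
    add(cid[w], cid[w], geo)
  }

  # axial fluxes G = (1/eps) du/dz ; divergence (G_n - G_s)/dz
  nn <- cells + nr
  act_n <- conn_n[cells]
  w <- which(act_n)
  if (length(w)) {
    j <- cj[w]
    d1 <- dz[j] / 2; d2 <- dz[j + 1] / 2
    cf <- (d1 + d2) / (d1 * epsc[cells[w]] + d2 * epsc[nn[w]])
    geo <- cf / (zc[j + 1] - zc[j]) / dz[j]
    add(cid[w], cid[w], -geo)
    add(cid[w], idx[nn[w]], geo)
  }
  sn <- cells - nr
  conn_s <- cbind(FALSE, conn_n[, -nz])
  act_s <- conn_s[cells]
  w <- which(act_s)
  if (length(w)) {
    j <- cj[w]
    d1 <- dz[j] / 2; d2 <- dz[j - 1] / 2
    cf <- (d1 + d2) / (d1 * epsc[cells[w]] + d2 * epsc[sn[w]])
    geo <- cf / (zc[j] - zc[j - 1]) / dz[j]
    add(cid[w], cid[w], -geo)
    add(cid[w], idx[sn[w]], geo)
  }
  # bottom boundary z = 0: first-order absorbing evaluated at the face
  # (u_face eliminated through the half-cell Taylor step, which restores
  # second-order accuracy of the boundary flux)
  w <- which(cj == 1)
  if (length(w)) {
    kb <- kcell[cells[w]]
    cf <- 1i * kb / (1 + 1i * kb * dz[1] / 2)
    add(cid[w], cid[w], -cf / e_c[w] / dz[1])
  }
  # top boundary z = H: port on dielectric cells, absorbing elsewhere
  w <- which(cj == nz)
  if (length(w)) {
    top_cells <- cells[w]
    is_port <- mesh$region[top_cells] == REG[["dielectric"]]
    kb <- ifelse(is_port, k_port, kcell[top_cells])
    cf <- 1i * kb / (1 + 1i * kb * dz[nz] / 2)
    add(cid[w], cid[w], -cf / e_c[w] / dz[nz])
    p <- w[is_port]
    if (length(p)) {
      u_inc <- A_inc / rc[ci[p]]
      # incident term with the same face elimination
      binc <- (2i * k_port) * u_inc *
        (1 - (1i * k_port * dz[nz] / 2) / (1 + 1i * k_port * dz[nz] / 2))
      b[cid[p]] <- -binc / epsc[cells[p]] / dz[nz]
    }
  }
  # mass term
  add(cid, cid, rep(omega^2 * mu, na))

  K <- Matrix::sparseMatrix(i = c(ii, ii + na, ii + na, ii),
                            j = c(jj, jj + na, jj, jj + na),
                            x = c(Re(vv), Re(vv), Im(vv), -Im(vv)),
                            dims = c(2 * na, 2 * na))
  rhs <- c(Re(b), Im(b))
  sol <- Matrix::solve(K, rhs)
  u <- complex(real = sol[seq_len(na)], imaginary = sol[na + seq_len(na)])

  H <- matrix(0 + 0i, nr, nz); H[active] <- u

  field <- .em_postprocess(mesh, H, epsc, omega, active, port_cells,
                           k_port, A_inc, conn_n)
  # normalize so net port power equals P_in
  s <- sqrt(P_in / field$port_power)
  field$H_phi <- field$H_phi * s
  field$E_r <- field$E_r * s
  field$E_z <- field$E_z * s
  field$escaped_power <- field$escaped_power * s^2
  field$port_power <- P_in
  field$f <- f; field$omega <- omega; field$P_in <- P_in
  field$eps_complex <- epsc; field$mesh <- mesh; field$active <- active
  field$sigma_at_solve <- sigma
  class(field) <- "em_field"
  field
}

# derive E from H, port/boundary Poynting powers
.em_postprocess <- function(mesh, H, epsc, omega, active, port_cells,
                            k_port, A_inc, conn_n) {
  nr <- mesh$nr; nz <- mesh$nz
  rc <- mesh$rc; zc <- mesh$zc; dr <- mesh$dr; dz <- mesh$dz
  Hz <- matrix(0 + 0i, nr, nz) # du/dz
  Hr <- matrix(0 + 0i, nr, nz) # (1/r) d(r u)/dr
  act <- active
  # axial derivative: central where connected both ways, else one-sided
  up <- cbind(H[, -1], H[, nz]); dn <- cbind(H[, 1], H[, -nz])
  aup <- conn_n; adn <- cbind(FALSE, conn_n[, -nz])
  zup <- matrix(c(zc[-1], zc[nz]), nr, nz, byrow = TRUE)
  zdn <- matrix(c(zc[1], zc[-nz]), nr, nz, byrow = TRUE)
  Z <- matrix(zc, nr, nz, byrow = TRUE)
  both <- aup & adn
  Hz[both] <- ((up - dn) / (zup - zdn))[both]
  only_up <- aup & !adn; Hz[only_up] <- ((up - H) / (zup - Z))[only_up]
  only_dn <- adn & !aup; Hz[only_dn] <- ((H - dn) / (Z - zdn))[only_dn]
  # radial derivative of v = r u
  V <- H * matrix(rc, nr, nz)
  ve <- rbind(V[-1, ], V[nr, ]); vw <- rbind(V[1, ], V[-nr, ])
  ae <- rbind(act[-1, ], matrix(FALSE, 1, nz)); aw <- rbind(matrix(FALSE, 1, nz), act[-nr, ])
  re_ <- matrix(c(rc[-1], rc[nr]), nr, nz)
  rw_ <- matrix(c(rc[1], rc[-nr]), nr, nz)
  Rm <- matrix(rc, nr, nz)
  both <- ae & aw
  Hr[both] <- (((ve - vw) / (re_ - rw_)) / Rm)[both]
  only_e <- ae & !aw; Hr[only_e] <- (((ve - V) / (re_ - Rm)) / Rm)[only_e]
  only_w <- aw & !ae; Hr[only_w] <- (((V - vw) / (Rm - rw_)) / Rm)[only_w]
  # first radial cell: v ~ c r^2 so (1/r) dv/dr = 2 u / r
  Hr[1, ] <- 2 * H[1, ] / rc[1]

  jwe <- 1i * omega * epsc
  E_r <- -Hz / jwe
  E_z <- Hr / jwe
  E_r[!act] <- 0; E_z[!act] <- 0

  # port power: net inward Poynting through the top dielectric annulus,
  # with u and dU/dz eliminated onto the boundary face
  u_p <- H[port_cells, nz]
  u_inc <- A_inc / rc[port_cells]
  hdz <- 1i * k_port * dz[nz] / 2
  u_f <- (u_p + 2 * hdz * u_inc) / (1 + hdz)
  dudz <- 1i * k_port * (-u_f + 2 * u_inc)
  Erp <- -dudz / jwe[port_cells, nz]
  area <- 2 * pi * rc[port_cells] * dr[port_cells]
  port_power <- sum(-0.5 * Re(Erp * Conj(u_f)) * area)

  # escaping power through absorbing boundaries; S = Re(E x H*)/2 with
  # S_r = -Re(E_z H*)/2 and S_z = +Re(E_r H*)/2 for H = H_phi
  esc <- 0
  w <- which(act[nr, ]) # outer radius, outward normal +r
  if (length(w))
    esc <- esc + sum(-0.5 * Re(E_z[nr, w] * Conj(H[nr, w])) *
                       2 * pi * mesh$rf[nr + 1] * dz[w])
  w <- which(act[, 1]) # bottom, outward normal -z
  if (length(w))
    esc <- esc - sum(0.5 * Re(E_r[w, 1] * Conj(H[w, 1])) *
                       2 * pi * rc[w] * dr[w])
  w <- setdiff(which(act[, nz]), port_cells) # top outside port, normal +z
  if (length(w))
    esc <- esc + sum(0.5 * Re(E_r[w, nz] * Conj(H[w, nz])) *
                       2 * pi * rc[w] * dr[w])
  list(H_phi = H, E_r = E_r, E_z = E_z, port_power = port_power,
       escaped_power = esc)
}

#' Resistive heat deposition from a solved field
#'
#' \eqn{Q_{ext} = \sigma |E|^2 / 2} per cell with
#' \eqn{|E|^2 = |E_r|^2 + |E_z|^2}; totals use axisymmetric
#' \eqn{2\pi r} volume weights.
#'
#' @param field An `em_field` from [solve_em()].
#' @param sigma Per-cell conductivity (S/m), defaulting to the field's
#'   solve-time values.
#' @return List with `Q` (W/m^3, nr x nz), `absorbed` and `escaped` (W).
#' @export
heat_deposition <- function(field, sigma = field$sigma_at_solve) {
  stopifnot(inherits(field, "em_field"))
  Q <- sigma * (Mod(field$E_r)^2 + Mod(field$E_z)^2) / 2
  list(Q = Q, absorbed = sum(Q * field$mesh$vol),
       escaped = field$escaped_power)
}

#' Should the EM field be re-solved?
#'
#' The segregated coupling re-solves the wave problem only when the
#' dielectric properties have drifted appreciably since the last solve.
#'
#' @param sigma_now,sigma_at_last_solve Matching per-cell conductivity (or
#'   permittivity) fields.
#' @param tol Relative-change trigger, default 0.02.
#' @return `TRUE` iff the maximum relative change exceeds `tol`.
#' @export
needs_resolve <- function(sigma_now, sigma_at_last_solve, tol = 0.02) {
  stopifnot(length(sigma_now) == length(sigma_at_last_solve))
  # floor the per-node reference at a few percent of the field scale so
  # near-zero (desiccated) nodes do not trigger perpetual re-solves
  scale <- max(abs(sigma_at_last_solve), 1e-12)
  ref <- pmax(abs(sigma_at_last_solve), 0.05 * scale)
  max(abs(sigma_now - sigma_at_last_solve) / ref) > tol
}
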