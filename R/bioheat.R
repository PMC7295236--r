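#' Thermal state of the tissue domain
#'
#' Holds the per-cell temperature, the simulation clock, the accumulated
#' evaporation enthalpy per cell (J/m^3, capped at w rho L_vap) and the
#' evaporation sink of the last completed step.
#'
#' @param mesh An [build_mesh()] mesh.
#' @param T_init Initial temperature (deg C), scalar or nr x nz matrix.
#' @return An object of class `thermal_state`.
#' @export
thermal_state <- function(mesh, T_init = 37) {
  T0 <- if (length(T_init) == 1) matrix(T_init, mesh$nr, mesh$nz)
        else matrix(T_init, mesh$nr, mesh$nz)
  structure(list(T = T0, t = 0,
                 evap = matrix(0, mesh$nr, mesh$nz),
                 Q_E = matrix(0, mesh$nr, mesh$nz),
                 balance = NULL, picard_iters = NA_integer_),
            class = "thermal_state")
}

#' Solver controls for the bioheat step
#'
#' @param picard_tol Relative tolerance on the Picard property iteration.
#' @param picard_max Maximum Picard iterations before the step fails.
#' @param perfusion Include the blood-perfusion exchange term?
#' @param evaporation Include the vaporization enthalpy sink?
#' @param k_coupling Evaluate k at the current temperature (otherwise at the
#'   reference temperature, freezing the property coupling)?
#' @param evap_band Vaporization band (deg C): crossing it absorbs
#'   w rho L_vap per unit volume via an augmented apparent heat capacity.
#' @param robin_sides Which outer boundaries carry the Robin exchange;
#'   subset of `"outer"` (radial), `"bottom"`, `"top"`. Excluded sides are
#'   adiabatic (used by 1-D verification fixtures).
#' @return List of control settings.
#' @export
bioheat_control <- function(picard_tol = 1e-3, picard_max = 50,
                            perfusion = TRUE, evaporation = TRUE,
                            k_coupling = TRUE, evap_band = c(99, 105),
                            robin_sides = c("outer", "bottom", "top")) {
  stopifnot(picard_tol > 0, picard_max >= 1, evap_band[2] > evap_band[1],
            all(robin_sides %in% c("outer", "bottom", "top")))
  list(picard_tol = picard_tol, picard_max = picard_max,
       perfusion = perfusion, evaporation = evaporation,
       k_coupling = k_coupling, evap_band = evap_band,
       robin_sides = robin_sides)
}

# geometric face/boundary template for the tissue finite-volume operator;
# antenna-facing and axis faces are adiabatic and simply absent
bioheat_template <- function(mesh) {
  nr <- mesh$nr; nz <- mesh$nz
  act <- mesh$region <= REG[["tumor"]]
  idx <- matrix(0L, nr, nz); idx[act] <- seq_len(sum(act))
  I <- matrix(seq_len(nr), nr, nz); J <- matrix(seq_len(nz), nr, nz, byrow = TRUE)
  cells <- which(act); ci <- I[cells]; cj <- J[cells]
  rc <- mesh$rc; rf <- mesh$rf; dr <- mesh$dr; dz <- mesh$dz; zc <- mesh$zc

  # interior radial faces (count each once, from the west cell)
  w <- which(ci < nr & act[pmin(cells + 1L, nr * nz)])
  fr <- list(a = cells[w], b = cells[w] + 1L,
             area = 2 * pi * rf[ci[w] + 1] * dz[cj[w]],
             da = dr[ci[w]] / 2, db = dr[ci[w] + 1] / 2)
  # interior axial faces
  w <- which(cj < nz & act[pmin(cells + nr, nr * nz)])
  fz <- list(a = cells[w], b = cells[w] + nr,
             area = 2 * pi * rc[ci[w]] * dr[ci[w]],
             da = dz[cj[w]] / 2, db = dz[cj[w] + 1] / 2)
  faces <- list(a = c(fr$a, fz$a), b = c(fr$b, fz$b),
                area = c(fr$area, fz$area),
                da = c(fr$da, fz$da), db = c(fr$db, fz$db))

  # Robin boundary faces on the domain surface
  bc <- list(cell = integer(0), area = numeric(0), dhalf = numeric(0),
             side = character(0))
  w <- which(ci == nr)
  bc$cell <- c(bc$cell, cells[w])
  bc$area <- c(bc$area, 2 * pi * rf[nr + 1] * dz[cj[w]])
  bc$dhalf <- c(bc$dhalf, rep(dr[nr] / 2, length(w)))
  bc$side <- c(bc$side, rep("outer", length(w)))
  for (side in c(1L, nz)) {
    w <- which(cj == side)
    bc$cell <- c(bc$cell, cells[w])
    bc$area <- c(bc$area, 2 * pi * rc[ci[w]] * dr[ci[w]])
    bc$dhalf <- c(bc$dhalf, rep(dz[side] / 2, length(w)))
    bc$side <- c(bc$side, rep(if (side == 1L) "bottom" else "top",
                              length(w)))
  }
  list(act = act, idx = idx, cells = cells, n = length(cells),
       faces = faces, bc = bc)
}

# per-cell k(T) over tissue cells
conductivity_field <- function(mesh, T, materials, k_coupling = TRUE) {
  k <- matrix(0, mesh$nr, mesh$nz)
  hl <- mesh$region == REG[["healthy"]]; tm <- mesh$region == REG[["tumor"]]
  Th <- if (k_coupling) T else matrix(materials$healthy$T0_k, mesh$nr, mesh$nz)
  k[hl] <- thermal_conductivity(Th[hl], materials$healthy)
  k[tm] <- thermal_conductivity(Th[tm], materials$tumor)
  k
}

# per-cell volumetric heat capacity rho*C (J/m^3 K) and water enthalpy cap
.volumetric_props <- function(mesh, materials) {
  rhoC <- matrix(0, mesh$nr, mesh$nz)
  cap <- matrix(0, mesh$nr, mesh$nz)
  for (nm in c("healthy", "tumor")) {
    m <- mesh$region == REG[[nm]]
    p <- materials[[nm]]
    rhoC[m] <- p$density * p$specific_heat
    cap[m] <- p$water_fraction * p$density * materials$ambient$latent_heat
  }
  list(rhoC = rhoC, evap_cap = cap)
}

#' One implicit step of the Pennes bioheat equation
#'
#' Backward-Euler finite-volume step of
#' \deqn{\rho C \partial T/\partial t = \nabla\cdot(k(T)\nabla T) +
#'   \rho_b C_b \omega_b(T) (T_b - T) + Q_m + Q_{ext} + Q_E}
#' on the tissue cells of the axisymmetric mesh. Conduction, perfusion and
#' the Robin boundary exchange \eqn{k \partial T/\partial n = h (T - T_0)}
#' are implicit; temperature-dependent k and perfusion are lagged and
#' updated by Picard iteration to the requested relative tolerance. The
#' vaporization sink is an apparent-heat-capacity enthalpy method: inside
#' the band the volumetric capacity is augmented by
#' \eqn{w \rho L_{vap} / \Delta T_{band}} until the local water budget is
#' exhausted, after which temperatures may exceed the band freely. Antenna
#' surfaces are adiabatic; the axis is a symmetry (zero-flux) boundary.
#'
#' @param state A [thermal_state()].
#' @param Q_ext Per-cell volumetric heat source (W/m^3), nr x nz.
#' @param dt Time step (s), > 0.
#' @param mesh,materials Mesh and [material_model()].
#' @param control A [bioheat_control()].
#' @param template Precomputed [bioheat_template] (rebuilt when missing);
#'   pass it explicitly in time loops.
#' @param perfusion_off Optional logical per-cell mask forcing perfusion off
#'   locally (e.g. where tissue is already dead).
#' @param bc_flux Optional extra inward boundary flux density (W/m^2), one
#'   value per template boundary face (outer radius faces first, then
#'   bottom, then top). Used by manufactured-solution fixtures to impose
#'   exact Robin data.
#' @return The advanced `thermal_state`, with `balance` (per-step energy
#'   bookkeeping, W s) and `picard_iters` diagnostics.
#' @export
step_temperature <- function(state, Q_ext, dt, mesh, materials,
                             control = bioheat_control(),
                             template = NULL, perfusion_off = NULL,
                             bc_flux = NULL) {
  stopifnot(inherits(state, "thermal_state"), dt > 0,
            all(is.finite(Q_ext)))
  if (is.null(template)) template <- bioheat_template(mesh)
  tp <- template
  n <- tp$n; cells <- tp$cells
  amb <- materials$ambient; bl <- materials$blood
  vp <- .volumetric_props(mesh, materials)
  V <- mesh$vol[cells]
  Told <- state$T
  Tn <- Told
  band <- control$evap_band

  q <- (Q_ext[cells] + amb$Qm) * V
  ia <- tp$idx[tp$faces$a]; ib <- tp$idx[tp$faces$b]
  bc_id <- tp$idx[tp$bc$cell]

  applied_extra <- NULL
  for (it in seq_len(control$picard_max)) {
    kf_cell <- conductivity_field(mesh, Tn, materials, control$k_coupling)
    ka <- kf_cell[tp$faces$a]; kb <- kf_cell[tp$faces$b]
    kharm <- (tp$faces$da + tp$faces$db) /
      (tp$faces$da / ka + tp$faces$db / kb)
    g <- kharm * tp$faces$area / (tp$faces$da + tp$faces$db)

    # Robin coefficient through the half-cell: U = 1/(1/h + d/(2k));
    # beta = k/(d/2) is the half-cell conductance entering the exact
    # face-temperature elimination (also used for the extra-flux weight)
    kb_cell <- kf_cell[tp$bc$cell]
    beta <- kb_cell / tp$bc$dhalf
    side_on <- tp$bc$side %in% control$robin_sides
    if (amb$h > 0) {
      U <- 1 / (1 / amb$h + tp$bc$dhalf / kb_cell)
      bcoef <- U * tp$bc$area * side_on
    } else bcoef <- rep(0, length(tp$bc$cell))
    gflux <- if (is.null(bc_flux)) rep(0, length(tp$bc$cell))
             else bc_flux * beta / (beta + amb$h) * tp$bc$area

    if (control$perfusion) {
      wb <- blood_perfusion(Tn[cells], bl, materials$perfusion_scale)
      if (!is.null(perfusion_off)) wb[perfusion_off[cells]] <- 0
      pcoef <- bl$density * bl$specific_heat * wb * V
    } else pcoef <- rep(0, n)

    m <- vp$rhoC[cells] * V / dt

    diag_v <- m + pcoef
    diag_add <- numeric(n)
    # conduction: assemble symmetric stiffness
    ii <- c(seq_len(n), ia, ib, ia, ib)
    jj <- c(seq_len(n), ia, ib, ib, ia)
    xx <- c(diag_v, rep(0, 2 * length(ia)), -g, -g)
    # add g to the two face-cell diagonals
    dg <- numeric(n)
    dgt <- tapply(c(g, g), c(ia, ib), sum)
    dg[as.integer(names(dgt))] <- dgt
    bsum <- numeric(n)
    bt <- tapply(bcoef, bc_id, sum)
    bsum[as.integer(names(bt))] <- bt
    xx[seq_len(n)] <- diag_v + dg + bsum
    K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
    rhs <- m * Told[cells] + q + pcoef * bl$temperature
    rb <- numeric(n)
    rbt <- tapply(bcoef * amb$T0 + gflux, bc_id, sum)
    rb[as.integer(names(rbt))] <- rbt
    rhs <- rhs + rb
    Tsol <- as.numeric(Matrix::solve(K, rhs))
    Tprev <- Tn[cells]
    if (it > 8) Tsol <- 0.5 * (Tsol + Tprev) # damp rare property cycling
    Tn[cells] <- Tsol
    relchg <- max(abs(Tsol - Tprev)) / max(abs(Tsol), 1)
    if (relchg < control$picard_tol) break
    if (it == control$picard_max)
      stop(sprintf(paste0("Picard iteration did not converge in %d iterations",
                          " (last relative change %.3e)"),
                   control$picard_max, relchg), call. = FALSE)
  }

  # evaporation correction (operator split): the vaporization plateau sits
  # at band_lo when the local water budget is empty and rises linearly to
  # band_hi as it fills; sensible energy above the plateau converts to
  # latent enthalpy in closed form, exactly conserving energy
  T_tent <- Tsol # pre-correction solution; the implicit terms saw this one
  if (control$evaporation) {
    rhoCc <- vp$rhoC[cells]
    capc <- vp$evap_cap[cells]
    B_old <- state$evap[cells]
    dband <- diff(band)
    plateau <- band[1] + (B_old / pmax(capc, 1e-300)) * dband
    boiling <- capc > 0 & B_old < capc & Tsol > plateau
    B_new <- B_old
    B_new[boiling] <- pmin(capc[boiling],
      (B_old[boiling] + rhoCc[boiling] * (Tsol[boiling] - band[1])) /
        (1 + rhoCc[boiling] * dband / capc[boiling]))
    consumed <- B_new - B_old
    Tsol <- Tsol - consumed / rhoCc
    Tn[cells] <- Tsol
  } else consumed <- rep(0, n)
  dT <- Tsol - Told[cells]
  state$evap[cells] <- state$evap[cells] + consumed
  state$Q_E <- matrix(0, mesh$nr, mesh$nz)
  state$Q_E[cells] <- -consumed / dt

  # per-step energy bookkeeping (J): sensible change vs integrated terms
  sensible <- sum(vp$rhoC[cells] * dT * V)
  source <- sum(q) * dt
  perf <- sum(pcoef * (bl$temperature - T_tent)) * dt
  bloss <- sum(bcoef * (T_tent[match(tp$bc$cell, cells)] - amb$T0) -
                 gflux) * dt
  evap <- sum(consumed * V)
  state$balance <- list(sensible = sensible, source = source,
                        perfusion = perf, boundary_loss = bloss,
                        evaporation = evap,
                        residual = sensible - (source + perf - bloss - evap))
  state$T <- Tn
  state$t <- state$t + dt
  state$picard_iters <- it
  state
}

#' Evaporation sink of the last completed step
#'
#' @param state A [thermal_state()] advanced by [step_temperature()].
#' @return Per-cell volumetric sink Q_E (W/m^3, <= 0); zero everywhere
#'   below the vaporization band or once the water budget is exhausted.
#' @export
evaporation_sink <- function(state) {
  stopifnot(inherits(state, "thermal_state"))
  state$Q_E
}

#' Run the segregated multiphysics loop
#'
#' Per time step: update the temperature-dependent dielectric and thermal
#' properties, re-solve the electromagnetic field when the conductivity has
#' drifted beyond `em_resolve_tol` since the last solve (rescaling so port
#' power stays at `P_in`), take one implicit bioheat step, advance the
#' cell-death kinetics and the shrinkage dose, and record region metrics at
#' the output cadence.
#'
#' @param mesh An [build_mesh()] mesh.
#' @param materials A [material_model()].
#' @param P_in Input power (W); 0 runs an unpowered control.
#' @param f Frequency (Hz).
#' @param t_end Treatment duration cap (s).
#' @param dt Time step (s).
#' @param T_init Initial temperature (deg C).
#' @param control A [bioheat_control()].
#' @param em_resolve_tol Relative conductivity drift that triggers an EM
#'   re-solve.
#' @param Q_fixed Optional fixed deposition field (W/m^3, nr x nz); when
#'   given the EM solver is bypassed entirely (used with analytic SAR
#'   surrogates).
#' @param cadence Metric recording interval (s).
#' @param monitor Function `(sim) -> named numeric` evaluated at the
#'   cadence; its values are collected into the trajectory table.
#' @param stop_when Function `(metrics row) -> logical`; the loop ends at
#'   the first cadence where it returns `TRUE`.
#' @return List of class `coupled_run`: final `thermal`, `cells`,
#'   `shrink` states, `em` field (or `NULL`), `trajectory` data frame,
#'   `stop_reason` (`"cap_reached"` or `"stopped"`), `stop_time`, mesh.
#' @export
run_coupled <- function(mesh, materials, P_in, f, t_end, dt = 0.1,
                        T_init = 37, control = bioheat_control(),
                        em_resolve_tol = 0.02, Q_fixed = NULL,
                        cadence = 1, monitor = NULL, stop_when = NULL) {
  stopifnot(t_end > 0, dt > 0)
  template <- bioheat_template(mesh)
  thermal <- thermal_state(mesh, T_init)
  cstate <- cell_state(mesh$nr * mesh$nz, materials$cell_death)
  shrink <- shrinkage_state(mesh$nr * mesh$nz, T0_baseline = T_init,
                            T_ref = T_init)
  em <- NULL; Q <- matrix(0, mesh$nr, mesh$nz)
  if (!is.null(Q_fixed)) {
    stopifnot(all(Q_fixed >= 0))
    Q <- Q_fixed
  }
  rows <- list()
  record <- function(sim, t) {
    vals <- if (is.null(monitor)) c() else monitor(sim)
    c(time_s = t, vals)
  }
  sim <- list(mesh = mesh, materials = materials, thermal = thermal,
              cells = cstate, shrink = shrink, em = em, Q = Q)
  rows[[1]] <- record(sim, 0)
  nstep <- ceiling(t_end / dt - 1e-9)
  rec_every <- max(1L, round(cadence / dt))
  stop_reason <- "cap_reached"; stop_time <- t_end

  for (s in seq_len(nstep)) {
    if (P_in > 0 && is.null(Q_fixed)) {
      dl <- dielectric_fields(mesh, thermal$T, materials)
      if (is.null(em) ||
          needs_resolve(dl$sigma, em$sigma_at_solve, em_resolve_tol)) {
        em <- solve_em(mesh, dl$eps_r, dl$sigma, f, P_in)
        Q <- heat_deposition(em, dl$sigma)$Q
      }
    }
    pmask <- NULL
    if (is.finite(materials$perfusion_shutoff_D))
      pmask <- matrix(cstate$D > materials$perfusion_shutoff_D,
                      mesh$nr, mesh$nz)
    thermal <- step_temperature(thermal, Q, dt, mesh, materials, control,
                                template, perfusion_off = pmask)
    cstate <- step_cell_state(cstate, as.numeric(thermal$T), dt,
                              materials$cell_death)
    shrink <- shrinkage_step(shrink, as.numeric(thermal$T), dt)
    t_now <- s * dt
    if (s %% rec_every == 0 || s == nstep) {
      sim <- list(mesh = mesh, materials = materials, thermal = thermal,
                  cells = cstate, shrink = shrink, em = em, Q = Q)
      row <- record(sim, t_now)
      rows[[length(rows) + 1]] <- row
      if (!is.null(stop_when) && isTRUE(stop_when(row))) {
        stop_reason <- "stopped"; stop_time <- t_now
        break
      }
    }
  }
  traj <- as.data.frame(do.call(rbind, rows))
  structure(list(thermal = thermal, cells = cstate, shrink = shrink,
                 em = em, Q = Q, trajectory = traj,
                 stop_reason = stop_reason,
                 stop_time = if (stop_reason == "stopped") stop_time
                             else min(t_end, nstep * dt),
                 mesh = mesh, materials = materials),
            class = "coupled_run")
}
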