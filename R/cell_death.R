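#' Three-state cell-death kinetics parameters
#'
#' Rate constants of the alive/vulnerable/dead model
#' \eqn{A \rightleftharpoons V \rightarrow D} with forward rate
#' \eqn{k_f = \bar{k}_f e^{T/T_k} (1 - A)} and constant backward (recovery)
#' rate \eqn{k_b}. The defaults are the fitted values of the source
#' three-state hyperthermia model; they are fully configurable because
#' different cell lines calibrate differently.
#'
#' @param kf_bar Forward-rate scaling factor (1/s).
#' @param kb Backward (vulnerable-to-alive recovery) rate (1/s).
#' @param Tk Temperature scale of the exponential rate increase (deg C,
#'   consistent with the temperature input).
#' @param A_init Initial alive fraction. Slightly below 1 by default: the
#'   (1 - A) factor makes A = 1 a fixed point, so a small vulnerable seed is
#'   needed for damage to initiate.
#' @return An object of class `cell_death_params`.
#' @export
cell_death_params <- function(kf_bar = 3.33e-3, kb = 7.77e-3, Tk = 40.5,
                              A_init = 0.99) {
  stopifnot(kf_bar >= 0, kb >= 0, Tk > 0, A_init >= 0, A_init <= 1)
  structure(list(kf_bar = kf_bar, kb = kb, Tk = Tk, A_init = A_init),
            class = "cell_death_params")
}

#' Create a fresh per-node cell state
#'
#' @param n Number of nodes.
#' @param params A [cell_death_params()].
#' @return An object of class `cell_state` with alive fraction `A` and dead
#'   fraction `D`; the vulnerable fraction is `1 - A - D` by construction.
#' @export
cell_state <- function(n, params = cell_death_params()) {
  structure(list(A = rep(params$A_init, n), D = rep(0, n)),
            class = "cell_state")
}

#' Forward damage rate
#'
#' \eqn{k_f = \bar{k}_f e^{T/T_k} (1 - A)}: exponentially increasing in
#' temperature, proportional to the non-alive fraction (zero at A = 1).
#'
#' @param T Temperature (deg C), vectorized.
#' @param A Alive fraction in \[0, 1\], vectorized.
#' @param params A [cell_death_params()].
#' @return Forward rate (1/s).
#' @export
forward_rate <- function(T, A, params = cell_death_params()) {
  stopifnot(all(A >= 0 & A <= 1))
  params$kf_bar * exp(T / params$Tk) * (1 - A)
}

.cell_rhs <- function(A, D, T, params) {
  kf <- params$kf_bar * exp(T / params$Tk) * (1 - A)
  V <- 1 - A - D
  list(dA = -kf * A + params$kb * V, dD = kf * V)
}

#' Advance the cell state by one time step
#'
#' Integrates \eqn{dA/dt = -k_f A + k_b (1 - A - D)},
#' \eqn{dD/dt = k_f (1 - A - D)} per node with classical RK4 on internal
#' substeps sized so the fastest local rate is well resolved. The dead state
#' is absorbing; the state is clipped back onto the simplex only for
#' round-off-size violations (anything above 1e-9 is an integration error
#' and raises).
#'
#' @param state A `cell_state`.
#' @param T_field Per-node temperature (deg C), length matching the state.
#' @param dt Time step (s), > 0.
#' @param params A [cell_death_params()].
#' @param max_substep Upper bound on the internal RK4 substep (s).
#' @return The advanced `cell_state`.
#' @export
step_cell_state <- function(state, T_field, dt, params = cell_death_params(),
                            max_substep = 0.25) {
  stopifnot(inherits(state, "cell_state"), dt > 0,
            length(T_field) == length(state$A))
  A <- state$A; D <- state$D; T <- T_field
  # nodes so hot that the forward rate empties the simplex many times over
  # within dt go straight to the absorbing limit (A, V -> 0, D -> 1);
  # integrating them explicitly would demand absurd substepping while the
  # answer is already saturated
  rate <- params$kf_bar * exp(pmin(T, 2000) / params$Tk)
  sat <- rate * dt > 5
  if (any(sat)) {
    A[sat] <- 0; D[sat] <- 1
    T[sat] <- min(T) # keep saturated nodes out of the substep rule
  }
  # substep: keep (max rate)*h small so RK4 local error is ~1e-10 or better
  rate_max <- max(params$kf_bar * exp(max(T) / params$Tk), params$kb, 1e-12)
  nsub <- max(1L, ceiling(dt / min(max_substep, 0.2 / rate_max)))
  h <- dt / nsub
  for (s in seq_len(nsub)) {
    k1 <- .cell_rhs(A, D, T, params)
    k2 <- .cell_rhs(A + h / 2 * k1$dA, D + h / 2 * k1$dD, T, params)
    k3 <- .cell_rhs(A + h / 2 * k2$dA, D + h / 2 * k2$dD, T, params)
    k4 <- .cell_rhs(A + h * k3$dA, D + h * k3$dD, T, params)
    A <- A + h / 6 * (k1$dA + 2 * k2$dA + 2 * k3$dA + k4$dA)
    D <- D + h / 6 * (k1$dD + 2 * k2$dD + 2 * k3$dD + k4$dD)
  }
  viol <- max(0, -min(A), -min(D), max(A + D) - 1)
  if (viol > 1e-9)
    stop(sprintf("cell-state simplex violation %.3e exceeds 1e-9", viol),
         call. = FALSE)
  A <- pmin(pmax(A, 0), 1)
  D <- pmin(pmax(D, 0), 1 - A)
  structure(list(A = A, D = D), class = "cell_state")
}

#' Extract alive/vulnerable/dead fields and the lesion indicator
#'
#' @param state A `cell_state`.
#' @return List with components `A`, `V`, `D` and `lesion = V + D` (the
#'   field thresholded to delimit the ablation zone).
#' @export
viability_fields <- function(state) {
  stopifnot(inherits(state, "cell_state"))
  V <- 1 - state$A - state$D
  list(A = state$A, V = V, D = state$D, lesion = V + state$D)
}
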