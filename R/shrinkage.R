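#' Temperature-time-integral (TTI) increment
#'
#' The shrinkage dose accumulates the temperature excess over the baseline,
#' weighted by a piecewise coefficient that switches with the current
#' temperature: 0 for T <= 12 degC, 0.1573 up to 44.1 degC, 0.3011 up to
#' 102.1 degC and 0.54163 above. Negative excesses (sub-baseline
#' temperatures) contribute nothing, so TTI is nondecreasing.
#'
#' @param T Current temperature (deg C), vectorized.
#' @param T0_baseline Baseline temperature subtracted inside the integral
#'   (deg C); defaults to the scenario initial temperature.
#' @param dt Time step (s), > 0.
#' @param coefficients Branch coefficients, lowest branch first.
#' @param thresholds Branch edges (deg C).
#' @return TTI increment (deg C s), nonnegative, same shape as `T`.
#' @export
tti_increment <- function(T, T0_baseline = 37, dt,
                          coefficients = c(0, 0.1573, 0.3011, 0.54163),
                          thresholds = c(12, 44.1, 102.1)) {
  stopifnot(dt > 0, length(coefficients) == length(thresholds) + 1)
  idx <- findInterval(T, thresholds, left.open = TRUE) + 1L
  pmax(coefficients[idx] * (T - T0_baseline) * dt, 0)
}

#' Thermal-expansion coefficient from accumulated TTI
#'
#' Power-law contraction coefficient
#' \eqn{\alpha_t = c_1 \mathrm{TTI}^{p} / (T_K - T_{off})} with default
#' constants \eqn{c_1 = -0.03}, \eqn{p = 0.4684}, \eqn{T_{off} = 285} and the
#' temperature in kelvin. Always nonpositive (heated tissue contracts) and
#' zero at zero dose. The printed form of this law is typographically
#' ambiguous; `parsing` selects between the division reading (default) and a
#' product reading \eqn{c_1 \mathrm{TTI}^{p} (T_K - T_{off})^{-1}} scaled to
#' the same units via no denominator at the reference point - results under
#' the non-default parsing are labeled by the attribute `parsing`.
#'
#' @param TTI Accumulated dose (deg C s), nonnegative, vectorized.
#' @param T Temperature; interpreted in deg C and converted to kelvin unless
#'   `T_in_kelvin = TRUE`.
#' @param constants Named list with `c1`, `p`, `offset`.
#' @param parsing `"divide"` (default, denominator \eqn{T_K - 285}) or
#'   `"plain"` (no denominator, exponent applied to TTI only).
#' @param T_in_kelvin Set `TRUE` when `T` is already absolute.
#' @return Thermal-expansion coefficient (1/K), <= 0.
#' @export
alpha_t <- function(TTI, T, constants = list(c1 = -0.03, p = 0.4684, offset = 285),
                    parsing = c("divide", "plain"), T_in_kelvin = FALSE) {
  stopifnot(all(TTI >= 0))
  parsing <- match.arg(parsing)
  TK <- if (T_in_kelvin) T else T + 273.15
  out <- if (parsing == "divide") {
    den <- TK - constants$offset
    if (any(abs(den) < 1e-6))
      stop("alpha_t denominator within 1e-6 of zero", call. = FALSE)
    constants$c1 * TTI^constants$p / den
  } else {
    constants$c1 * TTI^constants$p
  }
  out[TTI == 0] <- 0
  structure(out, parsing = parsing)
}

#' Thermal strain
#'
#' \eqn{E_{th} = \alpha_t (T - T_{ref})}: negative (contraction) for heated
#' tissue since \eqn{\alpha_t \le 0}.
#'
#' @param alpha Thermal-expansion coefficient (1/K), vectorized.
#' @param T Temperature (same scale as `T_ref`).
#' @param T_ref Reference (initial) temperature.
#' @return Dimensionless strain.
#' @export
thermal_strain <- function(alpha, T, T_ref) {
  as.numeric(alpha) * (T - T_ref)
}

#' Volumetric contraction of a region
#'
#' Volume-weighted mean of \eqn{(1 + E_{th})^3 - 1}, clamped at -1 (a cell
#' cannot lose more than its own volume).
#'
#' @param E_th Per-node thermal strain.
#' @param weights Per-node volume weights (e.g. axisymmetric cell volumes);
#'   nodes outside the region get weight 0.
#' @return Fractional volume change \eqn{\Delta V / V} (<= 0 under heating).
#' @export
volumetric_contraction <- function(E_th, weights) {
  stopifnot(length(E_th) == length(weights), sum(weights) > 0)
  dv <- pmax((1 + E_th)^3 - 1, -1)
  sum(dv * weights) / sum(weights)
}

#' Shrinkage accumulator state
#'
#' Tracks per-node TTI through a simulation; [shrinkage_step()] folds in one
#' time step, [shrinkage_report()] converts dose to strain and contraction.
#'
#' @param n Number of nodes.
#' @param T0_baseline Baseline temperature of the TTI integrand (deg C).
#' @param T_ref Reference temperature of the strain law (deg C).
#' @return An object of class `shrinkage_state`.
#' @export
shrinkage_state <- function(n, T0_baseline = 37, T_ref = 37) {
  structure(list(TTI = rep(0, n), T0_baseline = T0_baseline, T_ref = T_ref),
            class = "shrinkage_state")
}

#' @rdname shrinkage_state
#' @param state A `shrinkage_state`.
#' @param T_field Per-node temperature (deg C).
#' @param dt Time step (s).
#' @export
shrinkage_step <- function(state, T_field, dt) {
  state$TTI <- state$TTI +
    tti_increment(T_field, state$T0_baseline, dt)
  state
}

#' @rdname shrinkage_state
#' @param weights Per-node volume weights defining the reported region.
#' @param ... Passed to [alpha_t()] (e.g. `parsing`).
#' @export
shrinkage_report <- function(state, T_field, weights, ...) {
  a <- alpha_t(state$TTI, T_field, ...)
  E <- thermal_strain(a, T_field, state$T_ref)
  list(TTI = state$TTI, alpha_t = as.numeric(a), E_th = E,
       contraction = volumetric_contraction(E, weights))
}
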