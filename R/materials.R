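#' Tissue constitutive parameters
#'
#' Bundles every per-tissue constant the model uses: thermal baseline
#' properties, the affine thermal-conductivity law, the sigmoid
#' temperature-dependence coefficients of the dielectric properties, and the
#' water mass fraction feeding the evaporation enthalpy sink.
#'
#' @param density Tissue density \eqn{\rho} (kg/m^3).
#' @param specific_heat Specific heat capacity \eqn{C} (J/kg K).
#' @param k0 Baseline thermal conductivity (W/m K), measured at `T0_k`.
#' @param T0_k Reference temperature for `k0` (deg C).
#' @param dk Thermal-conductivity slope \eqn{\Delta k} (W/m K per K).
#' @param s1,s2,s3 Relative-permittivity sigmoid coefficients
#'   (`s1` dimensionless amplitude, `s2` dimensionless offset, `s3` 1/degC).
#' @param r1,r2,r3 Electrical-conductivity sigmoid coefficients
#'   (`r1` S/m amplitude, `r2` dimensionless, `r3` 1/degC).
#' @param water_fraction Water mass fraction w in \[0, 1\] consumed by the
#'   vaporization sink.
#' @return An object of class `tissue_params`.
#' @seealso [relative_permittivity()], [electrical_conductivity()],
#'   [thermal_conductivity()]
#' @export
tissue_params <- function(density, specific_heat, k0, T0_k = 37,
                          dk = 0.001161,
                          s1, s2 = 5.223, s3 = 0.0524,
                          r1, r2 = 6.583, r3 = 0.0598,
                          water_fraction = 0.778) {
  stopifnot(density > 0, specific_heat > 0, k0 > 0,
            s1 > 0, s3 > 0, r1 > 0, r3 > 0,
            water_fraction >= 0, water_fraction <= 1)
  structure(list(density = density, specific_heat = specific_heat,
                 k0 = k0, T0_k = T0_k, dk = dk,
                 s1 = s1, s2 = s2, s3 = s3,
                 r1 = r1, r2 = r2, r3 = r3,
                 water_fraction = water_fraction),
            class = "tissue_params")
}

#' Blood parameters for the perfusion heat-exchange term
#'
#' @param density Blood density (kg/m^3).
#' @param specific_heat Blood specific heat (J/kg K).
#' @param temperature Core blood temperature Tb (deg C).
#' @param perfusion_intercept,perfusion_slope Coefficients of the affine
#'   perfusion law \eqn{\omega_b(T)} (1/s and 1/s per deg C); the default pair
#'   gives \eqn{\omega_b = 0.000021 T + 0.0035}.
#' @return An object of class `blood_params`.
#' @export
blood_params <- function(density = 1060, specific_heat = 3600,
                         temperature = 37,
                         perfusion_intercept = 0.0035,
                         perfusion_slope = 0.000021) {
  stopifnot(density > 0, specific_heat > 0)
  structure(list(density = density, specific_heat = specific_heat,
                 temperature = temperature,
                 perfusion_intercept = perfusion_intercept,
                 perfusion_slope = perfusion_slope),
            class = "blood_params")
}

#' Ambient and universal constants
#'
#' @param h Boundary heat-transfer coefficient (W/m^2 K) of the Robin
#'   condition on the outer tissue boundary.
#' @param T0 Surroundings bulk temperature (deg C).
#' @param Qm Metabolic heat source (W/m^3); negligible next to microwave
#'   heating, hence 0 by default.
#' @param eps0 Vacuum permittivity (F/m).
#' @param mu_r Relative permeability (dimensionless).
#' @param latent_heat Latent heat of water vaporization (J/kg).
#' @return An object of class `ambient_params`.
#' @export
ambient_params <- function(h = 430, T0 = 37, Qm = 0,
                           eps0 = 8.854e-12, mu_r = 1,
                           latent_heat = 2.26e6) {
  stopifnot(h >= 0, eps0 > 0, latent_heat >= 0)
  structure(list(h = h, T0 = T0, Qm = Qm, eps0 = eps0, mu_r = mu_r,
                 latent_heat = latent_heat),
            class = "ambient_params")
}

#' Full material model
#'
#' @param healthy,tumor [tissue_params()] for the two tissue regions.
#' @param blood [blood_params()].
#' @param ambient [ambient_params()].
#' @param cell_death [cell_death_params()].
#' @param perfusion_scale Temperature scale assumed by the perfusion law:
#'   `"celsius"` (default) or `"kelvin"`.
#' @param perfusion_shutoff_D Dead fraction above which perfusion is shut off
#'   locally, or `NA` (default) for no damage coupling.
#' @return An object of class `material_model`.
#' @export
material_model <- function(healthy, tumor, blood = blood_params(),
                           ambient = ambient_params(),
                           cell_death = cell_death_params(),
                           perfusion_scale = c("celsius", "kelvin"),
                           perfusion_shutoff_D = NA_real_) {
  stopifnot(inherits(healthy, "tissue_params"), inherits(tumor, "tissue_params"),
            inherits(blood, "blood_params"), inherits(ambient, "ambient_params"))
  structure(list(healthy = healthy, tumor = tumor, blood = blood,
                 ambient = ambient, cell_death = cell_death,
                 perfusion_scale = match.arg(perfusion_scale),
                 perfusion_shutoff_D = perfusion_shutoff_D),
            class = "material_model")
}

#' Packaged default material set for liver tissue and tumor
#'
#' Density/heat-capacity/conductivity values for healthy liver, tumor and
#' blood together with the dielectric sigmoid coefficients at microwave
#' frequencies, the thermal-conductivity slope, the affine perfusion law and
#' the boundary heat-transfer coefficient.
#'
#' @param ... Overrides forwarded to [material_model()].
#' @return A [material_model()].
#' @export
default_materials <- function(...) {
  healthy <- tissue_params(density = 1079, specific_heat = 3540, k0 = 0.52,
                           s1 = 44.3, r1 = 1.80)
  tumor <- tissue_params(density = 1040, specific_heat = 3960, k0 = 0.57,
                         s1 = 54.8, r1 = 2)
  material_model(healthy = healthy, tumor = tumor, ...)
}

.check_T <- function(T) {
  if (!is.numeric(T) || any(!is.finite(T)))
    stop("temperature must be finite numeric", call. = FALSE)
}

#' Relative permittivity as a function of temperature
#'
#' Sigmoid decay \eqn{\epsilon_r(T) = s_1 (1 - 1/(1 + e^{s_2 - s_3 T}))}:
#' dielectric properties fall with rising temperature as tissue water is
#' driven off. Strictly decreasing in T, bounded in (0, s1).
#'
#' @param T Temperature (deg C), scalar or vector.
#' @param params A [tissue_params()].
#' @return Relative permittivity (dimensionless), same shape as `T`.
#' @export
relative_permittivity <- function(T, params) {
  .check_T(T)
  params$s1 * (1 - 1 / (1 + exp(params$s2 - params$s3 * T)))
}

#' Electrical conductivity as a function of temperature
#'
#' Sigmoid decay \eqn{\sigma(T) = r_1 (1 - 1/(1 + e^{r_2 - r_3 T}))} (S/m).
#'
#' @inheritParams relative_permittivity
#' @return Conductivity (S/m).
#' @export
electrical_conductivity <- function(T, params) {
  .check_T(T)
  params$r1 * (1 - 1 / (1 + exp(params$r2 - params$r3 * T)))
}

#' Thermal conductivity as a function of temperature
#'
#' Affine law \eqn{k(T) = k_0 + \Delta k (T - T_{0})} with \eqn{k_0} measured
#' at the reference temperature.
#'
#' @inheritParams relative_permittivity
#' @return Conductivity (W/m K).
#' @export
thermal_conductivity <- function(T, params) {
  .check_T(T)
  k <- params$k0 + params$dk * (T - params$T0_k)
  if (any(k <= 0))
    stop("thermal conductivity evaluated non-positive; check k0/dk", call. = FALSE)
  k
}

#' Blood perfusion rate as a function of temperature
#'
#' Affine law \eqn{\omega_b(T) = 0.000021 T + 0.0035} (1/s) with T in deg C
#' by default, clamped at zero below its root.
#'
#' @param T Temperature (deg C).
#' @param params A [blood_params()].
#' @param scale `"celsius"` (default) or `"kelvin"`: temperature scale the
#'   affine law is evaluated on.
#' @return Perfusion rate (1/s), nonnegative.
#' @export
blood_perfusion <- function(T, params = blood_params(),
                            scale = c("celsius", "kelvin")) {
  .check_T(T)
  scale <- match.arg(scale)
  Tu <- if (scale == "kelvin") T + 273.15 else T
  pmax(params$perfusion_intercept + params$perfusion_slope * Tu, 0)
}

#' Serialize / restore a material model
#'
#' Round-trips every constant through a plain named list (and hence YAML/JSON)
#' bit-exactly.
#'
#' @param model A [material_model()].
#' @return `materials_to_list()`: a named list; `materials_from_list()`: a
#'   [material_model()].
#' @export
materials_to_list <- function(model) {
  stopifnot(inherits(model, "material_model"))
  list(healthy = unclass(model$healthy), tumor = unclass(model$tumor),
       blood = unclass(model$blood), ambient = unclass(model$ambient),
       cell_death = unclass(model$cell_death),
       perfusion_scale = model$perfusion_scale,
       perfusion_shutoff_D = model$perfusion_shutoff_D)
}

#' @rdname materials_to_list
#' @param x A list produced by `materials_to_list()`.
#' @export
materials_from_list <- function(x) {
  material_model(healthy = do.call(tissue_params, x$healthy),
                 tumor = do.call(tissue_params, x$tumor),
                 blood = do.call(blood_params, x$blood),
                 ambient = do.call(ambient_params, x$ambient),
                 cell_death = do.call(cell_death_params, x$cell_death),
                 perfusion_scale = x$perfusion_scale,
                 perfusion_shutoff_D = x$perfusion_shutoff_D)
}
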