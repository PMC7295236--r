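#' Uniform tissue-only test mesh
#'
#' A plain cylinder of healthy tissue (optionally with a centered spherical
#' tumor) on a uniform grid, without any antenna: the workhorse domain for
#' manufactured-solution convergence studies and SAR-surrogate runs where
#' the electromagnetic stage is bypassed.
#'
#' @param radius,height Domain dimensions (m).
#' @param nr,nz Cell counts.
#' @param tumor Optional [make_tumor()] centered at mid-height.
#' @return An `axi_mesh` compatible with every solver in the package.
#' @export
tissue_block_mesh <- function(radius = 0.02, height = 0.04, nr = 24, nz = 48,
                              tumor = NULL) {
  rf <- seq(0, radius, length.out = nr + 1)
  zf <- seq(0, height, length.out = nz + 1)
  rc <- (rf[-1] + rf[-length(rf)]) / 2; zc <- (zf[-1] + zf[-length(zf)]) / 2
  region <- matrix(REG[["healthy"]], nr, nz)
  frac_tumor <- matrix(0, nr, nz)
  z_c <- height / 2
  if (!is.null(tumor)) {
    frac_tumor <- .membership_fraction(rf, zf, function(r, z)
      (r / tumor$semi_r)^2 + ((z - z_c) / tumor$semi_z)^2 <= 1)
    region[frac_tumor > 0.5] <- REG[["tumor"]]
  }
  vol <- outer(pi * (rf[-1]^2 - rf[-length(rf)]^2), diff(zf))
  mesh <- structure(list(
    rf = rf, zf = zf, rc = rc, zc = zc, dr = diff(rf), dz = diff(zf),
    nr = nr, nz = nz, region = region, vol = vol, frac_tumor = frac_tumor,
    tumor = tumor, antenna = NULL, domain = domain_spec(radius, height),
    z_slots = z_c, z_tip = 0, z_center = z_c), class = "axi_mesh")
  mesh$region_volumes <- region_volume_table(mesh)
  mesh
}

#' Manufactured heat-equation problems
#'
#' A small catalog of exact temperature fields \eqn{T^*(r,z,t)} with the
#' volumetric forcing that makes them solve the bioheat equation exactly
#' (constant properties, perfusion optional) and the boundary data
#' consistent with a Robin condition. All catalog entries are linear in
#' time, so a backward-Euler step introduces no temporal error and spatial
#' convergence can be measured cleanly.
#'
#' @param kind `"constant"`, `"linear_t"` (spatially uniform ramp) or
#'   `"cosine"` (separable cosine bump growing linearly in time).
#' @param mesh An `axi_mesh` (typically [tissue_block_mesh()]).
#' @param materials A [material_model()]; conduction uses the healthy-row
#'   baseline `k0` (the catalog assumes temperature-independent k).
#' @param amplitude Spatial amplitude (deg C) for the cosine entry.
#' @param rate Uniform heating rate (deg C/s).
#' @param perfusion Include the perfusion exchange in the forcing balance?
#' @return List with functions `T_exact(t)` (nr x nz matrix),
#'   `forcing(t)` (W/m^3, evaluated at cell centers) and
#'   `robin_g(t)` (extra boundary flux density W/m^2 on each boundary face
#'   making the Robin condition exact), plus the constants used.
#' @export
make_manufactured <- function(kind = c("cosine", "constant", "linear_t"),
                              mesh, materials = default_materials(),
                              amplitude = 10, rate = 0.05,
                              perfusion = FALSE) {
  kind <- match.arg(kind)
  p <- materials$healthy; bl <- materials$blood; amb <- materials$ambient
  rhoC <- p$density * p$specific_heat
  k <- p$k0
  R <- mesh$rf[length(mesh$rf)]; H <- mesh$zf[length(mesh$zf)]
  Tb <- bl$temperature
  base <- amb$T0
  RC <- matrix(mesh$rc, mesh$nr, mesh$nz)
  ZC <- matrix(mesh$zc, mesh$nr, mesh$nz, byrow = TRUE)

  if (kind == "constant") {
    T_exact <- function(t) matrix(base, mesh$nr, mesh$nz)
    lap <- function(t) 0 * RC
    dTdt <- function(t) 0 * RC
  } else if (kind == "linear_t") {
    T_exact <- function(t) matrix(base + rate * t, mesh$nr, mesh$nz)
    lap <- function(t) 0 * RC
    dTdt <- function(t) matrix(rate, mesh$nr, mesh$nz)
  } else {
    # T* = base + A (1 + t/60) cos(pi r / (2R)) cos(pi z / H)
    ar <- pi / (2 * R); az <- pi / H
    shape <- cos(ar * RC) * cos(az * ZC)
    T_exact <- function(t) base + amplitude * (1 + t / 60) * shape
    lap <- function(t) {
      g <- amplitude * (1 + t / 60)
      # axisymmetric Laplacian of cos(ar r) cos(az z):
      # T_rr + T_r / r + T_zz
      g * (-(ar^2 + az^2) * shape -
             ar * sin(ar * RC) / RC * cos(az * ZC))
    }
    dTdt <- function(t) amplitude / 60 * shape
  }

  forcing <- function(t) {
    f <- rhoC * dTdt(t) - k * lap(t)
    if (perfusion) {
      Tex <- T_exact(t)
      wb <- blood_perfusion(Tex, bl, materials$perfusion_scale)
      f <- f - bl$density * bl$specific_heat * wb * (Tb - Tex)
    }
    f
  }
  # extra inward boundary flux g making the solver's Robin condition exact
  # for T*: the solver imposes outward flux h(T_s - T0) - g, while the
  # exact outward flux is -k dT*/dn, so g = h(T* - T0) + k dT*/dn with n
  # the outward normal
  robin_g <- function(t) {
    if (kind != "cosine")
      return(list(r_outer = rep(0, mesh$nz), z_bottom = rep(0, mesh$nr),
                  z_top = rep(0, mesh$nr)))
    gfun <- amplitude * (1 + t / 60)
    ar <- pi / (2 * R); az <- pi / H
    Tex_r <- base + gfun * cos(ar * R) * cos(az * mesh$zc)
    dTdn_r <- gfun * (-ar * sin(ar * R)) * cos(az * mesh$zc)
    Tex_b <- base + gfun * cos(ar * mesh$rc)        # cos(0) = 1
    dTdn_b <- 0 * mesh$rc                           # -dT*/dz = 0 at z = 0
    Tex_t <- base + gfun * cos(ar * mesh$rc) * cos(pi)
    dTdn_t <- 0 * mesh$rc                           # sin(pi) = 0
    list(r_outer = amb$h * (Tex_r - amb$T0) + k * dTdn_r,
         z_bottom = amb$h * (Tex_b - amb$T0) + k * dTdn_b,
         z_top = amb$h * (Tex_t - amb$T0) + k * dTdn_t)
  }
  list(kind = kind, T_exact = T_exact, forcing = forcing, robin_g = robin_g,
       constants = list(rhoC = rhoC, k = k, base = base,
                        amplitude = amplitude, rate = rate))
}

#' Analytic heat-deposition (SAR) surrogates
#'
#' Parametric nonnegative deposition fields standing in for the
#' electromagnetic solve, normalized so the axisymmetric volume integral
#' equals the requested total power. The `axial_gaussian` shape is a
#' separable Gaussian; the `teardrop` shape skews the axial profile so the
#' peak sits near the slot and the tail extends along the antenna, the way
#' ablation zones grow.
#'
#' @param kind `"axial_gaussian"` or `"teardrop"`.
#' @param mesh An `axi_mesh`.
#' @param total_power Total deposited power (W), > 0.
#' @param center_z Axial peak position (m); defaults to the mesh slot level.
#' @param sigma_r,sigma_z Radial/axial length scales (m).
#' @param skew Tail-length multiplier for the teardrop's below-peak side.
#' @return Per-cell deposition matrix (W/m^3) with attribute
#'   `total_power`.
#' @export
make_sar <- function(kind = c("axial_gaussian", "teardrop"), mesh,
                     total_power, center_z = NULL,
                     sigma_r = 3e-3, sigma_z = 6e-3, skew = 2) {
  kind <- match.arg(kind)
  stopifnot(total_power > 0, sigma_r > 0, sigma_z > 0)
  if (is.null(center_z)) center_z <- mesh$z_slots[1]
  RC <- matrix(mesh$rc, mesh$nr, mesh$nz)
  ZC <- matrix(mesh$zc, mesh$nr, mesh$nz, byrow = TRUE)
  shape <- if (kind == "axial_gaussian") {
    exp(-0.5 * (RC / sigma_r)^2 - 0.5 * ((ZC - center_z) / sigma_z)^2)
  } else {
    sz <- ifelse(ZC < center_z, sigma_z * skew, sigma_z)
    exp(-0.5 * (RC / sigma_r)^2 - 0.5 * ((ZC - center_z) / sz)^2)
  }
  shape[mesh$region > REG[["tumor"]]] <- 0
  tot <- sum(shape * mesh$vol)
  Q <- shape * (total_power / tot)
  attr(Q, "total_power") <- total_power
  Q
}

#' Prescribed temperature programs
#'
#' Deterministic T(t) traces driving the cell-death and shrinkage stages in
#' isolation.
#'
#' @param kind `"constant"`, `"ramp"`, `"step"` or `"recorded"`.
#' @param duration Trace duration (s), > 0.
#' @param T0 Starting temperature (deg C).
#' @param T1 Final/plateau temperature (deg C) for ramp and step.
#' @param t_step Switch time (s) for the step program.
#' @param times,values Sample points for `"recorded"` (linearly
#'   interpolated, constant extrapolation).
#' @return A function `T(t)`, vectorized over `t`, with attribute
#'   `duration`.
#' @export
temperature_program <- function(kind = c("constant", "ramp", "step",
                                         "recorded"),
                                duration = 600, T0 = 37, T1 = 60,
                                t_step = 60, times = NULL, values = NULL) {
  kind <- match.arg(kind)
  stopifnot(duration > 0)
  f <- switch(kind,
    constant = function(t) rep(T0, length(t)),
    ramp = function(t) T0 + (T1 - T0) * pmin(pmax(t, 0), duration) / duration,
    step = function(t) ifelse(t < t_step, T0, T1),
    recorded = {
      stopifnot(!is.null(times), !is.null(values),
                length(times) == length(values))
      approxfun(times, values, rule = 2)
    })
  attr(f, "duration") <- duration
  f
}
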