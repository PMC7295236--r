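#' Equal-volume spheroidal tumor shapes
#'
#' Constructs a sphere, prolate or oblate spheroid whose volume equals that
#' of a sphere of radius `r_eq`. The aspect ratio `lambda` is the
#' major-to-minor axis ratio (>= 1). The prolate major axis lies along the
#' antenna (z) axis; the oblate short axis lies along the antenna axis, so
#' its two long semi-axes are in-plane.
#'
#' @param kind `"sphere"`, `"prolate"` or `"oblate"`.
#' @param r_eq Equivalent sphere radius (m), > 0.
#' @param lambda Major-to-minor axis ratio, >= 1; ignored for spheres.
#' @return An object of class `tumor_shape` with minor semi-axis `a`, major
#'   semi-axis `b`, the radial (`semi_r`) and axial (`semi_z`) semi-axes of
#'   the axisymmetric cross-section, and `volume` (m^3).
#' @export
make_tumor <- function(kind = c("sphere", "prolate", "oblate"), r_eq,
                       lambda = 1) {
  kind <- match.arg(kind)
  stopifnot(r_eq > 0)
  if (kind != "sphere" && lambda < 1)
    stop("lambda is major/minor and must be >= 1", call. = FALSE)
  if (kind == "sphere") lambda <- 1
  if (kind == "prolate") {
    a <- r_eq * lambda^(-1 / 3); b <- r_eq * lambda^(2 / 3)
    semi_r <- a; semi_z <- b
  } else if (kind == "oblate") {
    a <- r_eq * lambda^(-2 / 3); b <- r_eq * lambda^(1 / 3)
    semi_r <- b; semi_z <- a
  } else {
    a <- b <- semi_r <- semi_z <- r_eq
  }
  structure(list(kind = kind, r_eq = r_eq, lambda = lambda, a = a, b = b,
                 semi_r = semi_r, semi_z = semi_z,
                 volume = 4 / 3 * pi * r_eq^3),
            class = "tumor_shape")
}

#' Coaxial slot antenna layout
#'
#' Radii of the nested antenna components and axial slot placement. The
#' single-slot layout centers its slot on the tumor center; the double-slot
#' layout places the bottom slot b/2 below the tumor center (b = tumor
#' semi-major axis) and the top slot a distance `L` above the bottom one.
#' Dimensions default to surrogate thin-coax values since the reference
#' design is not fully specified; all are configurable.
#'
#' @param kind `"single_slot"` or `"double_slot"`.
#' @param r_inner Inner-conductor radius (m).
#' @param r_dielectric Dielectric outer radius (m).
#' @param r_outer Outer-conductor radius (m).
#' @param r_catheter Catheter outer radius (m).
#' @param slot_height Axial height of each slot (m).
#' @param L Slot-to-slot distance (m), double-slot only.
#' @param eps_dielectric,eps_catheter Relative permittivities of the coax
#'   dielectric (and slot fill) and the catheter sheath.
#' @return An object of class `antenna_layout`.
#' @export
antenna_layout <- function(kind = c("single_slot", "double_slot"),
                           r_inner = 0.135e-3, r_dielectric = 0.47e-3,
                           r_outer = 0.595e-3, r_catheter = 0.895e-3,
                           slot_height = 1e-3, L = NULL,
                           eps_dielectric = 2.03, eps_catheter = 2.6) {
  kind <- match.arg(kind)
  if (!(r_inner < r_dielectric && r_dielectric < r_outer &&
        r_outer < r_catheter))
    stop("antenna radii must be strictly nested", call. = FALSE)
  if (kind == "double_slot" && is.null(L))
    stop("double_slot layout needs a slot-to-slot distance L", call. = FALSE)
  structure(list(kind = kind, r_inner = r_inner, r_dielectric = r_dielectric,
                 r_outer = r_outer, r_catheter = r_catheter,
                 slot_height = slot_height, L = L,
                 eps_dielectric = eps_dielectric,
                 eps_catheter = eps_catheter),
            class = "antenna_layout")
}

#' Cylindrical simulation domain
#'
#' @param radius Domain radius (m).
#' @param height Domain height (m).
#' @param tip_height Antenna tip height above the domain bottom (m); the
#'   antenna is inserted along the axis from the top boundary.
#' @param tumor_center_z Axial position of the tumor center (m).
#' @return An object of class `domain_spec`.
#' @export
domain_spec <- function(radius = 0.04, height = 0.08, tip_height = 0.01,
                        tumor_center_z = 0.04) {
  structure(list(radius = radius, height = height, tip_height = tip_height,
                 tumor_center_z = tumor_center_z),
            class = "domain_spec")
}

# region codes shared by the solvers
REG <- c(healthy = 1L, tumor = 2L, dielectric = 3L, conductor = 4L,
         catheter = 5L, slot = 6L)

.graded_widths <- function(len, w0, ratio = 1.12, wmax = Inf) {
  w <- numeric(0); tot <- 0; cur <- w0
  while (tot < len) {
    w <- c(w, cur); tot <- tot + cur
    cur <- min(cur * ratio, wmax)
  }
  w * (len / tot)
}

.segment_faces <- function(breaks, widths) {
  faces <- breaks[1]
  for (s in seq_len(length(breaks) - 1)) {
    len <- breaks[s + 1] - breaks[s]
    n <- max(1L, round(len / widths[s]))
    faces <- c(faces, breaks[s] + seq_len(n) / n * len)
  }
  faces
}

#' Build the axisymmetric computational mesh
#'
#' Tensor-product (r,z) finite-volume mesh with faces snapped to every
#' antenna radius, the antenna tip and each slot edge; radial spacing is
#' finest at the antenna surface and grows geometrically outward, axial
#' spacing is fine in a window around the tumor/slots. Each cell carries a
#' region label (healthy, tumor, antenna dielectric, conductor, catheter,
#' slot) assigned at its center, plus a fractional tumor-membership weight
#' from subcell sampling used for accurate region volumes and means.
#'
#' @param tumor A [make_tumor()] shape, or `NULL` for homogeneous tissue.
#' @param antenna An [antenna_layout()].
#' @param domain A [domain_spec()].
#' @param res Resolution multiplier; 1 gives the default desk-scale mesh
#'   (roughly 55 x 90 cells), 2 halves every target spacing.
#' @return An object of class `axi_mesh`: face/center coordinate vectors,
#'   region matrix (nr x nz), axisymmetric cell volumes (m^3), fractional
#'   tumor and (after [monitor_regions()]) shell weights, slot positions and
#'   a region volume table.
#' @export
build_mesh <- function(tumor, antenna = antenna_layout(),
                       domain = domain_spec(), res = 1) {
  R <- domain$radius; H <- domain$height
  z_tip <- domain$tip_height; z_c <- domain$tumor_center_z
  if (!is.null(tumor)) {
    if (tumor$semi_r >= R || z_c + tumor$semi_z >= H || z_c - tumor$semi_z <= 0)
      stop("tumor does not fit inside the domain", call. = FALSE)
  }
  # slot placement relative to the tumor center
  hs <- antenna$slot_height / 2
  if (antenna$kind == "single_slot") {
    z_slots <- z_c
  } else {
    b <- if (is.null(tumor)) 0.01 else tumor$semi_z
    z_slots <- c(z_c - b / 2, z_c - b / 2 + antenna$L)
  }
  if (any(z_slots - hs < z_tip) || any(z_slots + hs > H))
    stop("slots must lie on the antenna shaft inside the domain", call. = FALSE)

  # radial faces: exact antenna radii, then graded tissue spacing
  a <- antenna
  r_ant <- c(0, a$r_inner, a$r_dielectric, a$r_outer, a$r_catheter)
  n_ant <- pmax(1L, round(c(2, 3, 1, 2) * sqrt(res)))
  rf <- 0
  for (s in 1:4)
    rf <- c(rf, r_ant[s] + seq_len(n_ant[s]) / n_ant[s] * (r_ant[s + 1] - r_ant[s]))
  w0 <- 0.14e-3 / res; wmax <- 1.8e-3 / res
  rf <- c(rf, a$r_catheter + cumsum(.graded_widths(R - a$r_catheter, w0,
                                                   wmax = wmax)))
  rf[length(rf)] <- R

  # axial faces: fine window around tumor and slots, snapped breakpoints
  half_win <- max(if (is.null(tumor)) 0.015 else tumor$semi_z + 0.008,
                  max(abs(z_slots - z_c)) + 0.008)
  win <- c(max(0, z_c - half_win), min(H, z_c + half_win))
  breaks <- sort(unique(pmin(pmax(c(0, z_tip, win,
                                    z_slots - hs, z_slots + hs, H), 0), H)))
  breaks <- breaks[c(TRUE, diff(breaks) > 1e-9)]
  wz_fine <- 0.65e-3 / res; wz_coarse <- 2.6e-3 / res
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  widths <- ifelse(mids >= win[1] & mids <= win[2], wz_fine, wz_coarse)
  zf <- .segment_faces(breaks, widths)

  rc <- (rf[-1] + rf[-length(rf)]) / 2; dr <- diff(rf)
  zc <- (zf[-1] + zf[-length(zf)]) / 2; dz <- diff(zf)
  nr <- length(rc); nz <- length(zc)

  RC <- matrix(rc, nr, nz); ZC <- matrix(zc, nr, nz, byrow = TRUE)
  in_antenna <- ZC > z_tip + 1e-12 & RC < a$r_catheter
  in_slot_band <- Reduce(`|`, lapply(z_slots, function(zs)
    ZC > zs - hs & ZC < zs + hs))
  region <- matrix(REG[["healthy"]], nr, nz)
  region[in_antenna & RC < a$r_inner] <- REG[["conductor"]]
  region[in_antenna & RC >= a$r_inner & RC < a$r_dielectric] <- REG[["dielectric"]]
  region[in_antenna & RC >= a$r_dielectric & RC < a$r_outer] <-
    ifelse(in_slot_band[in_antenna & RC >= a$r_dielectric & RC < a$r_outer],
           REG[["slot"]], REG[["conductor"]])
  region[in_antenna & RC >= a$r_outer & RC < a$r_catheter] <- REG[["catheter"]]

  # frac_tumor is the geometric membership of each cell in the tumor
  # spheroid (kept even where the antenna shaft displaces tissue, so the
  # equal-volume bookkeeping across shapes is exact); metrics mask it to
  # tissue cells
  frac_tumor <- matrix(0, nr, nz)
  if (!is.null(tumor)) {
    tissue <- region <= REG[["tumor"]]
    frac_tumor <- .membership_fraction(rf, zf, function(r, z)
      (r / tumor$semi_r)^2 + ((z - z_c) / tumor$semi_z)^2 <= 1)
    region[tissue & frac_tumor > 0.5] <- REG[["tumor"]]
  }
  vol <- outer(pi * (rf[-1]^2 - rf[-length(rf)]^2), dz)

  mesh <- structure(list(
    rf = rf, zf = zf, rc = rc, zc = zc, dr = dr, dz = dz, nr = nr, nz = nz,
    region = region, vol = vol, frac_tumor = frac_tumor,
    tumor = tumor, antenna = antenna, domain = domain,
    z_slots = z_slots, z_tip = z_tip, z_center = z_c), class = "axi_mesh")
  mesh$region_volumes <- region_volume_table(mesh)
  mesh
}

# fraction of each cell inside an analytic region, 4x4 subcell sampling
.membership_fraction <- function(rf, zf, inside) {
  nr <- length(rf) - 1; nz <- length(zf) - 1
  q <- (seq_len(4) - 0.5) / 4
  frac <- matrix(0, nr, nz)
  for (a in q) for (b in q) {
    rp <- rf[-length(rf)] + a * diff(rf)
    zp <- zf[-length(zf)] + b * diff(zf)
    frac <- frac + outer(rp, zp, inside) / 16
  }
  frac
}

#' Region volume table of a mesh
#'
#' @param mesh An [build_mesh()] mesh.
#' @return Data frame of region name and summed axisymmetric volume (m^3);
#'   tumor volume uses the fractional membership weights.
#' @export
region_volume_table <- function(mesh) {
  nm <- names(REG)
  v <- vapply(REG, function(code) sum(mesh$vol[mesh$region == code]), 0)
  tissue <- mesh$region <= REG[["tumor"]]
  v[["tumor"]] <- sum(mesh$vol * mesh$frac_tumor)
  v[["healthy"]] <- sum(mesh$vol[tissue]) -
    sum((mesh$vol * mesh$frac_tumor)[tissue])
  data.frame(region = nm, volume_m3 = as.numeric(v[nm]))
}

#' Healthy monitor shell and fixed monitor point
#'
#' Returns (i) the healthy shell enclosing the tumor whose volume is eight
#' times the tumor volume (a similar spheroid scaled by 9^(1/3)) as a
#' fractional per-cell weight field, and (ii) the index of the fixed monitor
#' point 2.5 mm radially outside the tumor boundary at the tumor-center
#' axial level.
#'
#' @param mesh An [build_mesh()] mesh with a tumor.
#' @param shell_volume_ratio Shell volume as a multiple of tumor volume.
#' @param point_offset Radial monitor-point offset from the tumor border (m).
#' @return List with `frac_shell` (nr x nz fractional weights),
#'   `point_index` (single cell index), `point_r`, `point_z`.
#' @export
monitor_regions <- function(mesh, shell_volume_ratio = 8,
                            point_offset = 2.5e-3) {
  tumor <- mesh$tumor
  if (is.null(tumor)) stop("mesh has no tumor region", call. = FALSE)
  s <- (shell_volume_ratio + 1)^(1 / 3)
  z_c <- mesh$z_center
  if (tumor$semi_r * s > mesh$domain$radius ||
      z_c + tumor$semi_z * s > mesh$domain$height ||
      z_c - tumor$semi_z * s < 0)
    stop("monitor shell exceeds the domain", call. = FALSE)
  frac_outer <- .membership_fraction(mesh$rf, mesh$zf, function(r, z)
    (r / (tumor$semi_r * s))^2 + ((z - z_c) / (tumor$semi_z * s))^2 <= 1)
  tissue <- mesh$region <= REG[["tumor"]]
  frac_shell <- pmax(frac_outer - mesh$frac_tumor, 0)
  frac_shell[!tissue] <- 0
  pr <- tumor$semi_r + point_offset
  i <- which.min(abs(mesh$rc - pr)); j <- which.min(abs(mesh$zc - z_c))
  list(frac_shell = frac_shell,
       point_index = (j - 1L) * mesh$nr + i,
       point_r = mesh$rc[i], point_z = mesh$zc[j])
}
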