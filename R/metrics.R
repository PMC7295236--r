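#' Axisymmetric volume-weighted region mean
#'
#' \eqn{\sum 2\pi r w q / \sum 2\pi r w} over the region's cells: `weights`
#' carries both the region membership (possibly fractional near analytic
#' boundaries) and any quadrature weighting; volumes supply the 2 pi r
#' factor.
#'
#' @param field Per-cell values (nr x nz matrix or vector).
#' @param weights Per-cell region weights in \[0, 1\] (fractional
#'   membership), zero outside the region.
#' @param vol Per-cell axisymmetric volumes (m^3), e.g. `mesh$vol`.
#' @return Scalar mean of `field` over the region.
#' @export
region_mean <- function(field, weights, vol) {
  w <- as.numeric(weights) * as.numeric(vol)
  tot <- sum(w)
  if (tot <= 0) stop("empty region", call. = FALSE)
  sum(as.numeric(field) * w) / tot
}

#' Ablation-zone axes from the lesion field
#'
#' Extracts the super-threshold region of the lesion indicator (V + D) in
#' the (r,z) half-plane. The long axis is the axial extent of the contour;
#' the short axis is twice its maximum radial extent (the full 3-D diameter
#' by rotational symmetry). Crossings are located by linear interpolation
#' between cell centers, so the axes are accurate to a fraction of a cell.
#'
#' @param lesion Per-cell lesion field (nr x nz), e.g.
#'   `viability_fields(state)$lesion`.
#' @param mesh An [build_mesh()] mesh.
#' @param threshold Contour level in (0, 1), default 0.5.
#' @return Named numeric `c(long_axis_m, short_axis_m)`; both zero with
#'   attribute `empty = TRUE` when nothing exceeds the threshold.
#' @export
ablation_axes <- function(lesion, mesh, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  L <- matrix(lesion, mesh$nr, mesh$nz)
  tissue <- mesh$region <= REG[["tumor"]]
  L[!tissue] <- NA_real_
  rc <- mesh$rc; zc <- mesh$zc
  sup <- !is.na(L) & L >= threshold
  if (!any(sup)) {
    out <- c(long_axis_m = 0, short_axis_m = 0)
    attr(out, "empty") <- TRUE
    return(out)
  }
  cross_out <- function(v, x) {
    # outermost value >= threshold along x, interpolated outward
    ok <- !is.na(v) & v >= threshold
    if (!any(ok)) return(NA_real_)
    i <- max(which(ok))
    if (i < length(v) && !is.na(v[i + 1]) && v[i + 1] < threshold)
      x[i] + (v[i] - threshold) / (v[i] - v[i + 1]) * (x[i + 1] - x[i])
    else x[i]
  }
  short <- 2 * max(vapply(seq_len(mesh$nz),
                          function(j) {
                            r <- cross_out(L[, j], rc)
                            if (is.na(r)) -Inf else r
                          }, 0))
  z_hi <- max(vapply(seq_len(mesh$nr),
                     function(i) {
                       z <- cross_out(L[i, ], zc)
                       if (is.na(z)) -Inf else z
                     }, 0))
  z_lo <- min(vapply(seq_len(mesh$nr),
                     function(i) {
                       z <- cross_out(rev(L[i, ]), rev(zc))
                       if (is.na(z)) Inf else z
                     }, 0))
  c(long_axis_m = z_hi - z_lo, short_axis_m = short)
}
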