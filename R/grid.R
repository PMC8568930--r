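#' Model grid for the x-z plume slice
#'
#' Builds the staggered finite-volume grid used by the solver: `nx` columns of
#' width `dx` along the plume axis (x positive offshore) and `nz` layers whose
#' thicknesses are given by `dz` (layer 1 is the surface layer; z is positive
#' upward). Tracers live at cell centres, `u` on vertical (x-normal) faces and
#' `w` on horizontal (z-normal) faces.
#'
#' @param nx Number of columns along the plume axis.
#' @param nz Number of vertical layers (at least 4).
#' @param dx Column width, m.
#' @param dz Vector of layer thicknesses, m, surface first. Recycled to length
#'   `nz` if scalar. The default surface resolution is 1 m.
#' @param H Bottom depth, m. Currently the bottom is flat; `H` must equal
#'   `sum(dz)` (the default).
#'
#' @return An object of class `fp_grid`: a list with `nx`, `nz`, `dx`, `dz`,
#'   `H`, cell-centre depths `zc` (m, positive down for readability of
#'   profiles), interface depths `zf`, face spacings `dzf`, and cell volumes
#'   per unit width `vol` (an `nx` x `nz` matrix, m^2).
#' @examples
#' g <- fp_grid(nx = 20, nz = 6, dx = 500, dz = c(1, 1, 2, 2, 4, 4))
#' g$zc
#' @export
fp_grid <- function(nx, nz, dx, dz = 1, H = NULL) {
  if (length(dz) == 1L) dz <- rep(dz, nz)
  stopifnot(nx >= 3, nz >= 4, length(dz) == nz)
  if (dx <= 0 || any(dz <= 0)) stop("grid spacings must be positive", call. = FALSE)
  depth <- sum(dz)
  if (is.null(H)) H <- depth
  if (length(H) == 1L) H <- rep(H, nx)
  if (any(abs(H - depth) > 1e-9)) {
    stop("flat bottom required: H must equal sum(dz)", call. = FALSE)
  }
  zf <- c(0, cumsum(dz))          # interface depths below surface, m
  zc <- zf[-(nz + 1)] + dz / 2    # centre depths, m
  dzf <- c(dz[1] / 2, (dz[-nz] + dz[-1]) / 2, dz[nz] / 2)  # centre-to-centre (+ half cells at ends)
  nxi <- as.integer(nx); nzi <- as.integer(nz)
  structure(
    list(nx = nxi, nz = nzi, dx = dx, dz = dz, H = H,
         zc = zc, zf = zf, dzf = dzf,
         vol = outer(rep(dx, nx), dz),
         # precomputed per-layer scaling matrices for the hot loops
         i_dz = matrix(1 / dz, nxi, nzi, byrow = TRUE),
         i_dzf = matrix(1 / dzf[2:nzi], nxi, nzi - 1L, byrow = TRUE),
         # linear interpolation weights from layer centres to interior z-faces
         wface_up = matrix(dz[2:nzi] / (dz[1:(nzi - 1L)] + dz[2:nzi]),
                           nxi, nzi - 1L, byrow = TRUE),
         wface_dn = matrix(dz[1:(nzi - 1L)] / (dz[1:(nzi - 1L)] + dz[2:nzi]),
                           nxi, nzi - 1L, byrow = TRUE)),
    class = "fp_grid"
  )
}

#' @export
print.fp_grid <- function(x, ...) {
  cat(sprintf("<fp_grid> %d x %d cells, dx = %g m, depth = %g m (top layer %g m)\n",
              x$nx, x$nz, x$dx, sum(x$dz), x$dz[1]))
  invisible(x)
}
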