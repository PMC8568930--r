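# Finite-volume tracer transport on the staggered slice grid.
#
# Advection is unsplit flux-form upwind with a van Leer harmonic-mean
# limited correction (monotone, positivity-preserving at the CFL used by
# stable_dt(); the correction vanishes at CFL = 1 so a uniform shift by one
# cell is exact).  Diffusion is explicit centred with no-flux walls.  Both
# conserve the domain integral to round-off in closed configurations.

# harmonic-mean (van Leer) limited difference: 2ab/(a+b) where a,b same sign
limited_diff <- function(a, b) {
  p <- a * b
  pos <- p > 0
  den <- a + b
  den[!pos] <- 1
  2 * p * pos / den
}

# Precompute the face-velocity factors shared by every tracer advected with
# the same (u, w, dt): signed upwind velocities and limited-correction
# prefactors.  One call per step serves all ~15 tracer fields.
advect_prepare <- function(u, w, grid, dt, limit = TRUE, Kh = 0, Kv = 0) {
  # Kv may be a scalar or an nx x (nz-1) matrix of face diffusivities (the
  # Richardson-number closure supplies a matrix)
  ui <- u[2:grid$nx, , drop = FALSE]
  wi <- w[, 2:grid$nz, drop = FALSE]
  aui <- abs(ui); awi <- abs(wi)
  list(u = u, w = w, dt = dt, limit = limit, Kh = Kh, Kv = Kv,
       use_Kv = any(Kv > 0),
       up = pmax(u, 0), un = pmin(u, 0),
       wp = pmax(wi, 0), wn = pmin(wi, 0),
       upos = ui > 0, wpos = wi > 0,
       fac_x = if (limit) 0.5 * aui * (1 - aui * dt / grid$dx),
       fac_z = if (limit) 0.5 * awi * (1 - awi * dt * grid$i_dzf))
}

# Advect one tracer with precomputed factors.  left, right: length-nz inflow
# concentrations used where the boundary face velocity points into the domain
# (NULL = treat as wall; inflow there errors).
advect_apply <- function(fld, prep, grid, left = NULL, right = NULL) {
  nx <- grid$nx; nz <- grid$nz; dx <- grid$dx; dt <- prep$dt
  if (is.null(left)) {
    if (any(prep$u[1, ] > 0)) stop("inflow at closed river-end boundary", call. = FALSE)
    left <- rep(0, nz)
  }
  if (is.null(right)) {
    if (any(prep$u[nx + 1, ] < 0)) stop("inflow at closed offshore boundary", call. = FALSE)
    right <- rep(0, nz)
  }
  phiL <- rbind(left, fld)            # upwind value if u > 0, faces 1..nx+1
  phiR <- rbind(fld, right)           # upwind value if u < 0
  Fx <- prep$up * phiL + prep$un * phiR
  D <- fld[-1, , drop = FALSE] - fld[-nx, , drop = FALSE]     # faces 2..nx
  if (prep$limit && nx >= 3) {
    nfi <- nx - 1L
    zrow <- matrix(0, 1, nz)
    Dup <- prep$upos * rbind(zrow, D[-nfi, , drop = FALSE]) +
      (!prep$upos) * rbind(D[-1, , drop = FALSE], zrow)
    Fx[2:nx, ] <- Fx[2:nx, ] + prep$fac_x * limited_diff(Dup, D)
  }
  if (prep$Kh > 0) {                  # fused explicit diffusion (no-flux walls)
    Fx[2:nx, ] <- Fx[2:nx, ] - prep$Kh * D / dx
  }
  # --- z faces (w positive upward; face k sits above layer k) --------------
  Fz <- matrix(0, nx, nz + 1L)
  Fz[, 2:nz] <- prep$wp * fld[, 2:nz, drop = FALSE] +
    prep$wn * fld[, 1:(nz - 1), drop = FALSE]
  Dv <- fld[, -1, drop = FALSE] - fld[, -nz, drop = FALSE]    # across faces 2..nz
  if (prep$limit && nz >= 3) {
    nfk <- nz - 1L
    zcol <- matrix(0, nx, 1)
    Dupv <- prep$wpos * cbind(Dv[, -1, drop = FALSE], zcol) +
      (!prep$wpos) * cbind(zcol, Dv[, -nfk, drop = FALSE])
    # sign: positive-up flux carries -d(phi)/dz correction
    Fz[, 2:nz] <- Fz[, 2:nz] - prep$fac_z * limited_diff(Dupv, Dv)
  }
  if (prep$use_Kv) {
    Fz[, 2:nz] <- Fz[, 2:nz] + prep$Kv * Dv * grid$i_dzf
  }
  new <- fld -
    dt / dx * (Fx[-1, , drop = FALSE] - Fx[-(nx + 1L), , drop = FALSE]) -
    dt * grid$i_dz * (Fz[, 1:nz, drop = FALSE] - Fz[, 2:(nz + 1L), drop = FALSE])
  dimnames(new) <- NULL
  list(field = new,
       in_left = dt * sum(Fx[1, ] * grid$dz),          # > 0 into the domain
       out_right = dt * sum(Fx[nx + 1L, ] * grid$dz))  # > 0 out of the domain
}

# one-shot convenience wrapper (prepare + apply)
advect_field <- function(fld, u, w, grid, dt, left = NULL, right = NULL,
                         limit = TRUE) {
  advect_apply(fld, advect_prepare(u, w, grid, dt, limit), grid, left, right)
}

#' Advect a tracer field one step
#'
#' Flux-form, positivity-preserving (limited upwind) advection by the face
#' velocities `(u, w)`. With closed boundaries (zero boundary-face normal
#' velocity) the domain integral is conserved to round-off, a uniform field is
#' left unchanged by any divergence-free flow, and no new extrema are created.
#'
#' @param field `nx` x `nz` tracer matrix.
#' @param u `(nx+1)` x `nz` face velocities, m/s.
#' @param w `nx` x `(nz+1)` face velocities, m/s, positive upward.
#' @param grid An [fp_grid()].
#' @param dt Time step, s. Must satisfy the advective CFL condition (checked).
#' @param bc_left,bc_right Optional length-`nz` inflow concentrations at the
#'   boundary faces; `NULL` treats the boundary as a wall.
#' @return Updated `nx` x `nz` field.
#' @export
advect_tracer <- function(field, u, w, grid, dt, bc_left = NULL, bc_right = NULL) {
  cfl <- advective_cfl(u, w, grid, dt)
  if (cfl > 1 + 1e-12) {
    stop(sprintf("advective CFL violated (%.3f > 1); reduce dt", cfl), call. = FALSE)
  }
  advect_field(field, u, w, grid, dt, bc_left, bc_right)$field
}

advective_cfl <- function(u, w, grid, dt) {
  nx <- grid$nx; nz <- grid$nz
  cu <- pmax(abs(u[-1, , drop = FALSE]), abs(u[-(nx + 1L), , drop = FALSE])) * dt / grid$dx
  wmax <- pmax(abs(w[, -1, drop = FALSE]), abs(w[, -(nz + 1L), drop = FALSE]))
  max(cu + wmax * dt * grid$i_dz)
}

#' Diffuse a tracer field one step
#'
#' Explicit centred diffusion with constant horizontal/vertical diffusivities
#' and no-flux boundaries: conserves the domain integral and damps extrema
#' monotonically under the stability bound (checked).
#'
#' @param field `nx` x `nz` tracer matrix.
#' @param Kh,Kv Horizontal and vertical diffusivity, m^2/s.
#' @param grid An [fp_grid()].
#' @param dt Time step, s.
#' @return Updated field.
#' @export
diffuse_tracer <- function(field, Kh, Kv, grid, dt) {
  nx <- grid$nx; nz <- grid$nz; dx <- grid$dx; dz <- grid$dz
  dnum <- dt * (2 * Kh / dx^2 + 2 * Kv / (min(dz) * min(grid$dzf[2:nz])))
  if (dnum > 1 + 1e-12) {
    stop(sprintf("diffusive stability bound violated (%.3f > 1)", dnum), call. = FALSE)
  }
  Fx <- matrix(0, nx + 1L, nz)
  Fx[2:nx, ] <- Kh * (field[-1, , drop = FALSE] - field[-nx, , drop = FALSE]) / dx
  Fz <- matrix(0, nx, nz + 1L)   # positive-up flux = +Kv * (phi_below - phi_above)/dzf
  Fz[, 2:nz] <- Kv * (field[, 2:nz, drop = FALSE] -
                      field[, 1:(nz - 1), drop = FALSE]) * grid$i_dzf
  field +
    dt / dx * (Fx[-1, , drop = FALSE] - Fx[-(nx + 1L), , drop = FALSE]) -
    dt * grid$i_dz * (Fz[, 1:nz, drop = FALSE] - Fz[, 2:(nz + 1L), drop = FALSE])
}
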