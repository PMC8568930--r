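# Non-hydrostatic pressure projection on the staggered slice grid.
#
# The Boussinesq momentum equations are advanced explicitly (upwind advection,
# centred viscosity, buoyancy relative to the ambient density profile) and the
# provisional velocity is projected onto the divergence-free subspace by
# solving a variable-coefficient Poisson problem.  The volume-weighted
# operator is symmetric positive definite and is factored once per run
# (sparse Cholesky), so each projection is a pair of triangular solves.
#
# Boundary conditions: the river-end face (i = 1) and the lid/floor faces
# carry prescribed velocities (Neumann for pressure); the offshore face is
# either a wall (closed) or an open boundary realised as a zero-pressure
# ghost column (Dirichlet), which lets the projection carry the net river
# volume flux out of the domain under a rigid lid.

#' Build the pressure-projection operator
#'
#' Assembles and factors the discrete Poisson operator for the grid. Reuse the
#' returned object for every step on that grid.
#'
#' @param grid An [fp_grid()].
#' @param open_right Logical; `TRUE` for an open offshore boundary
#'   (zero-pressure ghost column), `FALSE` for a closed basin (the operator is
#'   then anchored at one cell to remove the constant null space).
#' @return An `fp_poisson` object holding the Cholesky factor.
#' @export
fp_poisson <- function(grid, open_right = TRUE) {
  nx <- grid$nx; nz <- grid$nz; dx <- grid$dx
  dz <- grid$dz; dzf <- grid$dzf
  n <- nx * nz
  idx <- function(i, k) (k - 1L) * nx + i
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  add <- function(r, c, v) {
    ii <<- c(ii, r); jj <<- c(jj, c); vv <<- c(vv, v)
  }
  for (k in seq_len(nz)) {
    ch <- dz[k] / dx                 # horizontal face conductance
    for (i in seq_len(nx)) {
      r <- idx(i, k); diag <- 0
      if (i > 1)  { add(r, idx(i - 1L, k), -ch); diag <- diag + ch }
      if (i < nx) { add(r, idx(i + 1L, k), -ch); diag <- diag + ch }
      if (i == nx && open_right) diag <- diag + ch   # phi = 0 ghost column
      if (k > 1)  { cv <- dx / dzf[k];      add(r, idx(i, k - 1L), -cv); diag <- diag + cv }
      if (k < nz) { cv <- dx / dzf[k + 1L]; add(r, idx(i, k + 1L), -cv); diag <- diag + cv }
      if (!open_right && i == 1L && k == 1L) diag <- diag + dx  # anchor (closed basin)
      add(r, r, diag)
    }
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
  structure(list(ch = Matrix::Cholesky(Matrix::forceSymmetric(A)),
                 open_right = open_right, nx = nx, nz = nz),
            class = "fp_poisson")
}

# velocity divergence at cell centres, 1/s
divergence <- function(u, w, grid) {
  nx <- grid$nx; nz <- grid$nz
  (u[-1, , drop = FALSE] - u[-(nx + 1L), , drop = FALSE]) / grid$dx +
    grid$i_dz * (w[, 1:nz, drop = FALSE] - w[, 2:(nz + 1L), drop = FALSE])
}

# Project (u, w) onto the discretely divergence-free subspace.  Prescribed
# faces (river end, lid, floor; offshore too when closed) are not modified.
project_velocity <- function(u, w, grid, ps, dt) {
  nx <- grid$nx; nz <- grid$nz
  div <- divergence(u, w, grid)
  rhs <- -as.vector(div * grid$vol) / dt                         # volume-weighted
  phi <- matrix(as.vector(Matrix::solve(ps$ch, rhs)), nx, nz)
  u[2:nx, ] <- u[2:nx, , drop = FALSE] -
    dt * (phi[-1, , drop = FALSE] - phi[-nx, , drop = FALSE]) / grid$dx
  if (ps$open_right) {
    u[nx + 1L, ] <- u[nx + 1L, ] + dt * phi[nx, ] / grid$dx
  }
  w[, 2:nz] <- w[, 2:nz, drop = FALSE] -
    dt * (phi[, 1:(nz - 1L), drop = FALSE] - phi[, 2:nz, drop = FALSE]) * grid$i_dzf
  list(u = u, w = w, phi = phi, max_div = max(abs(divergence(u, w, grid))))
}

# vertical diffusion tendency of a face- or centre-registered field with
# zero-flux (free-slip) ends; spacing: thickness of the control volumes and
# centre-to-centre distances
vdiff_tendency <- function(fld, K, thick, sep) {
  n <- ncol(fld)
  nr <- nrow(fld)
  Fz <- matrix(0, nr, n + 1L)
  if (n >= 2) {
    Fz[, 2:n] <- K * (fld[, 2:n, drop = FALSE] - fld[, 1:(n - 1L), drop = FALSE]) *
      matrix(1 / sep, nr, n - 1L, byrow = TRUE)
  }
  -(Fz[, 1:n, drop = FALSE] - Fz[, 2:(n + 1L), drop = FALSE]) *
    matrix(1 / thick, nr, n, byrow = TRUE)
}

#' Advance the momentum equations one step
#'
#' Upwind momentum advection, eddy viscosity, buoyancy from
#' [equation_of_state()] relative to the ambient density profile, optional
#' Coriolis coupling to a transverse velocity `v` (when `phys$f != 0`), and a
#' pressure projection enforcing discrete incompressibility. A resting state
#' whose density equals the ambient profile is preserved exactly.
#'
#' @param state An `fp_state`.
#' @param phys An [fp_phys()].
#' @param grid An [fp_grid()].
#' @param dt Time step, s.
#' @param ps An [fp_poisson()] operator for this grid.
#' @param rho_ambient Length-`nz` ambient density profile, kg/m^3, subtracted
#'   from the buoyancy term (defaults to the horizontal mean of the state's
#'   own density).
#' @param u_left Prescribed river-end face velocity profile (length `nz`),
#'   m/s; defaults to a wall.
#' @return The state with updated `u`, `w` (and `v`), `eta` diagnosed from the
#'   surface pressure, and attribute `max_div` (s^-1, after projection).
#' @export
momentum_step <- function(state, phys, grid, dt, ps,
                          rho_ambient = NULL, u_left = NULL) {
  nx <- grid$nx; nz <- grid$nz; dx <- grid$dx
  dz <- grid$dz; dzf <- grid$dzf
  u <- state$u; w <- state$w
  rho <- equation_of_state(state$T, state$S, state$C, phys)
  if (is.null(rho_ambient)) rho_ambient <- colMeans(rho)

  # --- u tendencies on interior x-faces (2..nx) ---------------------------
  ui <- u[2:nx, , drop = FALSE]
  dudx_b <- (u[2:nx, , drop = FALSE] - u[1:(nx - 1L), , drop = FALSE]) / dx
  dudx_f <- (u[3:(nx + 1L), , drop = FALSE] - u[2:nx, , drop = FALSE]) / dx
  upos <- ui > 0
  adv_x <- ui * (upos * dudx_b + (!upos) * dudx_f)
  wu <- 0.25 * (w[1:(nx - 1L), 1:nz, drop = FALSE] + w[2:nx, 1:nz, drop = FALSE] +
                w[1:(nx - 1L), 2:(nz + 1L), drop = FALSE] + w[2:nx, 2:(nz + 1L), drop = FALSE])
  # upwind du/dz (z positive up; column k-1 lies above column k)
  dudz_i <- (ui[, 1:(nz - 1L), drop = FALSE] - ui[, 2:nz, drop = FALSE]) *
    grid$i_dzf[1:(nx - 1L), , drop = FALSE]
  zcol1 <- matrix(0, nx - 1L, 1)
  dudz_up <- cbind(zcol1, dudz_i)                     # used when w < 0 (from above)
  dudz_dn <- cbind(dudz_i, zcol1)                     # used when w > 0 (from below)
  wpos <- wu > 0
  adv_z <- wu * (wpos * dudz_dn + (!wpos) * dudz_up)
  visc_u <- phys$Ah * (u[3:(nx + 1L), , drop = FALSE] - 2 * ui +
                       u[1:(nx - 1L), , drop = FALSE]) / dx^2 +
    vdiff_tendency(ui, phys$Av, dz, dzf[2:nz])
  du <- -adv_x - adv_z + visc_u
  if (phys$f != 0) {
    if (is.null(state$v)) state$v <- matrix(0, nx + 1L, nz)
    vi <- state$v[2:nx, , drop = FALSE]
    du <- du + phys$f * vi
    dv <- -phys$f * ui + vdiff_tendency(vi, phys$Av, dz, dzf[2:nz])
    state$v[2:nx, ] <- vi + dt * dv
  }

  # --- w tendencies on interior z-faces (2..nz) ---------------------------
  wi <- w[, 2:nz, drop = FALSE]
  uw <- 0.25 * (u[1:nx, 1:(nz - 1L), drop = FALSE] + u[2:(nx + 1L), 1:(nz - 1L), drop = FALSE] +
                u[1:nx, 2:nz, drop = FALSE] + u[2:(nx + 1L), 2:nz, drop = FALSE])
  dwdx_b <- (wi - rbind(wi[1, , drop = FALSE], wi[-nx, , drop = FALSE])) / dx
  dwdx_f <- (rbind(wi[-1, , drop = FALSE], wi[nx, , drop = FALSE]) - wi) / dx
  upw <- uw > 0
  adv_wx <- uw * (upw * dwdx_b + (!upw) * dwdx_f)
  # vertical upwind dw/dz: faces kf = 2..nz, separated by layer thicknesses
  nf <- nz - 1L
  dwdz_i <- (wi[, 1:(nf - 1L), drop = FALSE] - wi[, 2:nf, drop = FALSE]) *
    matrix(1 / dz[2:nf], nx, nf - 1L, byrow = TRUE)
  dwdz_dn <- cbind(dwdz_i, wi[, nf] / dz[nz])         # below face nz is the floor (w = 0)
  dwdz_up <- cbind(-wi[, 1] / dz[1], dwdz_i)          # above face 2 is the lid (w = 0)
  wfpos <- wi > 0
  adv_wz <- wi * (wfpos * dwdz_dn + (!wfpos) * dwdz_up)
  rho_f <- grid$wface_up * rho[, 1:nf, drop = FALSE] +
    grid$wface_dn * rho[, 2:nz, drop = FALSE]
  rhoa_f <- (rho_ambient[1:nf] * dz[2:nz] + rho_ambient[2:nz] * dz[1:nf]) /
    (dz[1:nf] + dz[2:nz])
  buoy <- -phys$g / phys$rho0 *
    (rho_f - matrix(rhoa_f, nx, nf, byrow = TRUE))
  visc_w <- phys$Ah * (rbind(wi[-1, , drop = FALSE], wi[nx, , drop = FALSE]) - 2 * wi +
                       rbind(wi[1, , drop = FALSE], wi[-nx, , drop = FALSE])) / dx^2 +
    vdiff_tendency(wi, phys$Av, dzf[2:nz], dz[2:nf])
  dwten <- -adv_wx - adv_wz + buoy + visc_w

  # --- provisional velocities and boundaries ------------------------------
  # The buoyancy restoring force is treated implicitly per face:
  # w' = (w + dt*F)/(1 + dt^2 N^2), the backward-Euler solution of the local
  # buoyancy oscillation.  Unconditionally stable; damps internal-wave
  # frequencies the step cannot resolve while the projection preserves the
  # slow, continuity-driven circulation.
  N2f <- pmax(0, -phys$g / phys$rho0 *
                (rho[, 1:nf, drop = FALSE] - rho[, 2:nz, drop = FALSE]) *
                grid$i_dzf)
  u[2:nx, ] <- ui + dt * du
  w[, 2:nz] <- (wi + dt * dwten) / (1 + dt^2 * N2f)
  u[1, ] <- if (is.null(u_left)) 0 else u_left
  if (!ps$open_right) u[nx + 1L, ] <- 0
  w[, 1] <- 0; w[, nz + 1L] <- 0

  pr <- project_velocity(u, w, grid, ps, dt)
  state$u <- pr$u; state$w <- pr$w
  state$eta <- pr$phi[, 1] / phys$g   # rigid-lid surface pressure head, m
  attr(state, "max_div") <- pr$max_div
  state
}
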