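#' Rubey (1933) settling velocity
#'
#' Empirical particle fall speed bridging the viscous (Stokes) and inertial
#' regimes:
#' \deqn{w_s = F \sqrt{g\,d\,(s-1)},\quad
#'       F = \sqrt{\tfrac{2}{3} + \tfrac{36\nu^2}{g d^3 (s-1)}}
#'         - \sqrt{\tfrac{36\nu^2}{g d^3 (s-1)}},\quad s = \rho_{sed}/\rho_w.}
#' For small grains this reduces to Stokes' law \eqn{g d^2 (s-1)/(18\nu)}; for
#' large grains \eqn{F \to \sqrt{2/3}}. Strictly increasing in diameter.
#'
#' @param d Particle diameter, m (> 0). Vectorised.
#' @param rho_sed Grain density, kg/m^3 (> `rho_w`).
#' @param rho_w Water density, kg/m^3.
#' @param nu Kinematic viscosity of water, m^2/s.
#' @param g Gravitational acceleration, m/s^2.
#' @return Settling speed, m/s (positive downward).
#' @references Rubey, W.W. (1933) Settling velocities of gravel, sand and silt
#'   particles. American Journal of Science 25, 325-338.
#' @examples
#' rubey_settling_velocity(d = c(0.01e-3, 0.05e-3))
#' @export
rubey_settling_velocity <- function(d, rho_sed = 2650, rho_w = 1023,
                                    nu = 1.0e-6, g = 9.81) {
  if (any(d <= 0)) stop("particle diameter must be positive", call. = FALSE)
  if (any(rho_sed <= rho_w) || any(rho_w <= 0)) {
    stop("need rho_sed > rho_w > 0", call. = FALSE)
  }
  s1 <- rho_sed / rho_w - 1
  visc <- 36 * nu^2 / (g * d^3 * s1)
  F_fac <- sqrt(2 / 3 + visc) - sqrt(visc)
  F_fac * sqrt(g * d * s1)
}

#' Sediment class: one grain size and its derived settling speed
#'
#' Each sensitivity case uses a single particle diameter (one size class per
#' run). The settling speed is derived from [rubey_settling_velocity()] at
#' construction and stored.
#'
#' @param d Particle diameter, m.
#' @param rho_sed Grain density, kg/m^3 (default 2650).
#' @param phys [fp_phys()] set providing water density, viscosity and gravity.
#' @return An `fp_sediment` object with fields `d`, `rho_sed`, `ws` (m/s).
#' @export
fp_sediment <- function(d, rho_sed = 2650, phys = fp_phys(rho_sed = rho_sed)) {
  ws <- rubey_settling_velocity(d, rho_sed, phys$rho0, phys$nu, phys$g)
  structure(list(d = d, rho_sed = rho_sed, ws = ws), class = "fp_sediment")
}

#' @export
print.fp_sediment <- function(x, ...) {
  cat(sprintf("<fp_sediment> d = %g mm, rho = %g kg/m3, ws = %.3g mm/s (%.1f m/day)\n",
              x$d * 1e3, x$rho_sed, x$ws * 1e3, x$ws * 86400))
  invisible(x)
}

#' Create an empty deposition ledger
#'
#' Deposition is terminal: sediment reaching the seafloor stays there (no
#' resuspension). The ledger records per-column deposited mass and, as the run
#' proceeds, the cumulative riverine input, open-boundary export and sponge
#' export needed to audit SSM mass closure.
#'
#' @param grid An [fp_grid()].
#' @return An `fp_ledger` object: `deposit` (kg/m^2 per column), plus scalar
#'   accumulators `input`, `outflow`, `sponge` (kg per unit width).
#' @export
fp_ledger <- function(grid) {
  structure(list(deposit = numeric(grid$nx), input = 0, outflow = 0, sponge = 0),
            class = "fp_ledger")
}

# Vertical settling of a cell-centred concentration field at speed ws
# (positive downward).  First-order downward upwind flux in mass form, with
# the per-layer outflux fraction capped at 1 (a cell can lose at most its
# content), so the scheme is conservative, monotone and positive for any dt
# and reduces to plain upwind when ws*dt <= dz.  The mass through the bottom
# face of the deepest layer is returned so the caller can deposit it (SSM) or
# remineralise it (detritus).
settle_field <- function(fld, ws, grid, dt) {
  if (ws == 0 || dt == 0) {
    return(list(field = fld, bottom_flux = numeric(grid$nx)))
  }
  nz <- grid$nz
  frac <- pmin(1, ws * dt * grid$i_dz)      # fraction of each layer leaving
  m_out <- frac * fld / grid$i_dz           # mass per area leaving downward
  m_in <- cbind(0, m_out[, -nz, drop = FALSE])
  fld <- fld + (m_in - m_out) * grid$i_dz
  list(field = fld, bottom_flux = m_out[, nz])  # kg/m^2 over dt
}

#' Apply gravitational settling of SSM and record deposition
#'
#' Moves suspended sediment downward at the class settling speed with a
#' first-order upwind flux (sub-stepped so the settling CFL stays below one)
#' and accumulates the flux through the seafloor in the deposition ledger.
#' Column mass (water column + deposit) is conserved to round-off.
#'
#' @param state An `fp_state` (see [fp_state()]).
#' @param sed An [fp_sediment()] class.
#' @param grid An [fp_grid()].
#' @param dt Time step, s.
#' @param ledger An [fp_ledger()].
#' @return List with updated `state` and `ledger`.
#' @export
apply_settling <- function(state, sed, grid, dt, ledger) {
  out <- settle_field(state$C, sed$ws, grid, dt)
  state$C <- out$field
  ledger$deposit <- ledger$deposit + out$bottom_flux
  list(state = state, ledger = ledger)
}
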