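#' Physical parameters of the solver
#'
#' Reference densities, linear equation-of-state coefficients, eddy
#' viscosities/diffusivities and gravity. Defaults describe a warm,
#' salt-stratified coastal sea in late summer; the sediment grain density
#' default is 2650 kg/m^3 (quartz-like mineral composition).
#'
#' @param rho0 Reference seawater density, kg/m^3.
#' @param alpha Thermal expansion coefficient, 1/degC.
#' @param beta Haline contraction coefficient, 1/psu.
#' @param T0,S0 Reference temperature (degC) and salinity (psu) at which the
#'   linear equation of state returns exactly `rho0`.
#' @param rho_sed Sediment grain density, kg/m^3.
#' @param nu Molecular kinematic viscosity of water, m^2/s.
#' @param g Gravitational acceleration, m/s^2.
#' @param Ah,Av Horizontal and vertical eddy viscosity, m^2/s.
#' @param Kh,Kv Horizontal and background vertical eddy diffusivity, m^2/s.
#' @param Kv_shear Shear-driven vertical diffusivity ceiling for the
#'   Richardson-number closure (see [shear_diffusivity()]), m^2/s; 0 turns the
#'   closure off (constant `Kv`).
#' @param convect_mix Homogenisation fraction used by [convective_adjust()]
#'   inside the coupled step, in \[0, 1\]; the remainder of each overturning
#'   event is parcel displacement.
#' @param f Coriolis parameter, 1/s; 0 disables the transverse momentum
#'   equation (pure 2-D slice).
#'
#' @return An object of class `fp_phys` (a validated list).
#' @export
fp_phys <- function(rho0 = 1023.0, alpha = 2.5e-4, beta = 7.6e-4,
                    T0 = 26.0, S0 = 32.8,
                    rho_sed = 2650, nu = 1.0e-6, g = 9.81,
                    Ah = 5.0, Av = 1.0e-4, Kh = 5.0, Kv = 5.0e-5,
                    Kv_shear = 5.0e-4, convect_mix = 0.3, f = 0) {
  p <- list(rho0 = rho0, alpha = alpha, beta = beta, T0 = T0, S0 = S0,
            rho_sed = rho_sed, nu = nu, g = g,
            Ah = Ah, Av = Av, Kh = Kh, Kv = Kv, Kv_shear = Kv_shear,
            convect_mix = convect_mix, f = f)
  if (convect_mix < 0 || convect_mix > 1) {
    stop("convect_mix must be in [0, 1]", call. = FALSE)
  }
  if (!(rho_sed > rho0 && rho0 > 0)) stop("need rho_sed > rho0 > 0", call. = FALSE)
  if (nu <= 0 || g <= 0 || Ah < 0 || Av < 0 || Kh < 0 || Kv < 0) {
    stop("viscosities, diffusivities, nu and g must be non-negative (nu, g > 0)",
         call. = FALSE)
  }
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0", call. = FALSE)
  structure(p, class = "fp_phys")
}

#' Density of seawater carrying suspended sediment
#'
#' Linear equation of state for the water phase plus the bulk-density
#' contribution of suspended sediment matter (SSM):
#' \deqn{\rho = \rho_w(T,S) + (1 - \rho_w/\rho_{sed})\,C,\qquad
#'       \rho_w = \rho_0\,(1 - \alpha (T - T_0) + \beta (S - S_0)).}
#' The SSM term is the volume-weighted mixture density of water and mineral
#' grains: it vanishes at `C = 0` and reaches `rho_sed` exactly in the
#' pure-sediment limit `C = rho_sed`. Density is strictly increasing in `C`
#' (slope between 0 and 1) and `S`, decreasing in `T`.
#'
#' @param T Temperature, degC.
#' @param S Salinity, psu (>= 0).
#' @param C SSM concentration, kg/m^3 (>= 0).
#' @param phys An [fp_phys()] parameter set.
#' @return Density, kg/m^3, with the shape of the broadcast inputs.
#' @examples
#' p <- fp_phys()
#' equation_of_state(p$T0, p$S0, 0, p) # == p$rho0
#' @export
equation_of_state <- function(T, S, C, phys) {
  if (any(!is.finite(T)) || any(!is.finite(S)) || any(!is.finite(C))) {
    stop("non-finite input to equation_of_state", call. = FALSE)
  }
  if (any(C < 0)) stop("negative SSM concentration", call. = FALSE)
  if (any(S < 0)) stop("negative salinity", call. = FALSE)
  rho_w <- phys$rho0 * (1 - phys$alpha * (T - phys$T0) + phys$beta * (S - phys$S0))
  rho_w + (1 - rho_w / phys$rho_sed) * C
}

#' SSM concentration at which river water matches an ambient density
#'
#' Closed-form inversion of [equation_of_state()]: the concentration `C*` at
#' which fresh river water (salinity `S_river`, temperature `T_river`) has the
#' same density as ambient seawater, i.e. the hypopycnal/hyperpycnal crossing
#' point of the density-difference axis.
#'
#' @param T_river,S_river River water temperature (degC) and salinity (psu).
#' @param T_amb,S_amb Ambient surface temperature and salinity.
#' @param phys An [fp_phys()] parameter set.
#' @return Crossing concentration, kg/m^3 (negative when river water is
#'   already denser than ambient without any sediment).
#' @export
crossing_concentration <- function(T_river, S_river, T_amb, S_amb, phys) {
  rho_r <- equation_of_state(T_river, S_river, 0, phys)
  rho_a <- equation_of_state(T_amb, S_amb, 0, phys)
  (rho_a - rho_r) / (1 - rho_r / phys$rho_sed)
}
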