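#' Biological (NPZD) parameters
#'
#' Parameter set for the nitrogen-based nutrient-phytoplankton-zooplankton-
#' detritus model. Functional forms (declared, with literature-style
#' defaults): Michaelis-Menten nitrate uptake with an Eppley temperature
#' factor `exp(kT*T)` and a Steele optimum-light factor; Ivlev grazing with a
#' threshold; linear plankton mortality to detritus; detritus remineralisation
#' back to nitrate; detritus sinks at `wD` through the settling machinery and
#' is remineralised into the bottom cell so the nitrogen budget stays closed.
#'
#' @param Vmax Maximum phytoplankton uptake at 0 degC, 1/day.
#' @param Ks Half-saturation for nitrate, mol N/m^3.
#' @param Iopt Optimum light intensity, W/m^2 (default 65).
#' @param kT Temperature coefficient, 1/degC.
#' @param kw Background light attenuation, 1/m.
#' @param kp Phytoplankton self-shading attenuation, m^2/(mol N/m^3)/m
#'   (i.e. per metre per unit concentration).
#' @param Rmax Maximum grazing rate, 1/day.
#' @param lambda_ivlev Ivlev constant, m^3/mol N.
#' @param P0 Grazing threshold, mol N/m^3.
#' @param mP,mZ Phytoplankton and zooplankton mortality, 1/day.
#' @param gamma Zooplankton assimilation efficiency, in (0, 1].
#' @param rD Detritus remineralisation rate, 1/day.
#' @param wD Detritus sinking speed, m/s.
#' @param chl_per_N Chlorophyll-a yield, ug chl.a per umol N (default 1.59
#'   from Redfield C:N = 106:16 and C:chl = 50 g/g).
#' @return An `fp_bio` parameter object.
#' @export
fp_bio <- function(Vmax = 0.4, Ks = 1.0e-3, Iopt = 65, kT = 0.0693,
                   kw = 0.15, kp = 30, Rmax = 0.3, lambda_ivlev = 1400,
                   P0 = 2e-4, mP = 0.05, mZ = 0.08, gamma = 0.7,
                   rD = 0.05, wD = 1.0e-4, chl_per_N = 1.59) {
  p <- list(Vmax = Vmax, Ks = Ks, Iopt = Iopt, kT = kT, kw = kw, kp = kp,
            Rmax = Rmax, lambda_ivlev = lambda_ivlev, P0 = P0,
            mP = mP, mZ = mZ, gamma = gamma, rD = rD, wD = wD,
            chl_per_N = chl_per_N)
  rates <- c(Vmax, Ks, Rmax, lambda_ivlev, P0, mP, mZ, rD, wD, kw, kp)
  if (any(rates < 0)) stop("rates must be non-negative", call. = FALSE)
  if (!(gamma > 0 && gamma <= 1)) stop("gamma must be in (0, 1]", call. = FALSE)
  if (Iopt <= 0) stop("Iopt must be positive", call. = FALSE)
  structure(p, class = "fp_bio")
}

#' Photosynthetically active light profile
#'
#' Downward attenuation of surface irradiance by water and phytoplankton
#' self-shading: \eqn{I(z) = I_0 \exp(-\int_0^z (k_w + k_p P)\,dz')}, with the
#' optical depth integral evaluated by the trapezoidal rule on cell-centre
#' depths. Suspended sediment does not attenuate light here.
#'
#' @param I_surface Surface PAR irradiance, W/m^2 (>= 0).
#' @param P Phytoplankton field, mol N/m^3: `nz` profile or `nx` x `nz` matrix.
#' @param grid An [fp_grid()].
#' @param bio An [fp_bio()].
#' @return Irradiance at cell centres, W/m^2, same shape as `P` (matrix in,
#'   matrix out). Non-negative and non-increasing with depth in each column.
#' @export
light_profile <- function(I_surface, P, grid, bio) {
  if (any(I_surface < 0)) stop("surface irradiance must be >= 0", call. = FALSE)
  vec_in <- !is.matrix(P)
  if (vec_in) P <- matrix(P, 1)
  a <- bio$kw + bio$kp * P                       # attenuation at centres, 1/m
  zc <- grid$zc
  nz <- grid$nz
  tau <- matrix(0, nrow(P), nz)
  tau[, 1] <- a[, 1] * zc[1]                     # constant above first centre
  for (k in 2:nz) {
    tau[, k] <- tau[, k - 1L] + 0.5 * (a[, k - 1L] + a[, k]) * (zc[k] - zc[k - 1L])
  }
  I <- I_surface * exp(-tau)
  if (vec_in) I[1, ] else I
}

#' Steele optimum-light photosynthesis factor
#'
#' \eqn{(I/I_{opt})\exp(1 - I/I_{opt})}: rises to 1 at `I = Iopt`, with
#' photoinhibition above the optimum.
#'
#' @param I Irradiance, W/m^2 (>= 0). Vectorised.
#' @param Iopt Optimum irradiance, W/m^2.
#' @return Dimensionless factor in \[0, 1\].
#' @export
steele_light_factor <- function(I, Iopt) {
  if (any(I < 0)) stop("irradiance must be >= 0", call. = FALSE)
  r <- I / Iopt
  r * exp(1 - r)
}

#' NPZD source terms
#'
#' Tendencies of nitrate (N), phytoplankton (P), zooplankton (Z) and detritus
#' (Dt), mol N/m^3/day:
#' uptake `Vmax exp(kT*T) N/(N+Ks) f(I) P`, Ivlev grazing
#' `Rmax max(0, 1 - exp(-lambda (P - P0))) Z`, linear mortalities, and
#' detritus remineralisation. The four tendencies sum to zero exactly
#' (detritus sinking is transport and is handled elsewhere).
#'
#' @param N,P,Z,Dt State concentrations, mol N/m^3 (>= 0). Vectorised.
#' @param T Temperature, degC.
#' @param I Irradiance, W/m^2.
#' @param bio An [fp_bio()].
#' @return List of `dN`, `dP`, `dZ`, `dDt` (mol N/m^3/day) and the `uptake`
#'   and `grazing` fluxes.
#' @export
npzd_tendencies <- function(N, P, Z, Dt, T, I, bio) {
  if (any(N < 0) || any(P < 0) || any(Z < 0) || any(Dt < 0)) {
    stop("NPZD state must be non-negative", call. = FALSE)
  }
  uptake <- bio$Vmax * exp(bio$kT * T) * N / (N + bio$Ks) *
    steele_light_factor(I, bio$Iopt) * P
  uptake[N + bio$Ks == 0] <- 0
  grazing <- bio$Rmax * pmax(0, 1 - exp(-bio$lambda_ivlev * (P - bio$P0))) * Z
  dP <- uptake - grazing - bio$mP * P
  dZ <- bio$gamma * grazing - bio$mZ * Z
  dDt <- (1 - bio$gamma) * grazing + bio$mP * P + bio$mZ * Z - bio$rD * Dt
  dN <- -uptake + bio$rD * Dt
  list(dN = dN, dP = dP, dZ = dZ, dDt = dDt, uptake = uptake, grazing = grazing)
}

#' Convert phytoplankton nitrogen to chlorophyll-a
#'
#' Linear conversion from umol N/l to ug chl.a/l with a configurable yield.
#'
#' @param P Phytoplankton nitrogen, umol N/l (= mmol N/m^3).
#' @param chl_per_N Yield, ug chl.a per umol N.
#' @return Chlorophyll-a, ug/l.
#' @export
nitrogen_to_chla <- function(P, chl_per_N = 1.59) {
  if (any(P < 0)) stop("P must be >= 0", call. = FALSE)
  chl_per_N * P
}

# One forward-Euler biology step for every stack in the state, plus detritus
# sinking (bottom flux remineralised into N in the bottom cell).  Any clipping
# of sub-zero excursions is accumulated in the returned `clipped` total
# (mol N per unit width).
biology_step <- function(state, grid, bio, I_surface, dt) {
  clipped <- 0
  dtd <- dt / 86400
  nz <- grid$nz
  for (b in seq_along(state$bio)) {
    s <- state$bio[[b]]
    I <- light_profile(I_surface, s$P, grid, bio)
    td <- npzd_tendencies(s$N, s$P, s$Z, s$Dt, state$T, I, bio)
    s$N <- s$N + dtd * td$dN
    s$P <- s$P + dtd * td$dP
    s$Z <- s$Z + dtd * td$dZ
    s$Dt <- s$Dt + dtd * td$dDt
    for (nm in names(s)) {
      neg <- s[[nm]] < 0
      if (any(neg)) {
        clipped <- clipped + sum(-s[[nm]][neg] * grid$vol[neg])
        s[[nm]][neg] <- 0
      }
    }
    if (bio$wD > 0) {
      out <- settle_field(s$Dt, bio$wD, grid, dt)
      s$Dt <- out$field
      s$N[, nz] <- s$N[, nz] + out$bottom_flux / grid$dz[nz]
    }
    state$bio[[b]] <- s
  }
  state <- sync_bio(state)
  attr(state, "bio_clipped") <- clipped
  state
}
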