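#' Synthetic flood hydrograph
#'
#' Single-peak flood pulse on top of a constant base flow. The pulse is a
#' raised-cosine (Hann) bump, compactly supported, so the discharge is exactly
#' the base flow outside `[t_peak - rise, t_peak + fall]`, exactly `peak_Q` at
#' `t_peak`, and smooth throughout. The time-integrated flood volume above
#' base flow is `(peak_Q - base_Q) * (rise + fall) / 2` in closed form.
#'
#' @param base_Q Base discharge, m^3/s (default 62.46, an annual-mean flow).
#' @param peak_Q Peak discharge, m^3/s (> `base_Q`, or equal for a constant
#'   series).
#' @param t_peak Time of the peak, s.
#' @param rise,fall Half-widths of the rising and falling limbs, s (> 0).
#' @param duration Length of the run window covered by the series, s.
#' @return An `fp_hydrograph` object; evaluate it with [hydro_Q()] or
#'   materialise it with [hydrograph_series()].
#' @export
synthetic_flood_hydrograph <- function(base_Q = 62.46, peak_Q = 3000,
                                       t_peak = 36 * 3600,
                                       rise = 12 * 3600, fall = 24 * 3600,
                                       duration = 120 * 3600) {
  if (peak_Q < base_Q) stop("peak_Q must be >= base_Q", call. = FALSE)
  if (rise <= 0 || fall <= 0 || duration <= 0) {
    stop("rise, fall and duration must be positive", call. = FALSE)
  }
  if (t_peak < 0 || t_peak > duration) {
    stop("t_peak must lie inside the run window", call. = FALSE)
  }
  structure(list(base_Q = base_Q, peak_Q = peak_Q, t_peak = t_peak,
                 rise = rise, fall = fall, duration = duration),
            class = "fp_hydrograph")
}

#' Evaluate a hydrograph
#'
#' @param h An [synthetic_flood_hydrograph()] object.
#' @param t Times, s (vectorised).
#' @return Discharge, m^3/s.
#' @export
hydro_Q <- function(h, t) {
  tau <- t - h$t_peak
  shape <- ifelse(tau < 0,
                  ifelse(tau > -h$rise, cos(pi * tau / (2 * h$rise))^2, 0),
                  ifelse(tau < h$fall, cos(pi * tau / (2 * h$fall))^2, 0))
  h$base_Q + (h$peak_Q - h$base_Q) * shape
}

#' Materialise a hydrograph (and optionally river concentrations) as a tibble
#'
#' @param h An [synthetic_flood_hydrograph()].
#' @param dt Output spacing, s.
#' @param case Optional single-row case tibble (see [case_grid()]).
#' @param std Optional [fp_std_inputs()]; with `case`, adds riverine SSM and
#'   nutrient concentration columns.
#' @return A tibble with `time` (s), `Q` (m^3/s), and when `case`/`std` are
#'   given, `Criver` (kg/m^3) and `Nriver` (mol N/m^3).
#' @export
hydrograph_series <- function(h, dt = 3600, case = NULL, std = NULL) {
  times <- seq(0, h$duration, by = dt)
  out <- tibble::tibble(time = times, Q = hydro_Q(h, times))
  if (!is.null(case) && !is.null(std)) {
    conc <- riverine_concentrations(out$Q, case, std)
    out$Criver <- conc$Criver
    out$Nriver <- conc$Nriver
  }
  out
}

#' Standard-case riverine inputs
#'
#' The standard (STD) riverine nutrient concentration and the sediment rating
#' curve `C_STD(Q) = a Q^b` that the sensitivity multipliers scale. The rating
#' curve is parameterised by its value `c_ref` at a reference discharge
#' `Q_ref` (so `a = c_ref / Q_ref^b`). The defaults place the
#' hypopycnal-hyperpycnal density crossing of fresh sediment-laden river water
#' between 4 and 6 times the standard SSM load at peak discharge — the
#' qualitative structure of the regime diagram — and are a documented
#' calibration of the synthetic scenario, not observed values.
#'
#' @param N_std Standard riverine nutrient concentration, mol N/m^3
#'   (default 0.046).
#' @param c_ref Standard SSM concentration at `Q_ref`, kg/m^3.
#' @param Q_ref Reference discharge, m^3/s.
#' @param b Rating-curve exponent (dimensionless).
#' @return An `fp_std_inputs` object.
#' @export
fp_std_inputs <- function(N_std = 0.046, c_ref = 8.2, Q_ref = 3000, b = 1.2) {
  stopifnot(N_std >= 0, c_ref >= 0, Q_ref > 0)
  structure(list(N_std = N_std, c_ref = c_ref, Q_ref = Q_ref, b = b,
                 a = c_ref / Q_ref^b),
            class = "fp_std_inputs")
}

#' Riverine SSM and nutrient concentrations for a case
#'
#' `Criver = ssm_mult * a Q^b` from the standard rating curve and
#' `Nriver = N_std * nutrient_mult` (discharge-independent).
#'
#' @param Q Discharge, m^3/s (> 0). Vectorised.
#' @param case A single-row case tibble with `ssm_mult` and `nutrient_mult`.
#' @param std An [fp_std_inputs()].
#' @return List with `Criver` (kg/m^3) and `Nriver` (mol N/m^3).
#' @export
riverine_concentrations <- function(Q, case, std) {
  stopifnot(all(Q > 0))
  list(Criver = case$ssm_mult * std$a * Q^std$b,
       Nriver = rep(std$N_std * case$nutrient_mult, length(Q)))
}

#' Initial stratified ocean profiles
#'
#' Builds the pre-flood water column the scenario assumes: a warm, relatively
#' fresh surface mixed layer over colder, saltier deep water (tanh pycnocline),
#' a nutrient-depleted surface above a nutrient-rich sub-surface (tanh
#' nutricline), and a sub-surface chlorophyll maximum (Gaussian bump in
#' phytoplankton). The requested column must be statically stable.
#'
#' @param grid An [fp_grid()].
#' @param phys An [fp_phys()]; defaults give the surface water the reference
#'   temperature and salinity.
#' @param T_surf,dT Surface temperature (degC) and top-to-bottom decrease.
#' @param S_surf,dS Surface salinity (psu) and halocline strength (bottom
#'   minus surface; 0 gives a uniform column).
#' @param z_pyc,w_pyc Pycnocline centre depth and width, m.
#' @param N_surf,N_deep Surface and deep nitrate, mol N/m^3.
#' @param z_nut,w_nut Nutricline centre depth and width, m.
#' @param P_surf,P_max Surface and sub-surface-maximum phytoplankton,
#'   mol N/m^3.
#' @param z_scm,w_scm Sub-surface chlorophyll maximum depth and width, m.
#' @param Z_frac Zooplankton as a fraction of local phytoplankton.
#' @param Dt0 Uniform detritus, mol N/m^3.
#' @return An `fp_initial_ocean`: a tibble with `z` (centre depth, m) and
#'   columns `T`, `S`, `N`, `P`, `Z`, `Dt`, plus a `rho` column.
#' @export
build_initial_ocean <- function(grid, phys = fp_phys(),
                                T_surf = 26, dT = 9,
                                S_surf = 32.8, dS = 1.4,
                                z_pyc = 6, w_pyc = 2.5,
                                N_surf = 2e-4, N_deep = 3e-3,
                                z_nut = 8, w_nut = 2.5,
                                P_surf = 1e-4, P_max = 3e-3,
                                z_scm = 8, w_scm = 3,
                                Z_frac = 0.2, Dt0 = 1e-4) {
  z <- grid$zc
  ramp <- function(zc, w) 0.5 * (1 + tanh((z - zc) / w))
  Tp <- T_surf - dT * ramp(z_pyc, w_pyc)
  Sp <- S_surf + dS * ramp(z_pyc, w_pyc)
  Np <- N_surf + (N_deep - N_surf) * ramp(z_nut, w_nut)
  Pp <- P_surf + (P_max - P_surf) * exp(-((z - z_scm) / w_scm)^2)
  Zp <- Z_frac * Pp
  Dp <- rep(Dt0, grid$nz)
  rho <- equation_of_state(Tp, Sp, 0, phys)
  if (any(diff(rho) < -1e-9)) {
    stop("requested initial profile is statically unstable", call. = FALSE)
  }
  structure(tibble::tibble(z = z, T = Tp, S = Sp, N = Np, P = Pp,
                           Z = Zp, Dt = Dp, rho = rho),
            class = c("fp_initial_ocean", class(tibble::tibble())))
}

#' Sensitivity-case grid
#'
#' Cartesian product of SSM multipliers, particle diameters and nutrient
#' multipliers, plus one reference case without SSM (WOS) per distinct
#' nutrient multiplier (the reference varies only with nutrient input).
#' Duplicate multiplier values are deduplicated.
#'
#' @param ssm_mults SSM input multipliers, each in \[0, 10\]. A 0 entry is
#'   folded into the WOS references.
#' @param diameters Particle diameters, m.
#' @param nutrient_mults Riverine nutrient multipliers, each in \[0, 10\].
#' @return An `fp_case_grid` tibble with columns `label`, `ssm_mult`,
#'   `diameter` (NA for WOS), `nutrient_mult`.
#' @examples
#' nrow(case_grid(1:6 * 1.0, c(1, 2, 3, 4, 5) * 1e-5, c(0, 0.1, 1, 5, 10))) # 155
#' @export
case_grid <- function(ssm_mults, diameters, nutrient_mults = 1) {
  if (any(ssm_mults < 0 | ssm_mults > 10) ||
      any(nutrient_mults < 0 | nutrient_mults > 10)) {
    stop("multipliers must lie in [0, 10]", call. = FALSE)
  }
  if (any(diameters <= 0)) stop("diameters must be positive", call. = FALSE)
  sm <- sort(unique(ssm_mults[ssm_mults > 0]))
  dm <- sort(unique(diameters))
  nm <- sort(unique(nutrient_mults))
  wos <- tibble::tibble(label = paste0("WOS_n", nm), ssm_mult = 0,
                        diameter = NA_real_, nutrient_mult = nm)
  if (length(sm) && length(dm)) {
    cases <- tidyr::expand_grid(ssm_mult = sm, diameter = dm, nutrient_mult = nm)
    cases <- dplyr::mutate(
      cases,
      label = sprintf("ssm%g_d%gmm_n%g", .data$ssm_mult, .data$diameter * 1e3,
                      .data$nutrient_mult),
      .before = 1)
  } else {
    cases <- NULL
  }
  out <- dplyr::bind_rows(wos, cases)
  class(out) <- c("fp_case_grid", class(out))
  out
}

#' Typical-case presets
#'
#' The two marked cells of the regime diagram: the typical hypopycnal case
#' (SSM 4x the standard, diameter 0.05 mm, nutrient 1x) and the typical
#' hyperpycnal case (SSM 10x, diameter 0.01 mm, nutrient 1x).
#'
#' @return A single-row case tibble.
#' @export
hypopycnal_case <- function() {
  tibble::tibble(label = "hypopycnal", ssm_mult = 4, diameter = 0.05e-3,
                 nutrient_mult = 1)
}

#' @rdname hypopycnal_case
#' @export
hyperpycnal_case <- function() {
  tibble::tibble(label = "hyperpycnal", ssm_mult = 10, diameter = 0.01e-3,
                 nutrient_mult = 1)
}

#' Materialise scenario fixtures as CSV files
#'
#' Writes the configured flood hydrograph (with riverine SSM and nutrient
#' concentrations for a case) and the initial ocean profiles to plain CSV for
#' inspection. Deterministic: identical configurations produce byte-identical
#' files.
#'
#' @param config An [fp_config()].
#' @param dir Output directory (created if needed).
#' @param case Single-row case tibble; defaults to the standard case
#'   (SSM 1x, 0.05 mm, nutrient 1x).
#' @return Invisibly, the paths written.
#' @export
write_fixtures <- function(config, dir, case = NULL) {
  if (is.null(case)) {
    case <- tibble::tibble(label = "STD", ssm_mult = 1, diameter = 0.05e-3,
                           nutrient_mult = 1)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r <- config$river
  h <- synthetic_flood_hydrograph(r$base_Q, r$peak_Q, r$t_peak, r$rise,
                                  r$fall, config$output$duration)
  std <- do.call(fp_std_inputs, config$std)
  hydro_path <- file.path(dir, "hydrograph.csv")
  utils::write.csv(hydrograph_series(h, config$output$cadence, case, std),
                   hydro_path, row.names = FALSE)
  grid <- fp_grid(config$grid$nx, config$grid$nz, config$grid$dx,
                  config$grid$dz)
  phys <- do.call(fp_phys, config$physics)
  init <- do.call(build_initial_ocean,
                  c(list(grid = grid, phys = phys), config$initial))
  init_path <- file.path(dir, "initial_ocean.csv")
  utils::write.csv(as.data.frame(init), init_path, row.names = FALSE)
  invisible(c(hydro_path, init_path))
}
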