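#' Run configuration
#'
#' Builds the nested configuration that defines a scenario: grid, physics,
#' river forcing, standard riverine inputs, initial stratification, biology,
#' sponge layer, diagnostics, output cadence and numerics. Every section has
#' complete defaults (the desk-scale study configuration); supply named lists
#' to override individual entries. Unknown keys are rejected.
#'
#' @param ... Named sections (`grid`, `physics`, `river`, `std`, `initial`,
#'   `bio`, `light`, `sponge`, `diagnostics`, `output`, `numerics`, `seed`)
#'   whose entries override the defaults.
#' @return An `fp_config` nested list.
#' @examples
#' cfg <- fp_config(river = list(peak_Q = 2000), seed = 7)
#' cfg$river$peak_Q
#' @export
fp_config <- function(...) {
  defaults <- list(
    grid = list(nx = 60, nz = 12, dx = 250,
                dz = c(1, 1, 1, 1.5, 1.5, 2, 2, 2, 2, 2, 2, 2)),
    physics = list(rho0 = 1023.0, alpha = 2.5e-4, beta = 7.6e-4,
                   T0 = 26.0, S0 = 32.8, rho_sed = 2650, nu = 1.0e-6,
                   g = 9.81, Ah = 5.0, Av = 1.0e-4, Kh = 5.0, Kv = 5.0e-5,
                   Kv_shear = 5.0e-4, convect_mix = 0.3, f = 0),
    river = list(base_Q = 62.46, peak_Q = 3000, t_peak = 36 * 3600,
                 rise = 12 * 3600, fall = 24 * 3600, width = 18000,
                 n_layers = 2L, T_river = 20, S_river = 0,
                 mouth_mix = 0.02, mouth_cols = 2L),
    std = list(N_std = 0.046, c_ref = 8.2, Q_ref = 3000, b = 1.2),
    initial = list(T_surf = 26, dT = 9, S_surf = 32.8, dS = 1.4,
                   z_pyc = 6, w_pyc = 2.5, N_surf = 2e-4, N_deep = 3e-3,
                   z_nut = 8, w_nut = 2.5, P_surf = 1e-4, P_max = 3e-3,
                   z_scm = 8, w_scm = 3, Z_frac = 0.2, Dt0 = 1e-4),
    bio = list(Vmax = 0.4, Ks = 1.0e-3, Iopt = 65, kT = 0.0693, kw = 0.15,
               kp = 30, Rmax = 0.3, lambda_ivlev = 1400, P0 = 2e-4,
               mP = 0.05, mZ = 0.08, gamma = 0.7, rD = 0.05, wD = 1.0e-4,
               chl_per_N = 1.59, enabled = TRUE),
    light = list(I_mean = 150, diurnal = FALSE),
    sponge = list(n = 6L, tau = 3600),
    diagnostics = list(salinity_threshold = 28.0, surface_layers = 2L,
                       mask_source = "reference", neutral_tol = 0.01),
    output = list(cadence = 3600, duration = 120 * 3600),
    numerics = list(safety = 0.4, dt_max = 120, spinup_days = 2),
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  for (sec in names(over)) {
    if (sec == "seed") { defaults$seed <- over$seed; next }
    badk <- setdiff(names(over[[sec]]), names(defaults[[sec]]))
    if (length(badk)) {
      stop(sprintf("unknown key(s) in config$%s: %s", sec,
                   paste(badk, collapse = ", ")), call. = FALSE)
    }
    defaults[[sec]][names(over[[sec]])] <- over[[sec]]
  }
  structure(defaults, class = "fp_config")
}

#' Read / write a configuration file
#'
#' Configurations are stored as YAML with the same nested sections as
#' [fp_config()]; reading validates against the schema (unknown keys are
#' rejected).
#'
#' @param path File path.
#' @return For `read_run_config()`, an `fp_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  do.call(fp_config, raw)
}

#' @rdname read_run_config
#' @param config An `fp_config` to write.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Stable hash of a configuration (and optionally a case)
#'
#' Deterministic content hash used by the run manifest: identical
#' configurations give identical hashes.
#'
#' @param config An `fp_config`.
#' @param case Optional single-row case tibble.
#' @return A hex string.
#' @export
config_hash <- function(config, case = NULL) {
  txt <- paste(utils::capture.output(utils::str(
    list(config = unclass(config),
         case = if (!is.null(case)) as.list(case)), digits.d = 15)),
    collapse = "\n")
  # polynomial rolling hash over the serialised text; no external digest dep
  bytes <- utf8ToInt(txt)
  h1 <- 0; h2 <- 0
  for (b in bytes) {
    h1 <- (h1 * 31 + b) %% 2147483647
    h2 <- (h2 * 131 + b) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}

#' Assemble a runnable model from a configuration and a case
#'
#' Precomputes everything a time step needs: the grid, physical parameters,
#' the factored pressure operator, the sediment class, biological parameters,
#' the flood hydrograph, ambient profiles (buoyancy reference, offshore
#' boundary and sponge target), and the sponge profile.
#'
#' @param config An [fp_config()].
#' @param case Single-row case tibble (see [case_grid()]); default WOS.
#' @param nutrient_mults Vector of riverine nutrient multipliers carried as
#'   independent biological stacks in one physical integration (the physics
#'   does not depend on the nutrient fields). Defaults to the case's own
#'   multiplier.
#' @param open_right Open offshore boundary (default) or closed basin.
#' @return An `fp_model` list.
#' @export
fp_model <- function(config, case = NULL, nutrient_mults = NULL,
                     open_right = TRUE) {
  if (is.null(case)) {
    case <- tibble::tibble(label = "WOS", ssm_mult = 0, diameter = NA_real_,
                           nutrient_mult = 1)
  }
  if (is.null(nutrient_mults)) nutrient_mults <- case$nutrient_mult
  g <- config$grid
  grid <- fp_grid(g$nx, g$nz, g$dx, g$dz)
  phys <- do.call(fp_phys, config$physics)
  bio <- do.call(fp_bio, config$bio[setdiff(names(config$bio), "enabled")])
  std <- do.call(fp_std_inputs, config$std)
  r <- config$river
  hydro <- synthetic_flood_hydrograph(r$base_Q, r$peak_Q, r$t_peak, r$rise,
                                      r$fall, duration = 1e12)
  init <- do.call(build_initial_ocean,
                  c(list(grid = grid, phys = phys), config$initial))
  sed <- if (case$ssm_mult > 0 && is.finite(case$diameter)) {
    fp_sediment(case$diameter, phys$rho_sed, phys)
  } else NULL
  nsp <- config$sponge$n
  gamma <- numeric(grid$nx)
  if (nsp > 0) {
    i <- seq_len(nsp)
    gamma[grid$nx - nsp + i] <- (i / nsp)^2 / config$sponge$tau
  }
  rl <- seq_len(r$n_layers)
  amb <- list(T = init$T, S = init$S, C = rep(0, grid$nz),
              N = init$N, P = init$P, Z = init$Z, Dt = init$Dt)
  amb_mat <- lapply(amb, function(p) matrix(p, grid$nx, grid$nz, byrow = TRUE))
  # explicit-diffusion cap; the mouth-mixing part follows the hydrograph
  dzmin <- min(grid$dz) * min(grid$dzf[2:grid$nz])
  h_rate <- 2 * max(phys$Kh, phys$Ah) / grid$dx^2
  kv_fixed <- max(phys$Kv + (phys$Kv_shear %||% 0), phys$Av)
  mouth_coef <- (r$mouth_mix %||% 0) / r$width
  dt_cap <- function(t) {
    kvm <- mouth_coef * hydro_Q(hydro, t)
    0.45 / (h_rate + 2 * (kv_fixed + kvm) / dzmin)
  }
  structure(
    list(config = config, case = case, nutrient_mults = nutrient_mults,
         grid = grid, phys = phys, bio = bio, std = std, hydro = hydro,
         init = init, sed = sed, ps = fp_poisson(grid, open_right),
         open_right = open_right, gamma = gamma, river_layers = rl,
         river_area = sum(grid$dz[rl]) * r$width, dt_cap = dt_cap,
         rho_ambient = init$rho, ambient = amb, ambient_mat = amb_mat),
    class = "fp_model")
}

#' Initial model state from the configured profiles
#'
#' @param model An [fp_model()].
#' @return An `fp_state` with one biological stack per nutrient multiplier.
#' @export
initial_state <- function(model) {
  init <- model$init
  fp_state(model$grid, T = init$T, S = init$S, C = 0,
           N = init$N, P = init$P, Z = init$Z, Dt = init$Dt,
           n_bio = length(model$nutrient_mults))
}
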