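#' Largest stable time step for the current state
#'
#' Minimum over three closed-form bounds, times a safety factor: the advective
#' CFL limit (per-cell sum of horizontal and vertical Courant rates, with the
#' settling speed added to the vertical), the explicit diffusive/viscous
#' stability limit, and the internal-gravity-wave limit `dx / c` with
#' `c = sqrt(g * max(drho)/rho0 * H)` from the density range of the state.
#'
#' @param state An `fp_state`.
#' @param phys An [fp_phys()].
#' @param grid An [fp_grid()].
#' @param ws Additional vertical (settling) speed to include in the CFL, m/s.
#' @param safety Multiplier in (0, 1].
#' @return Time step, s.
#' @export
stable_dt <- function(state, phys, grid, ws = 0, safety = 1) {
  nx <- grid$nx; nz <- grid$nz
  umax <- pmax(abs(state$u[-1, , drop = FALSE]),
               abs(state$u[-(nx + 1L), , drop = FALSE]))
  wmax <- pmax(abs(state$w[, -1, drop = FALSE]),
               abs(state$w[, -(nz + 1L), drop = FALSE])) + ws
  adv_rate <- max(umax / grid$dx + wmax * grid$i_dz)
  dt_adv <- if (adv_rate > 0) 1 / adv_rate else Inf
  Kx <- max(phys$Kh, phys$Ah)
  Kz <- max(phys$Kv + (phys$Kv_shear %||% 0), phys$Av)
  dif_rate <- 2 * Kx / grid$dx^2 + 2 * Kz / (min(grid$dz) * min(grid$dzf[2:nz]))
  dt_dif <- if (dif_rate > 0) 1 / dif_rate else Inf
  rho <- equation_of_state(state$T, state$S, state$C, phys)
  # horizontal internal-wave CFL; the vertical buoyancy oscillation itself is
  # handled implicitly inside momentum_step and does not constrain dt
  drho <- max(rho) - min(rho)
  c_iw <- sqrt(phys$g * max(drho, 1e-12) / phys$rho0 * sum(grid$dz))
  dt_wave <- grid$dx / c_iw
  safety * min(dt_adv, dt_dif, dt_wave)
}

# river forcing at time t: left-face velocity profile and per-tracer inflow
# concentrations (one N per biological stack)
river_forcing <- function(model, t) {
  r <- model$config$river
  Q <- hydro_Q(model$hydro, t)
  u_left <- numeric(model$grid$nz)
  u_left[model$river_layers] <- Q / model$river_area
  conc <- riverine_concentrations(Q, model$case, model$std)
  list(Q = Q, u_left = u_left,
       Criver = conc$Criver,
       Nriver = model$std$N_std * model$nutrient_mults,
       T_river = r$T_river, S_river = r$S_river)
}

# surface PAR irradiance at time t, W/m^2
surface_irradiance <- function(model, t) {
  l <- model$config$light
  if (isTRUE(l$diurnal)) {
    max(0, l$I_mean * (pi / 2) * sin(pi * ((t / 86400) %% 1)))
  } else {
    l$I_mean
  }
}

# boundary-condition profile for one tracer: river value in the river layers,
# ambient below (only the river layers can carry inflow at the left face)
left_profile <- function(model, river_value, ambient_profile) {
  p <- ambient_profile
  p[model$river_layers] <- river_value
  p
}

#' Shear-dependent vertical tracer diffusivity
#'
#' Richardson-number mixing closure in the Pacanowski-Philander form: on every
#' interior z-face, `Kv = Kv_bg + Kv_shear / (1 + 5 Ri)^2` with
#' `Ri = N^2 / S^2` from the local stratification and vertical shear of the
#' horizontal velocity. Strong shear at the plume base (vigorous estuarine
#' exchange) mixes tracers at up to `Kv_bg + Kv_shear`; a calm, stratified
#' column mixes at the background rate. This is how a weakened exchange
#' circulation reduces the salt supply into the plume.
#'
#' @param state An `fp_state`.
#' @param phys An [fp_phys()]; uses `Kv` (background) and `Kv_shear`.
#' @param grid An [fp_grid()].
#' @return `nx` x `(nz-1)` matrix of face diffusivities, m^2/s.
#' @export
shear_diffusivity <- function(state, phys, grid) {
  if (is.null(phys$Kv_shear) || phys$Kv_shear <= 0) return(phys$Kv)
  nx <- grid$nx; nz <- grid$nz
  rho <- equation_of_state(state$T, state$S, state$C, phys)
  N2 <- pmax(0, -phys$g / phys$rho0 *
               (rho[, 1:(nz - 1L), drop = FALSE] - rho[, 2:nz, drop = FALSE]) *
               grid$i_dzf)
  uc <- 0.5 * (state$u[1:nx, , drop = FALSE] + state$u[2:(nx + 1L), , drop = FALSE])
  sh <- (uc[, 1:(nz - 1L), drop = FALSE] - uc[, 2:nz, drop = FALSE]) * grid$i_dzf
  S2 <- sh * sh + 1e-12
  Ri <- N2 / S2
  phys$Kv + phys$Kv_shear / (1 + 5 * Ri)^2
}

#' Advance the coupled model by one time step
#'
#' One full step of the coupled system: momentum + projection, limited-upwind
#' advection and explicit diffusion of all tracers (with riverine inflow at
#' the river-end face and ambient inflow at the offshore face), SSM settling
#' with terminal deposition, NPZD biology with detritus sinking, sponge
#' relaxation toward the ambient profiles, and convective adjustment. With all
#' forcing off (closed configuration) total salt and total nitrogen are
#' conserved to round-off.
#'
#' @param state An `fp_state`.
#' @param model An [fp_model()].
#' @param dt Time step, s (use [stable_dt()]).
#' @param ledger An [fp_ledger()] or `NULL`.
#' @return List with `state`, `ledger`, and `fluxes`: per-tracer boundary /
#'   sponge exchanges over the step (positive into the domain), the
#'   post-projection `max_div`, and clipping totals.
#' @export
step <- function(state, model, dt, ledger = NULL) {
  grid <- model$grid; phys <- model$phys
  frc <- river_forcing(model, state$t)
  state <- momentum_step(state, phys, grid, dt, model$ps,
                         rho_ambient = model$rho_ambient,
                         u_left = frc$u_left)
  max_div <- attr(state, "max_div")

  amb <- model$ambient
  fluxes <- list()
  Kv_face <- shear_diffusivity(state, phys, grid)
  # unresolved near-field (lift-off jet) entrainment at the river mouth:
  # extra vertical mixing in the first columns, scaling with the inflow speed
  r <- model$config$river
  if (r$mouth_mix > 0) {
    kvm <- r$mouth_mix * max(frc$u_left) * sum(grid$dz[model$river_layers])
    if (kvm > 0) {
      if (!is.matrix(Kv_face)) {
        Kv_face <- matrix(Kv_face, grid$nx, grid$nz - 1L)
      }
      mc <- seq_len(min(r$mouth_cols, grid$nx))
      Kv_face[mc, ] <- Kv_face[mc, , drop = FALSE] + kvm
    }
  }
  prep <- advect_prepare(state$u, state$w, grid, dt,
                         Kh = phys$Kh, Kv = Kv_face)
  adv_one <- function(fld, left, right) {
    advect_apply(fld, prep, grid, left, right)
  }
  # physical tracers
  phys_bc <- list(
    T = list(left = left_profile(model, frc$T_river, amb$T), right = amb$T),
    S = list(left = left_profile(model, frc$S_river, amb$S), right = amb$S),
    C = list(left = left_profile(model, frc$Criver, amb$C), right = amb$C))
  for (nm in names(phys_bc)) {
    out <- adv_one(state[[nm]], phys_bc[[nm]]$left, phys_bc[[nm]]$right)
    state[[nm]] <- out$field
    fluxes[[nm]] <- c(inflow = out$in_left, outflow = out$out_right, sponge = 0)
  }
  # biological stacks
  for (b in seq_along(state$bio)) {
    bcs <- list(N = left_profile(model, frc$Nriver[b], amb$N),
                P = left_profile(model, 0, amb$P),
                Z = left_profile(model, 0, amb$Z),
                Dt = left_profile(model, 0, amb$Dt))
    nin <- 0; nout <- 0
    for (nm in names(bcs)) {
      out <- adv_one(state$bio[[b]][[nm]], bcs[[nm]], amb[[nm]])
      state$bio[[b]][[nm]] <- out$field
      nin <- nin + out$in_left; nout <- nout + out$out_right
    }
    fluxes[[paste0("nitrogen", b)]] <- c(inflow = nin, outflow = nout, sponge = 0)
  }

  # settling and terminal deposition of SSM
  if (!is.null(model$sed)) {
    if (is.null(ledger)) ledger <- fp_ledger(grid)
    st <- apply_settling(state, model$sed, grid, dt, ledger)
    state <- st$state; ledger <- st$ledger
    ledger$input <- ledger$input + fluxes$C[["inflow"]]
    ledger$outflow <- ledger$outflow + fluxes$C[["outflow"]]
  }

  # positivity cleanup (limiter round-off), logged
  clip_tot <- 0
  clip_field <- function(fld) {
    neg <- fld < 0
    if (any(neg)) {
      clip_tot <<- clip_tot + sum(-fld[neg] * grid$vol[neg])
      fld[neg] <- 0
    }
    fld
  }
  state$S <- clip_field(state$S); state$C <- clip_field(state$C)
  for (b in seq_along(state$bio)) {
    state$bio[[b]] <- lapply(state$bio[[b]], clip_field)
  }
  state <- sync_bio(state)

  # biology
  clip_bio <- 0
  if (isTRUE(model$config$bio$enabled)) {
    state <- biology_step(state, grid, model$bio, surface_irradiance(model, state$t), dt)
    clip_bio <- attr(state, "bio_clipped")
  }

  # sponge relaxation toward ambient (accounted as boundary exchange)
  if (any(model$gamma > 0)) {
    gdt <- model$gamma * dt                    # per-column relaxation fraction
    act <- gdt > 0
    relax <- function(fld, prof_mat, key) {
      dfld <- (prof_mat - fld) * gdt
      fluxes[[key]]["sponge"] <<- fluxes[[key]]["sponge"] + sum(dfld * grid$vol)
      fld + dfld
    }
    am <- model$ambient_mat
    state$T <- relax(state$T, am$T, "T")
    state$S <- relax(state$S, am$S, "S")
    csp <- sum(-state$C * gdt * grid$vol)
    state$C <- state$C * (1 - gdt)             # ambient C = 0
    fluxes$C["sponge"] <- fluxes$C["sponge"] + csp
    if (!is.null(ledger)) ledger$sponge <- ledger$sponge - csp
    for (b in seq_along(state$bio)) {
      key <- paste0("nitrogen", b)
      for (nm in c("N", "P", "Z", "Dt")) {
        state$bio[[b]][[nm]] <- relax(state$bio[[b]][[nm]], am[[nm]], key)
      }
    }
    state$w[act, ] <- state$w[act, , drop = FALSE] * (1 - gdt[act])
  }

  state <- convective_adjust(state, phys, grid,
                             mix_frac = phys$convect_mix %||% 1)
  state <- sync_bio(state)
  state$t <- state$t + dt
  list(state = state, ledger = ledger,
       fluxes = fluxes, max_div = max_div,
       clipped = clip_tot, bio_clipped = clip_bio)
}

#' Integrate the model over a time window
#'
#' Adaptive explicit time stepping with [stable_dt()], landing exactly on the
#' requested output times; records compact surface diagnostics (the top
#' `surface_layers` of S and of every stack's N and P) at each output, audits
#' tracer budgets step by step, and returns the final state, the deposition
#' ledger and the budget report.
#'
#' @param model An [fp_model()].
#' @param state Starting `fp_state` (default [initial_state()]).
#' @param t_end End time, s (default the configured run duration).
#' @param out_dt Output cadence, s (default from the configuration).
#' @param progress Unused hook for callers; kept for API stability.
#' @return An `fp_run` object.
#' @export
simulate_run <- function(model, state = NULL, t_end = NULL, out_dt = NULL,
                         progress = FALSE) {
  if (is.null(state)) state <- initial_state(model)
  if (is.null(t_end)) t_end <- model$config$output$duration
  if (is.null(out_dt)) out_dt <- model$config$output$cadence
  grid <- model$grid; num <- model$config$numerics
  L <- model$config$diagnostics$surface_layers
  ledger <- fp_ledger(grid)
  out_times <- seq(state$t, t_end, by = out_dt)
  nb <- length(state$bio)
  rec <- list()
  budget <- new.env()
  budget$acc <- NULL
  inv0 <- inventory_multi(state, grid)
  add_fluxes <- function(fx) {
    v <- unlist(fx)
    if (is.null(budget$acc)) budget$acc <- v else budget$acc <- budget$acc + v
  }
  record <- function(state) {
    list(t = state$t,
         S = state$S[, seq_len(L), drop = FALSE],
         bio = lapply(state$bio, function(s) {
           list(N = s$N[, seq_len(L), drop = FALSE],
                P = s$P[, seq_len(L), drop = FALSE])
         }))
  }
  rec[[1]] <- record(state)
  max_div_seen <- 0; clip_seen <- 0; n_steps <- 0L
  ws <- if (!is.null(model$sed)) 0 else 0  # settling sub-steps internally
  dt_cache <- -1; dt_age <- 0L
  for (j in seq_along(out_times)[-1]) {
    t_next <- out_times[j]
    while (state$t < t_next - 1e-6) {
      # the stability bound evolves slowly; refresh it every few steps
      if (dt_cache < 0 || dt_age >= 4L) {
        dt_cache <- stable_dt(state, model$phys, grid, ws = ws,
                              safety = num$safety)
        dt_age <- 0L
      }
      dt_age <- dt_age + 1L
      cap <- if (is.function(model$dt_cap)) model$dt_cap(state$t) else Inf
      dt <- min(num$dt_max, cap, dt_cache, t_next - state$t)
      sp <- step(state, model, dt, ledger)
      state <- sp$state; ledger <- sp$ledger
      add_fluxes(sp$fluxes)
      max_div_seen <- max(max_div_seen, sp$max_div)
      clip_seen <- clip_seen + sp$clipped
      n_steps <- n_steps + 1L
    }
    rec[[j]] <- record(state)
  }
  inv1 <- inventory_multi(state, grid)
  structure(
    list(case = model$case, nutrient_mults = model$nutrient_mults,
         config = model$config, grid = grid,
         times = out_times, surface = rec,
         final_state = state, ledger = ledger,
         budget = budget_report(inv0, inv1, budget$acc, ledger, grid$dx),
         max_div = max_div_seen, clipped = clip_seen, n_steps = n_steps,
         hash = config_hash(model$config, model$case)),
    class = "fp_run")
}

# inventories including every biological stack
inventory_multi <- function(state, grid) {
  vol <- grid$vol
  v <- c(T = sum(state$T * vol), S = sum(state$S * vol), C = sum(state$C * vol))
  for (b in seq_along(state$bio)) {
    s <- state$bio[[b]]
    v[paste0("nitrogen", b)] <- sum((s$N + s$P + s$Z + s$Dt) * vol)
  }
  v
}

# closure audit: change in inventory vs integrated boundary/sponge/deposit
# fluxes, per tracer, with a relative residual
budget_report <- function(inv0, inv1, acc, ledger, dx) {
  keys <- names(inv0)
  rows <- lapply(keys, function(k) {
    infl <- acc[paste0(k, ".inflow")]
    outf <- acc[paste0(k, ".outflow")]
    spg <- acc[paste0(k, ".sponge")]
    dep <- if (k == "C") ledger_total(ledger, dx) else 0
    expected <- infl - outf + spg - dep
    resid <- (inv1[k] - inv0[k]) - expected
    scale <- max(abs(inv0[k]), abs(infl), abs(outf), 1e-300)
    tibble::tibble(tracer = k, initial = inv0[[k]], final = inv1[[k]],
                   inflow = unname(infl), outflow = unname(outf),
                   sponge = unname(spg), deposit = dep,
                   residual = unname(resid), rel_residual = unname(resid / scale))
  })
  dplyr::bind_rows(rows)
}

ledger_total <- function(ledger, dx) sum(ledger$deposit) * dx

#' @export
print.fp_run <- function(x, ...) {
  cat(sprintf("<fp_run> case %s: %d outputs over %.1f h, max|div| = %.2e 1/s\n",
              x$case$label, length(x$times), diff(range(x$times)) / 3600,
              x$max_div))
  invisible(x)
}
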