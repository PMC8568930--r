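#' Convective adjustment of statically unstable columns
#'
#' Stand-in for vertical motion the grid cannot resolve: wherever a cell is
#' denser than the cell below it (density from [equation_of_state()], so
#' suspended sediment participates — this is how sediment-loaded surface
#' water drives homopycnal/hyperpycnal overturning), the pair is restratified
#' conservatively and the column re-checked until statically stable.
#'
#' `mix_frac` interpolates between two limits of an overturning event.
#' `mix_frac = 1` homogenises the pair (classical convective adjustment: both
#' cells take the thickness-weighted average of every tracer). `mix_frac = 0`
#' swaps the parcels instead: the dense upper parcel sinks intact and an
#' equal volume of lower water rises, which is how a non-hydrostatic model
#' renders plunging river water that reaches its level of neutral buoyancy
#' without mixing. The coupled model uses a displacement-dominant default
#' (see `fp_config()$physics$convect_mix`); the pure-mixing default here
#' keeps the operation's standalone behaviour classical.
#'
#' Column integrals of all tracers are unchanged to round-off for any
#' `mix_frac`. Only the columns containing an instability are touched;
#' interfaces are processed in alternating odd/even passes so simultaneously
#' processed pairs are disjoint.
#'
#' @param state An `fp_state`.
#' @param phys An [fp_phys()].
#' @param grid An [fp_grid()].
#' @param tol Density tolerance, kg/m^3: interfaces are adjusted when the
#'   upper cell exceeds the lower by more than `tol`.
#' @param mix_frac Fraction of pair homogenisation per overturning event,
#'   in \[0, 1\]; the remainder is parcel swapping.
#' @return The adjusted state.
#' @export
convective_adjust <- function(state, phys, grid, tol = 1e-10, mix_frac = 1) {
  nz <- grid$nz; dz <- grid$dz
  rho <- equation_of_state(state$T, state$S, state$C, phys)
  d <- rho[, 1:(nz - 1L), drop = FALSE] - rho[, 2:nz, drop = FALSE]
  bad <- rowSums(d > tol) > 0
  if (!any(bad)) return(state)
  idx <- which(bad)
  nb <- length(idx)
  nm_phys <- c("T", "S", "C")
  sub <- lapply(nm_phys, function(nm) state[[nm]][idx, , drop = FALSE])
  names(sub) <- nm_phys
  sub_bio <- lapply(state$bio, function(s) {
    lapply(s, function(f) f[idx, , drop = FALSE])
  })
  ks_set <- list(seq(1L, nz - 1L, 2L), seq(2L, nz - 1L, 2L))
  # per-interface coefficients for the swap and mix end states:
  # upper (thickness a) over lower (thickness b)
  coef <- lapply(ks_set, function(ks) {
    a <- dz[ks]; b <- dz[ks + 1L]
    wmix <- a / (a + b)                       # homogenised value weight on upper
    # swapped state: see vignette; the thinner of the two parcels transfers whole
    up_keep <- pmax(0, (a - b) / a)           # fraction of upper staying up (a > b)
    lo_keep <- pmax(0, (b - a) / b)           # fraction of lower staying down (b > a)
    list(ks = ks,
         wmix = matrix(wmix, nb, length(ks), byrow = TRUE),
         up_keep = matrix(up_keep, nb, length(ks), byrow = TRUE),
         lo_keep = matrix(lo_keep, nb, length(ks), byrow = TRUE))
  })
  # alternating pairwise restratification converges geometrically
  for (sweep_i in seq_len(120L * nz)) {
    rho_s <- equation_of_state(sub$T, sub$S, sub$C, phys)
    ds <- rho_s[, 1:(nz - 1L), drop = FALSE] - rho_s[, 2:nz, drop = FALSE]
    if (max(ds) <= tol) break
    cf <- coef[[if (sweep_i %% 2L == 1L) 1L else 2L]]
    ks <- cf$ks
    U <- ds[, ks, drop = FALSE] > tol
    if (!any(U)) next
    adjust_pair <- function(fld) {
      Xk <- fld[, ks, drop = FALSE]
      Xk1 <- fld[, ks + 1L, drop = FALSE]
      M <- cf$wmix * Xk + (1 - cf$wmix) * Xk1
      up_swap <- cf$up_keep * Xk + (1 - cf$up_keep) * Xk1
      lo_swap <- cf$lo_keep * Xk1 + (1 - cf$lo_keep) * Xk
      up_new <- mix_frac * M + (1 - mix_frac) * up_swap
      lo_new <- mix_frac * M + (1 - mix_frac) * lo_swap
      fld[, ks] <- Xk + U * (up_new - Xk)
      fld[, ks + 1L] <- Xk1 + U * (lo_new - Xk1)
      fld
    }
    sub <- lapply(sub, adjust_pair)
    sub_bio <- lapply(sub_bio, function(s) lapply(s, adjust_pair))
  }
  for (nm in nm_phys) state[[nm]][idx, ] <- sub[[nm]]
  for (b in seq_along(state$bio)) {
    for (nm in names(state$bio[[b]])) {
      state$bio[[b]][[nm]][idx, ] <- sub_bio[[b]][[nm]]
    }
  }
  sync_bio(state)
}
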