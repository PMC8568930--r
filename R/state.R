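#' Model state on the staggered grid
#'
#' Holds one model time level: velocities on faces, tracers at cell centres.
#' Tracer matrices are `nx` x `nz` with column 1 the surface layer; `u` is
#' `(nx+1)` x `nz` on x-faces (face 1 is the river-end boundary, face `nx+1`
#' the offshore boundary); `w` is `nx` x `(nz+1)` on z-faces (face 1 the
#' surface, face `nz+1` the seafloor), positive upward.
#'
#' Biological state can carry several independent stacks (one per riverine
#' nutrient multiplier): the physics does not feel N/P/Z/D, so sensitivity
#' cases differing only in nutrient input share one physical integration.
#' Stack 1 is mirrored in the top-level `N`, `P`, `Z`, `Dt` fields.
#'
#' @param grid An [fp_grid()].
#' @param T,S Temperature (degC) and salinity (psu): scalars, `nz` profiles,
#'   or `nx` x `nz` matrices.
#' @param C SSM concentration, kg/m^3 (same recycling rules).
#' @param N,P,Z,Dt Nitrate, phytoplankton, zooplankton, detritus, mol N/m^3.
#' @param t Model time, s.
#' @param n_bio Number of biological stacks (all initialised identically).
#' @return An `fp_state` object.
#' @export
fp_state <- function(grid, T = 20, S = 33, C = 0,
                     N = 0, P = 0, Z = 0, Dt = 0, t = 0, n_bio = 1L) {
  mat <- function(x) {
    if (is.matrix(x)) {
      stopifnot(nrow(x) == grid$nx, ncol(x) == grid$nz)
      x
    } else if (length(x) == grid$nz) {
      matrix(x, grid$nx, grid$nz, byrow = TRUE)
    } else if (length(x) == 1L) {
      matrix(x, grid$nx, grid$nz)
    } else stop("field must be scalar, nz-profile, or nx x nz matrix", call. = FALSE)
  }
  bio1 <- list(N = mat(N), P = mat(P), Z = mat(Z), Dt = mat(Dt))
  st <- structure(
    list(t = t,
         u = matrix(0, grid$nx + 1L, grid$nz),
         w = matrix(0, grid$nx, grid$nz + 1L),
         v = NULL,
         T = mat(T), S = mat(S), C = mat(C),
         N = bio1$N, P = bio1$P, Z = bio1$Z, Dt = bio1$Dt,
         bio = rep(list(bio1), n_bio),
         eta = numeric(grid$nx)),
    class = "fp_state")
  validate_state(st, grid)
  st
}

validate_state <- function(state, grid) {
  fields <- list(S = state$S, C = state$C, N = state$N, P = state$P,
                 Z = state$Z, Dt = state$Dt)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    if (!all(is.finite(f))) stop("non-finite values in ", nm, call. = FALSE)
    if (any(f < -1e-13)) stop("negative values in ", nm, call. = FALSE)
  }
  if (!all(is.finite(state$T))) stop("non-finite values in T", call. = FALSE)
  if (!all(is.finite(state$u)) || !all(is.finite(state$w))) {
    stop("non-finite velocities", call. = FALSE)
  }
  invisible(state)
}

# keep top-level N/P/Z/Dt in sync with stack 1
sync_bio <- function(state) {
  state$N <- state$bio[[1]]$N; state$P <- state$bio[[1]]$P
  state$Z <- state$bio[[1]]$Z; state$Dt <- state$bio[[1]]$Dt
  state
}

#' @export
print.fp_state <- function(x, ...) {
  cat(sprintf("<fp_state> t = %.2f h, S in [%.2f, %.2f], max C = %.3g kg/m3, %d bio stack(s)\n",
              x$t / 3600, min(x$S), max(x$S), max(x$C), length(x$bio)))
  invisible(x)
}

# total tracer inventories per unit width (for budget audits)
inventory <- function(state, grid) {
  vol <- grid$vol
  c(salt = sum(state$S * vol),
    ssm = sum(state$C * vol),
    nitrogen = sum((state$N + state$P + state$Z + state$Dt) * vol),
    heat = sum(state$T * vol))
}
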