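# Solver-level properties: projection, equilibrium, buoyancy sign,
# convective adjustment, stable_dt, and conservation through full steps.

test_that("a resting stratified state stays at rest", {
  m <- closed_model()
  st <- initial_state(m)
  for (i in 1:20) {
    st <- momentum_step(st, m$phys, m$grid, 60, m$ps,
                        rho_ambient = m$rho_ambient, u_left = NULL)
  }
  expect_lt(max(abs(st$u)), 1e-10)
  expect_lt(max(abs(st$w)), 1e-10)
})

test_that("an unstable two-layer inversion drives downward motion", {
  grid <- small_grid()
  cfg <- fp_config(grid = list(nx = grid$nx, nz = grid$nz, dx = grid$dx,
                               dz = grid$dz),
                   river = list(base_Q = 1e-9, peak_Q = 1e-9),
                   sponge = list(n = 0), numerics = list(spinup_days = 0))
  m <- fp_model(cfg, open_right = FALSE)
  # dense (salty) top layer over fresher interior in the middle columns
  S <- matrix(33, grid$nx, grid$nz)
  S[5:8, 1] <- 35
  st <- fp_state(grid, T = 20, S = S)
  amb <- equation_of_state(rep(20, grid$nz), rep(33, grid$nz), 0, m$phys)
  st <- momentum_step(st, m$phys, grid, 30, m$ps, rho_ambient = amb)
  # downward velocity under the dense patch (w face 2, below the top layer)
  expect_lt(min(st$w[5:8, 2]), 0)
  expect_lt(attr(st, "max_div"), 1e-8)
})

test_that("pressure projection drives divergence to round-off", {
  m <- closed_model()
  st <- initial_state(m)
  set.seed(3)
  st$u[2:m$grid$nx, ] <- matrix(rnorm((m$grid$nx - 1) * m$grid$nz, 0, 0.05),
                                m$grid$nx - 1)
  st <- momentum_step(st, m$phys, m$grid, 20, m$ps, rho_ambient = m$rho_ambient)
  expect_lt(attr(st, "max_div"), 1e-12)
})

test_that("lock-exchange front speed is near the inviscid gravity-current estimate", {
  # two reservoirs of different salinity; front advances at ~0.5 sqrt(g' H)
  nx <- 60; nz <- 8
  H <- 4; dxx <- 25
  cfg <- fp_config(grid = list(nx = nx, nz = nz, dx = dxx, dz = rep(H / nz, nz)),
                   physics = list(Av = 1e-5, Ah = 1e-2, Kh = 1e-2, Kv = 1e-6),
                   river = list(base_Q = 1e-9, peak_Q = 1e-9),
                   bio = list(enabled = FALSE),
                   sponge = list(n = 0), numerics = list(spinup_days = 0))
  m <- fp_model(cfg, open_right = FALSE)
  S <- matrix(30, nx, nz); S[1:(nx / 2), ] <- 33
  st <- fp_state(m$grid, T = 20, S = S)
  m$rho_ambient <- rep(equation_of_state(20, 31.5, 0, m$phys), nz)
  m$ambient$S <- rep(31.5, nz)
  drho <- equation_of_state(20, 33, 0, m$phys) - equation_of_state(20, 30, 0, m$phys)
  gp <- 9.81 * drho / m$phys$rho0
  u_front <- 0.5 * sqrt(gp * H)
  front_at <- function(st) max(which(st$S[, nz] > 31.5)) * dxx
  t_tot <- 0
  advance_to <- function(st, t_stop) {
    while (t_tot < t_stop) {
      dt <- min(5, stable_dt(st, m$phys, m$grid, safety = 0.35),
                t_stop - t_tot)
      sp <- step(st, m, dt); st <- sp$state; t_tot <<- t_tot + dt
    }
    st
  }
  st <- advance_to(st, 300)            # let the current establish
  f1 <- front_at(st)
  st <- advance_to(st, 1200)
  f2 <- front_at(st)
  speed <- (f2 - f1) / 900
  expect_gt(speed, 0.6 * u_front)
  expect_lt(speed, 1.4 * u_front)
})

test_that("convective adjustment stabilises and conserves, matching brute force", {
  grid <- small_grid(nx = 6, nz = 6)
  phys <- fp_phys()
  set.seed(21)
  for (rep in 1:10) {
    S <- matrix(runif(grid$nx * grid$nz, 30, 35), grid$nx, grid$nz)
    Tm <- matrix(runif(grid$nx * grid$nz, 10, 28), grid$nx, grid$nz)
    st <- fp_state(grid, T = Tm, S = S, N = 1e-3, P = 1e-4, Z = 1e-4, Dt = 1e-4)
    salt0 <- colSums(t(st$S) * grid$dz)      # per-column integrals
    heat0 <- colSums(t(st$T) * grid$dz)
    st2 <- convective_adjust(st, phys, grid)
    rho <- equation_of_state(st2$T, st2$S, st2$C, phys)
    expect_true(all(rho[, -1] - rho[, -grid$nz] >= -1e-9))
    expect_equal(colSums(t(st2$S) * grid$dz), salt0, tolerance = 1e-12)
    expect_equal(colSums(t(st2$T) * grid$dz), heat0, tolerance = 1e-12)
  }
  # stable column passes through unchanged
  stbl <- fp_state(grid, T = 20, S = matrix(rep(seq(30, 35, length.out = grid$nz),
                                                each = grid$nx), grid$nx))
  expect_identical(convective_adjust(stbl, phys, grid)$S, stbl$S)
  # an isolated two-equal-thickness-cell inversion mixes to the pair average
  g2 <- fp_grid(4, 4, dx = 100, dz = 1)
  Sb <- matrix(32, 4, 4); Sb[, 1] <- 34
  Sb[, 3] <- 35; Sb[, 4] <- 36            # strongly stable below the pair
  stb <- fp_state(g2, T = 20, S = Sb)
  out <- convective_adjust(stb, phys, g2)
  expect_equal(out$S[1, 1], 33, tolerance = 1e-12)
  expect_equal(out$S[1, 2], 33, tolerance = 1e-12)
  expect_equal(out$S[1, 3], 35, tolerance = 1e-12)
})

test_that("stable_dt equals the minimum of the three closed-form bounds", {
  m <- closed_model()
  grid <- m$grid; phys <- m$phys
  st <- initial_state(m)
  set.seed(5)
  st$u[2:grid$nx, ] <- 0.4
  dt1 <- stable_dt(st, phys, grid, ws = 0, safety = 1)
  # independent recomputation
  adv <- 1 / max(abs(st$u[-1, ]) / grid$dx +
                 pmax(abs(st$w[, -1]), abs(st$w[, -(grid$nz + 1)])) %*% diag(1 / grid$dz))
  dif <- 1 / (2 * max(phys$Kh, phys$Ah) / grid$dx^2 +
              2 * max(phys$Kv, phys$Av) / (min(grid$dz) * min(grid$dzf[2:grid$nz])))
  rho <- equation_of_state(st$T, st$S, st$C, phys)
  ciw <- sqrt(phys$g * (max(rho) - min(rho)) / phys$rho0 * sum(grid$dz))
  expect_equal(dt1, min(adv, dif, grid$dx / ciw), tolerance = 1e-10)
  # doubling the binding advective velocity halves the step
  st2 <- st; st2$u <- st$u * 2
  if (dt1 == 1 / (max(abs(st$u)) / grid$dx)) {
    expect_equal(stable_dt(st2, phys, grid, safety = 1), dt1 / 2, tolerance = 1e-10)
  }
  # the settling speed tightens the vertical CFL
  expect_lt(stable_dt(st, phys, grid, ws = 0.05, safety = 1), dt1)
  # safety factor scales linearly
  expect_equal(stable_dt(st, phys, grid, safety = 0.4),
               0.4 * stable_dt(st, phys, grid, safety = 1), tolerance = 1e-12)
})

test_that("closed zero-forcing steps conserve salt and nitrogen to round-off", {
  m <- closed_model()
  st <- initial_state(m)
  inv0 <- floodplume:::inventory_multi(st, m$grid)
  drift_per_step <- c()
  prev <- inv0
  for (i in 1:200) {
    sp <- step(st, m, 30)
    st <- sp$state
    cur <- floodplume:::inventory_multi(st, m$grid)
    drift_per_step <- c(drift_per_step,
                        abs(cur - prev) / abs(prev))
    prev <- cur
  }
  expect_lt(max(drift_per_step[names(prev) == "S"]), 1e-10)
  fin <- floodplume:::inventory_multi(st, m$grid)
  expect_lt(abs(fin["S"] - inv0["S"]) / inv0["S"], 1e-8)
  expect_lt(abs(fin["nitrogen1"] - inv0["nitrogen1"]) / inv0["nitrogen1"], 1e-8)
})

test_that("tracers never go negative and clipping is negligible", {
  cfg <- test_config()
  cfg$numerics$spinup_days <- 0
  cfg$output$duration <- 12 * 3600
  m <- fp_model(cfg, hyperpycnal_case())
  run <- simulate_run(m)
  st <- run$final_state
  for (nm in c("S", "C", "N", "P", "Z", "Dt")) {
    expect_gte(min(st[[nm]]), 0)
  }
  inv <- floodplume:::inventory_multi(st, m$grid)
  expect_lt(run$clipped, 1e-12 * max(inv["S"], 1))
})
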