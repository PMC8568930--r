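test_that("the flood hydrograph has exact base flow, peak and pulse volume", {
  h <- synthetic_flood_hydrograph(base_Q = 62.46, peak_Q = 3000,
                                  t_peak = 36 * 3600, rise = 12 * 3600,
                                  fall = 24 * 3600, duration = 120 * 3600)
  expect_equal(hydro_Q(h, 36 * 3600), 3000)
  # exact base flow outside the pulse support
  expect_equal(hydro_Q(h, c(0, 20 * 3600, 70 * 3600, 120 * 3600)),
               rep(62.46, 4))
  # single peak
  q <- hydro_Q(h, seq(0, 120 * 3600, by = 60))
  ipk <- which.max(q)
  expect_true(all(diff(q[seq_len(ipk)]) >= 0))
  expect_true(all(diff(q[ipk:length(q)]) <= 0))
  # quadrature oracle for the closed-form pulse volume
  num <- stats::integrate(function(t) hydro_Q(h, t) - h$base_Q, 0, 120 * 3600,
                          subdivisions = 2000, rel.tol = 1e-10)$value
  expect_equal(num, (3000 - 62.46) * (12 + 24) * 3600 / 2, tolerance = 1e-8)
  # degenerate flat hydrograph stays at the configured mean flow
  h0 <- synthetic_flood_hydrograph(base_Q = 62.46, peak_Q = 62.46)
  expect_equal(hydro_Q(h0, seq(0, 4e5, length.out = 11)), rep(62.46, 11))
  expect_error(synthetic_flood_hydrograph(peak_Q = 10), "peak_Q")
  expect_error(synthetic_flood_hydrograph(rise = -1), "positive")
})

test_that("riverine concentrations follow the standard inputs and multipliers", {
  std <- fp_std_inputs()
  expect_equal(riverine_concentrations(1000, hypopycnal_case(), std)$Nriver,
               0.046)
  wos <- tibble::tibble(ssm_mult = 0, nutrient_mult = 1)
  expect_equal(riverine_concentrations(1500, wos, std)$Criver, 0)
  # rating-curve scaling: doubling Q multiplies C by 2^b
  c1 <- riverine_concentrations(800, hypopycnal_case(), std)$Criver
  c2 <- riverine_concentrations(1600, hypopycnal_case(), std)$Criver
  expect_equal(c2 / c1, 2^std$b, tolerance = 1e-12)
})

test_that("standard-case calibration separates the plume regimes at peak flow", {
  # 10x the standard SSM load at peak discharge exceeds the density crossing
  # (hyperpycnal river water); 1x stays below it (hypopycnal)
  cfg <- fp_config()
  phys <- do.call(fp_phys, cfg$physics)
  std <- do.call(fp_std_inputs, cfg$std)
  cstar <- crossing_concentration(cfg$river$T_river, 0,
                                  cfg$initial$T_surf, cfg$initial$S_surf, phys)
  cpk <- std$a * cfg$river$peak_Q^std$b
  expect_gt(10 * cpk, cstar)
  expect_lt(1 * cpk, cstar)
  # the transition lies between 4 and 6 times the standard load
  expect_gt(6 * cpk, cstar)
  expect_lt(4 * cpk, cstar)
})

test_that("initial ocean is stable with a depleted surface and sub-surface maxima", {
  grid <- fp_grid(10, 12, dx = 300, dz = c(1, 1, 1, 1.5, 1.5, 2, 2, 2, 2, 2, 2, 2))
  init <- build_initial_ocean(grid)
  expect_true(all(diff(init$rho) >= -1e-12))
  expect_lt(init$N[1], max(init$N))          # nutrient-depleted surface
  expect_gt(which.max(init$P), 1)            # sub-surface chlorophyll maximum
  expect_equal(grid$zc[which.max(init$P)],
               grid$zc[which.min(abs(grid$zc - 8))])    # at the configured depth
  deep <- build_initial_ocean(grid, z_scm = 12)
  expect_equal(grid$zc[which.max(deep$P)],
               grid$zc[which.min(abs(grid$zc - 12))])
  # zero halocline strength gives a uniform salinity column
  flat <- build_initial_ocean(grid, dS = 0)
  expect_equal(flat$S, rep(32.8, grid$nz), tolerance = 1e-12)
  # an upside-down request errors
  expect_error(build_initial_ocean(grid, dT = 0, dS = -2), "unstable")
})

test_that("case grid reproduces the full-study shape and handles edge cases", {
  # six SSM loads x five diameters x five nutrient levels + references = 155
  full <- case_grid(c(1, 2, 4, 6, 8, 10), c(1, 2, 3, 4, 5) * 1e-5,
                    c(0, 0.1, 1, 5, 10))
  expect_equal(nrow(full), 155)
  expect_equal(sum(full$ssm_mult == 0), 5)   # one reference per nutrient level
  # an ssm_mult of 0 in the input folds into the references
  g <- case_grid(c(0, 2), 1e-5, 1)
  expect_equal(nrow(g), 2)
  # WOS-only set
  wos_only <- case_grid(0, numeric(0), c(1, 2))
  expect_equal(nrow(wos_only), 2)
  expect_true(all(wos_only$ssm_mult == 0))
  # duplicates collapse
  dup <- case_grid(c(2, 2, 4), c(1e-5, 1e-5), 1)
  expect_equal(nrow(dup), 2 * 1 * 1 + 1)
  expect_error(case_grid(12, 1e-5, 1), "0, 10")
})

test_that("presets are the marked regime-diagram cells", {
  expect_equal(hypopycnal_case()$ssm_mult, 4)
  expect_equal(hypopycnal_case()$diameter, 0.05e-3)
  expect_equal(hyperpycnal_case()$ssm_mult, 10)
  expect_equal(hyperpycnal_case()$diameter, 0.01e-3)
})

test_that("scenario generation is deterministic", {
  cfg <- test_config()
  m1 <- fp_model(cfg, hypopycnal_case())
  m2 <- fp_model(cfg, hypopycnal_case())
  expect_identical(m1$init, m2$init)
  expect_identical(hydro_Q(m1$hydro, 1:100 * 600), hydro_Q(m2$hydro, 1:100 * 600))
  expect_identical(config_hash(cfg, hypopycnal_case()),
                   config_hash(cfg, hypopycnal_case()))
  expect_false(config_hash(cfg, hypopycnal_case()) ==
                 config_hash(cfg, hyperpycnal_case()))
})

test_that("spinup returns the initial state for zero days and approaches steadiness", {
  cfg <- test_config()
  st0 <- spinup(cfg, days = 0)
  m <- fp_model(cfg)
  expect_equal(st0$S, initial_state(m)$S)
  st <- cached("spin_test", spinup(cfg, days = cfg$numerics$spinup_days))
  stead <- attr(st, "steadiness")
  expect_true(all(is.finite(stead)))
  # the surface salinity tendency in the last interval is small relative to
  # the total surface salinity scale
  expect_lt(stead["dS_dt"] / 32.8, 0.5)
})

test_that("fixture files are deterministic byte for byte", {
  cfg <- test_config()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixtures(cfg, d1)
  write_fixtures(cfg, d2)
  for (f in c("hydrograph.csv", "initial_ocean.csv")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})
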