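# helper: minimal synthetic fp_run with prescribed surface fields
fake_run <- function(times, S_list, N_list = NULL, P_list = NULL,
                     grid = fp_grid(6, 4, dx = 100, dz = 1),
                     nutrient_mults = 1, case = NULL) {
  L <- ncol(S_list[[1]])
  surf <- lapply(seq_along(times), function(j) {
    list(t = times[j], S = S_list[[j]],
         bio = lapply(seq_along(nutrient_mults), function(b) {
           list(N = if (is.null(N_list)) S_list[[j]] * 0 else N_list[[j]],
                P = if (is.null(P_list)) S_list[[j]] * 0 else P_list[[j]])
         }))
  })
  structure(list(case = case %||% tibble::tibble(label = "fake", ssm_mult = 1,
                                                 diameter = 1e-5,
                                                 nutrient_mult = 1),
                 nutrient_mults = nutrient_mults, grid = grid,
                 times = times, surface = surf),
            class = "fp_run")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("plume mask selects exactly the fresh surface cells, inclusive at 28", {
  pp <- fp_plume_params()
  S <- matrix(35, 6, 2)
  expect_false(any(plume_mask(S, pp)))
  S2 <- matrix(c(20, 28, 28.0001, 35, 27, 30), 6, 2)
  mk <- plume_mask(S2, pp)
  expect_identical(as.vector(mk), as.vector(S2 <= 28))
  expect_true(plume_mask(matrix(28, 1, 2), pp)[1, 1])   # boundary included
  # reference-state masking requires the reference
  ppr <- fp_plume_params(mask_source = "reference")
  expect_error(plume_mask(S2, ppr), "reference")
  expect_identical(plume_mask(S2 * 0 + 35, ppr, reference_state = S2),
                   plume_mask(S2, pp))
  # lowering the threshold never grows the mask
  pp_lo <- fp_plume_params(salinity_threshold = 20)
  expect_true(all(plume_mask(S2, pp_lo) <= plume_mask(S2, pp)))
})

test_that("plume mean is the volume-weighted mean and NA on empty masks", {
  grid <- fp_grid(4, 4, dx = 100, dz = c(1, 2, 1, 1))
  pp <- fp_plume_params()
  f <- matrix(5, 4, 4)
  mask <- matrix(TRUE, 4, 2)
  expect_equal(plume_mean(f, mask, grid), 5)
  # two equal-volume cells with 0 and 2 average to 1
  g2 <- fp_grid(4, 4, dx = 100, dz = 1)
  f2 <- matrix(0, 4, 4); f2[2, 1] <- 2
  m2 <- matrix(FALSE, 4, 2); m2[1:2, 1] <- TRUE
  expect_equal(plume_mean(f2, m2, g2), 1)
  # volume weighting across layers of unequal thickness
  f3 <- matrix(0, 4, 4); f3[, 2] <- 3
  m3 <- matrix(TRUE, 4, 2)
  expect_equal(plume_mean(f3, m3, grid), 3 * 2 / 3)
  expect_true(is.na(plume_mean(f, mask & FALSE, grid)))
  # random fields against a direct summation oracle
  set.seed(9)
  for (i in 1:10) {
    fr <- matrix(runif(16), 4, 4)
    mr <- matrix(runif(8) > 0.5, 4, 2)
    if (!any(mr)) next
    vol <- grid$vol[, 1:2]
    expect_equal(plume_mean(fr, mr, grid),
                 sum(fr[, 1:2][mr] * vol[mr]) / sum(vol[mr]), tolerance = 1e-12)
  }
})

test_that("difference series subtracts reference means and finds extrema", {
  grid <- fp_grid(6, 4, dx = 100, dz = 1)
  times <- 0:5 * 3600
  base <- matrix(20, 6, 2)
  # case: salinity dips by a known amount at t = 2 h
  dips <- c(0, -0.2, -0.9, -0.5, -0.1, 0)
  Sc <- lapply(dips, function(d) base + d)
  Sw <- lapply(times, function(t) base)
  run_c <- fake_run(times, Sc, grid = grid)
  run_w <- fake_run(times, Sw, grid = grid)
  ds <- difference_series(run_c, run_w)
  expect_s3_class(ds, "fp_plume_series")
  expect_equal(ds$dS, dips, tolerance = 1e-12)
  ext <- attr(ds, "extrema")
  expect_equal(ext$dS_ext, -0.9)
  expect_equal(ext$dS_t_ext, 2 * 3600)
  # identical runs give identically zero differences
  dz0 <- difference_series(run_w, run_w)
  expect_true(all(dz0$dS == 0))
  # antisymmetry
  dsr <- difference_series(run_w, run_c)
  expect_equal(dsr$dS, -ds$dS, tolerance = 1e-14)
  # constructed uniform offset appears exactly
  So <- lapply(times, function(t) base + 0.5)
  dso <- difference_series(fake_run(times, So, grid = grid), run_w)
  expect_true(all(abs(dso$dS - 0.5) < 1e-12))
  # mismatched times are rejected
  run_bad <- fake_run(times + 60, Sw, grid = grid)
  expect_error(difference_series(run_c, run_bad), "times")
})

test_that("regime classification matches the sign convention", {
  expect_equal(regime_classify(-0.3), "hypopycnal")
  expect_equal(regime_classify(1.0), "hyperpycnal")
  expect_equal(regime_classify(0.0), "neutral")
  expect_equal(regime_classify(c(-0.005, 0.005), tol = 0.01),
               c("neutral", "neutral"))
  expect_error(regime_classify(NaN), "finite")
})

test_that("river-sea density difference is diameter-independent with the right signs", {
  cfg <- fp_config()
  phys <- do.call(fp_phys, cfg$physics)
  std <- do.call(fp_std_inputs, cfg$std)
  wos <- tibble::tibble(ssm_mult = 0, diameter = NA, nutrient_mult = 1)
  d_wos <- river_density_difference(wos, std, T_river = 20, Q_peak = 3000,
                                    T_amb = 26, S_amb = 32.8, phys)
  expect_lt(d_wos, 0)                       # plain freshwater is buoyant
  c1 <- hypopycnal_case(); c2 <- hypopycnal_case(); c2$diameter <- 0.01e-3
  expect_identical(
    river_density_difference(c1, std, 20, 3000, 26, 32.8, phys),
    river_density_difference(c2, std, 20, 3000, 26, 32.8, phys))
  # at the crossing concentration the difference is zero
  cstar <- crossing_concentration(20, 0, 26, 32.8, phys)
  mult_star <- cstar / (std$a * 3000^std$b)
  cs <- tibble::tibble(ssm_mult = mult_star, diameter = 1e-5, nutrient_mult = 1)
  expect_lt(abs(river_density_difference(cs, std, 20, 3000, 26, 32.8, phys)), 1e-9)
})

test_that("regime map collects extrema, labels cells, and finds transitions", {
  grid <- fp_grid(6, 4, dx = 100, dz = 1)
  times <- 0:3 * 3600
  base <- matrix(20, 6, 2)
  mk_series <- function(peak) {
    Sc <- lapply(c(0, peak / 2, peak, peak / 4), function(d) base + d)
    Sw <- lapply(times, function(t) base)
    difference_series(fake_run(times, Sc, grid = grid),
                      fake_run(times, Sw, grid = grid))
  }
  # monotone-in-ssm synthetic dS crossing zero between multipliers 4 and 6
  peaks <- c(`1` = -0.4, `2` = -0.6, `4` = -0.3, `6` = 0.8, `8` = 1.6, `10` = 2.4)
  runs <- tibble::tibble(
    ssm_mult = as.numeric(names(peaks)), diameter = 1e-5,
    series = lapply(peaks, mk_series))
  rm <- build_regime_map(runs)
  expect_s3_class(rm, "fp_regime_map")
  expect_equal(rm$dS, unname(peaks))
  expect_equal(rm$label, unname(regime_classify(peaks)))
  tr <- attr(rm, "transitions")
  expect_equal(tr$interval[[1]], c(4, 6))
  # all-zero map is all neutral with no transition
  zero_runs <- tibble::tibble(ssm_mult = c(1, 2), diameter = 1e-5,
                              series = lapply(c(0, 0), mk_series))
  rm0 <- build_regime_map(zero_runs)
  expect_true(all(rm0$label == "neutral"))
  expect_true(all(is.na(attr(rm0, "transitions")$interval[[1]])))
  # incomplete rectangular grids are rejected with the missing cells listed
  bad <- tibble::tibble(ssm_mult = c(1, 2, 1), diameter = c(1e-5, 1e-5, 2e-5),
                        series = lapply(c(0, 0, 0), mk_series))
  expect_error(build_regime_map(bad), "missing cells")
})

test_that("tidy and glance methods return well-formed tibbles", {
  grid <- fp_grid(6, 4, dx = 100, dz = 1)
  times <- 0:3 * 3600
  base <- matrix(20, 6, 2)
  Sc <- lapply(c(0, -0.2, -0.6, -0.1), function(d) base + d)
  Sw <- lapply(times, function(t) base)
  ds <- difference_series(fake_run(times, Sc, grid = grid),
                          fake_run(times, Sw, grid = grid))
  td <- generics::tidy(ds)
  expect_true(all(c("time", "variable", "difference") %in% names(td)))
  expect_equal(nrow(td), length(times) * 3)
  gl <- generics::glance(ds)
  expect_equal(gl$regime, "hypopycnal")
  runs <- tibble::tibble(ssm_mult = c(1, 2), diameter = 1e-5,
                         series = list(ds, ds))
  gm <- generics::glance(build_regime_map(runs))
  expect_equal(gm$n_hypopycnal, 2)
})
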