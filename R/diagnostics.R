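#' Plume diagnostic parameters
#'
#' The plume is the set of surface cells (top `surface_layers` layers,
#' roughly the top 2 m) whose salinity does not exceed `salinity_threshold`
#' (28 psu; the threshold value itself is inside the plume). `mask_source`
#' chooses whether each run is masked by its own salinity field
#' (`"per-case"`, the default) or by a designated reference run
#' (`"reference"`).
#'
#' @param salinity_threshold Plume salinity threshold, psu.
#' @param surface_layers Number of surface layers in the plume mask.
#' @param mask_source `"per-case"` or `"reference"`.
#' @param neutral_tol Salinity-difference tolerance, psu, inside which a case
#'   is classified neutral.
#' @return An `fp_plume_params` object.
#' @export
fp_plume_params <- function(salinity_threshold = 28.0, surface_layers = 2L,
                            mask_source = c("per-case", "reference"),
                            neutral_tol = 0.01) {
  mask_source <- match.arg(mask_source)
  stopifnot(salinity_threshold > 0, surface_layers >= 1)
  structure(list(salinity_threshold = salinity_threshold,
                 surface_layers = as.integer(surface_layers),
                 mask_source = mask_source, neutral_tol = neutral_tol),
            class = "fp_plume_params")
}

#' River-plume mask over the surface layers
#'
#' A surface cell belongs to the plume when its salinity is less than or
#' equal to the threshold (S = 28.0 exactly is inside).
#'
#' @param state An `fp_state`, or an `nx` x (>= `surface_layers`) salinity
#'   matrix.
#' @param pp An [fp_plume_params()].
#' @param reference_state Required when `pp$mask_source == "reference"`: the
#'   state (or salinity matrix) whose salinity defines the mask.
#' @return Logical `nx` x `surface_layers` matrix.
#' @export
plume_mask <- function(state, pp = fp_plume_params(), reference_state = NULL) {
  src <- if (pp$mask_source == "reference") {
    if (is.null(reference_state)) {
      stop("mask_source = 'reference' needs a reference_state", call. = FALSE)
    }
    reference_state
  } else state
  S <- if (is.matrix(src)) src else src$S
  S[, seq_len(pp$surface_layers), drop = FALSE] <= pp$salinity_threshold
}

#' Volume-weighted mean over the plume mask
#'
#' @param field `nx` x `nz` (or `nx` x `surface_layers`) field matrix.
#' @param mask Logical matrix from [plume_mask()].
#' @param grid An [fp_grid()].
#' @return The volume-weighted mean over masked cells; `NA` when the mask is
#'   empty (missing, not zero).
#' @export
plume_mean <- function(field, mask, grid) {
  if (!any(mask)) return(NA_real_)
  L <- ncol(mask)
  f <- field[, seq_len(L), drop = FALSE]
  v <- grid$vol[, seq_len(L), drop = FALSE]
  sum(f[mask] * v[mask]) / sum(v[mask])
}

# plume-masked surface means for every output time and stack of a run
plume_series_one <- function(run, pp, reference_run = NULL) {
  grid <- run$grid
  L <- pp$surface_layers
  nb <- length(run$nutrient_mults)
  rows <- vector("list", length(run$times) * nb)
  r <- 1L
  for (j in seq_along(run$times)) {
    snap <- run$surface[[j]]
    ref <- if (!is.null(reference_run)) reference_run$surface[[j]]$S else NULL
    mask <- plume_mask(snap$S, pp, reference_state = ref)
    area <- sum(grid$vol[, seq_len(L), drop = FALSE][mask])
    Sm <- plume_mean(snap$S, mask, grid)
    for (b in seq_len(nb)) {
      rows[[r]] <- tibble::tibble(
        time = run$times[j], nutrient_mult = run$nutrient_mults[b],
        area = area, S = Sm,
        N = plume_mean(snap$bio[[b]]$N, mask, grid),
        P = plume_mean(snap$bio[[b]]$P, mask, grid))
      r <- r + 1L
    }
  }
  dplyr::bind_rows(rows)
}

#' Plume-mean time series of a run
#'
#' @param run An `fp_run` from [simulate_run()] or [run_case()].
#' @param pp An [fp_plume_params()].
#' @param reference_run Reference run whose salinity defines the mask when
#'   `pp$mask_source == "reference"`.
#' @return Tibble with `time` (s), `nutrient_mult`, plume `area` (m^2 per unit
#'   width), and plume-mean `S` (psu), `N`, `P` (mol N/m^3). Empty-mask times
#'   are `NA`.
#' @export
plume_series <- function(run, pp = fp_plume_params(), reference_run = NULL) {
  if (pp$mask_source == "reference" && is.null(reference_run)) {
    stop("mask_source = 'reference' needs a reference_run", call. = FALSE)
  }
  plume_series_one(run, pp,
                   reference_run = if (pp$mask_source == "reference") reference_run)
}

#' Difference-from-reference plume series
#'
#' Joins the plume-mean series of a case run and its no-SSM reference at
#' matched output times and nutrient multipliers and forms
#' `dX(t) = mean_case(X) - mean_reference(X)` for X in S, N, P. The extremum
#' of each difference (value and time of the maximum magnitude, missing
#' values excluded) is attached as the `extrema` attribute.
#'
#' @param case_run,wos_run `fp_run` objects on identical grids and output
#'   times.
#' @param pp An [fp_plume_params()].
#' @return An `fp_plume_series` tibble: `time`, `nutrient_mult`, `area`, `S`,
#'   `N`, `P`, `S_ref`, `N_ref`, `P_ref`, `dS`, `dN`, `dP`.
#' @export
difference_series <- function(case_run, wos_run, pp = fp_plume_params()) {
  if (!isTRUE(all.equal(case_run$times, wos_run$times))) {
    stop("case and reference runs have different output times", call. = FALSE)
  }
  if (!identical(dim(case_run$surface[[1]]$S), dim(wos_run$surface[[1]]$S))) {
    stop("case and reference runs are on different grids", call. = FALSE)
  }
  ref_for_mask <- if (pp$mask_source == "reference") wos_run
  cs <- plume_series_one(case_run, pp, reference_run = ref_for_mask)
  ws <- plume_series_one(wos_run, pp, reference_run = ref_for_mask)
  j <- dplyr::left_join(cs,
                        dplyr::rename(ws, area_ref = "area", S_ref = "S",
                                      N_ref = "N", P_ref = "P"),
                        by = c("time", "nutrient_mult"))
  j <- dplyr::mutate(j, dS = .data$S - .data$S_ref, dN = .data$N - .data$N_ref,
                     dP = .data$P - .data$P_ref)
  ext <- j |>
    dplyr::group_by(.data$nutrient_mult) |>
    dplyr::summarise(dplyr::across(c("dS", "dN", "dP"),
                                   list(ext = ~extremum_value(.x, j$time[dplyr::cur_group_rows()]),
                                        t_ext = ~extremum_time(.x, j$time[dplyr::cur_group_rows()]))),
                     .groups = "drop")
  # differences at the time the (reference) plume is largest: the convention
  # the nutrient/plankton heat maps use ("when the river plume is
  # sufficiently large")
  at_max <- j |>
    dplyr::group_by(.data$nutrient_mult) |>
    dplyr::slice(which.max(ifelse(is.finite(.data$dS), .data$area_ref, -Inf))) |>
    dplyr::ungroup() |>
    dplyr::select("nutrient_mult", "time", "dS", "dN", "dP") |>
    dplyr::rename(t_area_max = "time")
  out <- structure(j, class = c("fp_plume_series", class(j)))
  attr(out, "extrema") <- ext
  attr(out, "at_plume_max") <- at_max
  attr(out, "case") <- case_run$case
  out
}

extremum_value <- function(x, time) {
  ok <- is.finite(x)
  if (!any(ok)) return(NA_real_)
  x[ok][which.max(abs(x[ok]))]
}

extremum_time <- function(x, time) {
  ok <- is.finite(x)
  if (!any(ok)) return(NA_real_)
  time[ok][which.max(abs(x[ok]))]
}

#' Classify a salinity-difference extremum into a plume regime
#'
#' Negative differences (fresher plume than the no-SSM reference) mark an
#' intensified hypopycnal plume; positive differences (saltier surface) mark
#' a hyperpycnal/homopycnal plume; differences within the tolerance are
#' neutral.
#'
#' @param delta_S Salinity difference at the extremum, psu. Vectorised.
#' @param tol Neutral tolerance, psu.
#' @return Character vector: `"hypopycnal"`, `"hyperpycnal"` or `"neutral"`.
#' @export
regime_classify <- function(delta_S, tol = 0.01) {
  if (any(!is.finite(delta_S))) stop("non-finite salinity difference", call. = FALSE)
  dplyr::case_when(delta_S < -tol ~ "hypopycnal",
                   delta_S > tol ~ "hyperpycnal",
                   TRUE ~ "neutral")
}

#' Predicted river-sea density difference for a case
#'
#' The regime-diagram abscissa: density of river water at the flood peak
#' (river temperature, zero salinity, SSM at the case's peak concentration)
#' minus ambient surface density. Independent of particle diameter.
#'
#' @param case Single-row case tibble.
#' @param std An [fp_std_inputs()].
#' @param T_river River temperature, degC.
#' @param Q_peak Peak discharge, m^3/s.
#' @param T_amb,S_amb Ambient surface temperature and salinity.
#' @param phys An [fp_phys()].
#' @return Density difference, kg/m^3 (positive = river water denser).
#' @export
river_density_difference <- function(case, std, T_river, Q_peak,
                                     T_amb, S_amb, phys) {
  Cpk <- case$ssm_mult * std$a * Q_peak^std$b
  equation_of_state(T_river, 0, Cpk, phys) -
    equation_of_state(T_amb, S_amb, 0, phys)
}

#' Build the regime map from a set of difference series
#'
#' Collects, for every cell of a rectangular (SSM multiplier x diameter)
#' sweep, the plume-mean salinity difference at the time of its maximum
#' magnitude, labels each cell with [regime_classify()], and reports per
#' diameter the bracketing SSM multipliers between which the sign of the
#' extremal difference flips (the hypopycnal-to-hyperpycnal transition
#' interval).
#'
#' @param runs A tibble with columns `ssm_mult`, `diameter` and a list-column
#'   `series` of [difference_series()] results (one row per case), e.g. the
#'   `runs` element of [run_sweep()].
#' @param pp An [fp_plume_params()].
#' @param nutrient_mult Which nutrient multiplier's series to map.
#' @return An `fp_regime_map` tibble: `ssm_mult`, `diameter`, `dS`, `t_ext`
#'   (s), `label`, with attributes `transitions` (per-diameter intervals) and
#'   `pp`.
#' @export
build_regime_map <- function(runs, pp = fp_plume_params(), nutrient_mult = 1) {
  stopifnot(all(c("ssm_mult", "diameter", "series") %in% names(runs)))
  sm <- sort(unique(runs$ssm_mult))
  dm <- sort(unique(runs$diameter))
  want <- tidyr::expand_grid(ssm_mult = sm, diameter = dm)
  have <- dplyr::distinct(runs[, c("ssm_mult", "diameter")])
  miss <- dplyr::anti_join(want, have, by = c("ssm_mult", "diameter"))
  if (nrow(miss)) {
    stop("incomplete sweep grid; missing cells: ",
         paste(sprintf("(ssm %g, d %g)", miss$ssm_mult, miss$diameter),
               collapse = ", "), call. = FALSE)
  }
  cells <- purrr::pmap(runs[, c("ssm_mult", "diameter", "series")],
                       function(ssm_mult, diameter, series) {
    ext <- attr(series, "extrema")
    ext <- ext[ext$nutrient_mult == nutrient_mult, ]
    tibble::tibble(ssm_mult = ssm_mult, diameter = diameter,
                   dS = ext$dS_ext, t_ext = ext$dS_t_ext)
  })
  map <- dplyr::arrange(dplyr::bind_rows(cells), .data$diameter, .data$ssm_mult)
  map$label <- regime_classify(ifelse(is.na(map$dS), 0, map$dS), pp$neutral_tol)
  map$label[is.na(map$dS)] <- NA_character_
  transitions <- map |>
    dplyr::group_by(.data$diameter) |>
    dplyr::summarise(interval = list(sign_flip_interval(.data$ssm_mult, .data$dS)),
                     .groups = "drop")
  out <- structure(map, class = c("fp_regime_map", class(map)))
  attr(out, "transitions") <- transitions
  attr(out, "pp") <- pp
  out
}

#' Summarise the flood response of a difference series
#'
#' The quantities the regime analysis reads off one case: the extremal
#' plume-mean salinity difference and its lag behind the flood peak; the
#' nutrient and phytoplankton differences evaluated at that moment (when the
#' SSM-physical interaction is strongest); their own extrema and times; and
#' the decay fraction `|dS(t_peak + 3 days)| / |dS_ext|`. A plume that has
#' dissipated by the evaluation time (undefined mean) has decayed completely
#' and scores 0.
#'
#' @param ds An [difference_series()] result.
#' @param t_peak Time of the flood-discharge peak, s.
#' @return A tibble with one row per nutrient multiplier.
#' @export
flood_response <- function(ds, t_peak) {
  ext <- attr(ds, "extrema")
  out <- lapply(seq_len(nrow(ext)), function(i) {
    nm <- ext$nutrient_mult[i]
    sub <- ds[ds$nutrient_mult == nm, ]
    t_ext <- ext$dS_t_ext[i]
    at_ext <- sub[sub$time == t_ext, ]
    t3d <- t_peak + 72 * 3600
    i3d <- which(sub$time >= t3d)[1]
    dS3d <- if (is.na(i3d)) NA_real_ else sub$dS[i3d]
    decay <- if (is.na(i3d)) NA_real_ else {
      if (is.na(dS3d)) 0 else abs(dS3d) / abs(ext$dS_ext[i])
    }
    tibble::tibble(
      nutrient_mult = nm,
      dS_ext = ext$dS_ext[i], t_ext = t_ext,
      lag_h = (t_ext - t_peak) / 3600,
      dN_at_Sext = at_ext$dN[1], dP_at_Sext = at_ext$dP[1],
      dN_ext = ext$dN_ext[i], dN_t_ext = ext$dN_t_ext[i],
      dP_ext = ext$dP_ext[i], dP_t_ext = ext$dP_t_ext[i],
      decay_frac_3d = decay)
  })
  dplyr::bind_rows(out)
}

# bracketing multipliers between which the extremal dS changes sign
sign_flip_interval <- function(ssm_mult, dS) {
  o <- order(ssm_mult)
  m <- ssm_mult[o]; d <- dS[o]
  ok <- is.finite(d)
  m <- m[ok]; d <- d[ok]
  if (length(d) < 2) return(c(NA_real_, NA_real_))
  s <- sign(d)
  flip <- which(s[-length(s)] * s[-1] < 0)
  if (!length(flip)) return(c(NA_real_, NA_real_))
  c(m[flip[1]], m[flip[1] + 1])
}
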