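#' Run one sensitivity case (and, if needed, its reference)
#'
#' Integrates the scaled flood scenario for one case: optional spinup under
#' constant base flow (shared across cases via the `spinup_state` argument),
#' then the flood window. Deterministic given the configuration. When
#' `out_dir` is given, the plume series and budget report are written as CSV
#' and a manifest entry as JSON; a case whose manifest entry matches the
#' configuration hash is not recomputed (its outputs are reloaded).
#'
#' @param config An [fp_config()].
#' @param case Single-row case tibble ([case_grid()], [hypopycnal_case()],
#'   [hyperpycnal_case()], or `NULL` for the no-SSM reference).
#' @param nutrient_mults Nutrient multipliers to carry as parallel biological
#'   stacks (default: the case's own).
#' @param spinup_state Optional pre-computed spinup `fp_state` (see
#'   [spinup()]); when `NULL` and `config$numerics$spinup_days > 0`, a spinup
#'   is run first.
#' @param out_dir Optional output directory for CSV/JSON artefacts.
#' @return An `fp_run`.
#' @export
run_case <- function(config, case = NULL, nutrient_mults = NULL,
                     spinup_state = NULL, out_dir = NULL) {
  model <- fp_model(config, case, nutrient_mults)
  if (!is.null(out_dir)) {
    hit <- manifest_lookup(out_dir, model$case$label,
                           config_hash(config, model$case), model$grid, config)
    if (!is.null(hit)) return(hit)
  }
  if (is.null(spinup_state) && config$numerics$spinup_days > 0) {
    spinup_state <- spinup(config, days = config$numerics$spinup_days,
                           nutrient_mults = model$nutrient_mults)
  }
  state <- if (!is.null(spinup_state)) {
    reset_clock(spinup_state, n_bio = length(model$nutrient_mults))
  } else {
    initial_state(model)
  }
  run <- simulate_run(model, state)
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# restart a spun-up state at t = 0, replicating biological stacks as needed
reset_clock <- function(state, n_bio = 1L) {
  state$t <- 0
  if (length(state$bio) != n_bio) {
    state$bio <- rep(state$bio[1], n_bio)
  }
  sync_bio(state)
}

#' Spin up the pre-flood quasi-steady state
#'
#' Integrates the model from the configured initial profiles under constant
#' base-flow river forcing (no SSM) until the plume and estuarine circulation
#' are quasi-steady. Returns the final state, with the domain-mean absolute
#' tendencies of S and N over the last day attached as the `steadiness`
#' attribute (psu/day, mol N/m^3/day).
#'
#' @param config An [fp_config()].
#' @param days Spinup length, days (0 returns the initial state unchanged).
#' @param nutrient_mults Biological stacks to carry.
#' @return An `fp_state`.
#' @export
spinup <- function(config, days = config$numerics$spinup_days,
                   nutrient_mults = 1) {
  cfg <- config
  cfg$river$peak_Q <- cfg$river$base_Q        # constant base flow
  cfg$numerics$spinup_days <- 0
  model <- fp_model(cfg, case = NULL, nutrient_mults = nutrient_mults)
  state <- initial_state(model)
  if (days <= 0) return(state)
  run <- simulate_run(model, state, t_end = days * 86400,
                      out_dt = max(3600, days * 86400 / 24))
  fin <- run$final_state
  nout <- length(run$times)
  if (nout >= 2) {
    dt_day <- (run$times[nout] - run$times[nout - 1]) / 86400
    s_prev <- run$surface[[nout - 1]]; s_last <- run$surface[[nout]]
    attr(fin, "steadiness") <- c(
      dS_dt = mean(abs(s_last$S - s_prev$S)) / dt_day,
      dN_dt = mean(abs(s_last$bio[[1]]$N - s_prev$bio[[1]]$N)) / dt_day)
  }
  fin
}

#' Run a sensitivity sweep and build its regime map
#'
#' Runs every case of the grid (the no-SSM reference once per distinct
#' nutrient multiplier — carried as parallel stacks in a single physical
#' integration), computes each case's difference series against the
#' reference, and assembles the regime map and the difference heat-map
#' tables. With `out_dir`, completed cases found in the manifest are reused
#' rather than recomputed, making an interrupted sweep resumable.
#'
#' @param config An [fp_config()].
#' @param cases An [case_grid()] tibble.
#' @param pp An [fp_plume_params()] (default from the configuration).
#' @param out_dir Optional output directory (CSV tables + JSON manifest).
#' @return An `fp_sweep` list: `runs` (tibble with one row per SSM case and a
#'   `series` list-column), `wos` (the reference `fp_run`), `regime_map`, and
#'   `tables` (named list of ssm x diameter matrices of dS, dN, dP at their
#'   extrema, one per nutrient multiplier).
#' @export
run_sweep <- function(config, cases, pp = NULL, out_dir = NULL) {
  if (is.null(pp)) pp <- do.call(fp_plume_params, config$diagnostics)
  nmults <- sort(unique(cases$nutrient_mult))
  spin <- if (config$numerics$spinup_days > 0) {
    spinup(config, nutrient_mults = nmults)
  }
  wos <- run_case(config, case = NULL, nutrient_mults = nmults,
                  spinup_state = spin, out_dir = out_dir)
  ssm_cases <- cases[cases$ssm_mult > 0, , drop = FALSE]
  key <- dplyr::distinct(ssm_cases[, c("ssm_mult", "diameter")])
  rows <- purrr::pmap(key, function(ssm_mult, diameter) {
    case <- tibble::tibble(
      label = sprintf("ssm%g_d%gmm", ssm_mult, diameter * 1e3),
      ssm_mult = ssm_mult, diameter = diameter, nutrient_mult = 1)
    run <- run_case(config, case, nutrient_mults = nmults,
                    spinup_state = spin, out_dir = out_dir)
    tibble::tibble(ssm_mult = ssm_mult, diameter = diameter,
                   label = case$label,
                   series = list(difference_series(run, wos, pp)))
  })
  runs <- dplyr::bind_rows(rows)
  rmap <- build_regime_map(runs, pp, nutrient_mult = nmults[which.min(abs(nmults - 1))])
  tables <- sweep_tables(runs, nmults)
  out <- structure(list(runs = runs, wos = wos, regime_map = rmap,
                        tables = tables, config = config, pp = pp),
                   class = "fp_sweep")
  if (!is.null(out_dir)) write_sweep_tables(out, out_dir)
  out
}

# ssm x diameter matrices of extremal dS, dN, dP per nutrient multiplier
sweep_tables <- function(runs, nmults) {
  out <- list()
  for (nm in nmults) {
    ext <- purrr::pmap(runs[, c("ssm_mult", "diameter", "series")],
                       function(ssm_mult, diameter, series) {
      e <- attr(series, "extrema")
      e <- e[e$nutrient_mult == nm, ]
      tibble::tibble(ssm_mult = ssm_mult, diameter = diameter,
                     dS = e$dS_ext, dN = e$dN_ext, dP = e$dP_ext)
    }) |> dplyr::bind_rows()
    for (v in c("dS", "dN", "dP")) {
      wide <- tidyr::pivot_wider(ext[, c("ssm_mult", "diameter", v)],
                                 names_from = "diameter",
                                 values_from = tidyselect::all_of(v))
      out[[sprintf("%s_n%g", v, nm)]] <- wide
    }
  }
  out
}

#' @export
print.fp_sweep <- function(x, ...) {
  cat(sprintf("<fp_sweep> %d SSM cases x %d nutrient multiplier(s) + reference\n",
              nrow(x$runs), length(x$wos$nutrient_mults)))
  print(x$regime_map)
  invisible(x)
}

# ---- on-disk artefacts ----------------------------------------------------

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(out_dir, run$case$label)
  utils::write.csv(plume_series(run), paste0(base, "_plume.csv"), row.names = FALSE)
  utils::write.csv(run$budget, paste0(base, "_budget.csv"), row.names = FALSE)
  # compact lossless surface archive so a finished case is never recomputed
  arch <- list(case = as.list(run$case), nutrient_mults = run$nutrient_mults,
               times = run$times, hash = run$hash,
               max_div = run$max_div, clipped = run$clipped,
               deposit = run$ledger$deposit,
               surface = lapply(run$surface, function(s) {
                 list(t = s$t, S = as.vector(s$S), dimS = dim(s$S),
                      bio = lapply(s$bio, function(bb) {
                        list(N = as.vector(bb$N), P = as.vector(bb$P))
                      }))
               }))
  jsonlite::write_json(arch, paste0(base, "_surface.json"),
                       auto_unbox = TRUE, digits = NA)
  man_path <- file.path(out_dir, "manifest.json")
  man <- if (file.exists(man_path)) jsonlite::read_json(man_path) else list()
  man[[run$case$label]] <- list(hash = run$hash, status = "complete",
                                files = basename(paste0(base, c("_plume.csv",
                                                                "_budget.csv",
                                                                "_surface.json"))),
                                written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(man, man_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(run)
}

# reload a completed case from its archive when the manifest hash matches
manifest_lookup <- function(out_dir, label, hash, grid, config) {
  man_path <- file.path(out_dir, "manifest.json")
  if (!file.exists(man_path)) return(NULL)
  man <- jsonlite::read_json(man_path)
  ent <- man[[label]]
  if (is.null(ent) || !identical(ent$hash, hash)) return(NULL)
  arch_path <- file.path(out_dir, paste0(label, "_surface.json"))
  if (!file.exists(arch_path)) return(NULL)
  a <- jsonlite::read_json(arch_path, simplifyVector = FALSE)
  num <- function(x) unlist(x, use.names = FALSE)
  times <- num(a$times)
  surf <- lapply(seq_along(times), function(j) {
    s <- a$surface[[j]]
    dimS <- as.integer(num(s$dimS))
    list(t = num(s$t), S = matrix(num(s$S), dimS[1], dimS[2]),
         bio = lapply(s$bio, function(bb) {
           list(N = matrix(num(bb$N), dimS[1], dimS[2]),
                P = matrix(num(bb$P), dimS[1], dimS[2]))
         }))
  })
  ledger <- fp_ledger(grid)
  ledger$deposit <- num(a$deposit)
  a$case[vapply(a$case, is.null, logical(1))] <- NA
  structure(
    list(case = tibble::as_tibble(a$case), nutrient_mults = num(a$nutrient_mults),
         config = config, grid = grid, times = times, surface = surf,
         final_state = NULL, ledger = ledger, budget = NULL,
         max_div = a$max_div, clipped = a$clipped, hash = a$hash,
         cached = TRUE),
    class = "fp_run")
}

write_sweep_tables <- function(sweep, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(sweep$tables)) {
    utils::write.csv(sweep$tables[[nm]],
                     file.path(out_dir, paste0("table_", nm, ".csv")),
                     row.names = FALSE)
  }
  rm <- sweep$regime_map
  utils::write.csv(as.data.frame(rm), file.path(out_dir, "regime_map.csv"),
                   row.names = FALSE)
  tr <- attr(rm, "transitions")
  jsonlite::write_json(
    list(axes = list(ssm_mult = sort(unique(rm$ssm_mult)),
                     diameter = sort(unique(rm$diameter))),
         labels = rm$label,
         transitions = stats::setNames(tr$interval, tr$diameter)),
    file.path(out_dir, "regime_map.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(sweep)
}
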