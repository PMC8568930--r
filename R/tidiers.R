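#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a difference series
#'
#' One row per output time, nutrient multiplier and variable, with the
#' case-minus-reference difference in long form.
#'
#' @param x An `fp_plume_series` from [difference_series()].
#' @param ... Unused.
#' @return A tibble with `time`, `nutrient_mult`, `variable` (S/N/P), `value`,
#'   `reference`, `difference`.
#' @export
tidy.fp_plume_series <- function(x, ...) {
  base <- tibble::as_tibble(x)
  out <- dplyr::bind_rows(lapply(c("S", "N", "P"), function(v) {
    tibble::tibble(time = base$time, nutrient_mult = base$nutrient_mult,
                   variable = v, value = base[[v]],
                   reference = base[[paste0(v, "_ref")]],
                   difference = base[[paste0("d", v)]])
  }))
  dplyr::arrange(out, .data$time, .data$nutrient_mult, .data$variable)
}

#' Summary of a difference series
#'
#' @param x An `fp_plume_series`.
#' @param ... Unused.
#' @return One row per nutrient multiplier: extremal dS, dN, dP, their times
#'   (s), and the regime label from the salinity extremum.
#' @export
glance.fp_plume_series <- function(x, ...) {
  ext <- attr(x, "extrema")
  dplyr::mutate(ext, regime = regime_classify(.data$dS_ext))
}

#' Tidy a regime map
#'
#' @param x An `fp_regime_map`.
#' @param ... Unused.
#' @return The map as a plain tibble (one row per sweep cell).
#' @export
tidy.fp_regime_map <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Summary of a regime map
#'
#' @param x An `fp_regime_map`.
#' @param ... Unused.
#' @return One row: cell counts per regime, the extreme dS values, and the
#'   range of per-diameter transition intervals.
#' @export
glance.fp_regime_map <- function(x, ...) {
  tr <- attr(x, "transitions")
  lo <- suppressWarnings(min(unlist(lapply(tr$interval, `[`, 1)), na.rm = TRUE))
  hi <- suppressWarnings(max(unlist(lapply(tr$interval, `[`, 2)), na.rm = TRUE))
  tibble::tibble(
    n_cells = nrow(x),
    n_hypopycnal = sum(x$label == "hypopycnal", na.rm = TRUE),
    n_hyperpycnal = sum(x$label == "hyperpycnal", na.rm = TRUE),
    n_neutral = sum(x$label == "neutral", na.rm = TRUE),
    min_dS = min(x$dS, na.rm = TRUE), max_dS = max(x$dS, na.rm = TRUE),
    transition_lo = if (is.finite(lo)) lo else NA_real_,
    transition_hi = if (is.finite(hi)) hi else NA_real_)
}

#' Glance at a run: budget-closure summary
#'
#' @param x An `fp_run`.
#' @param ... Unused.
#' @return One row per audited tracer with the relative budget residual and
#'   the worst post-projection divergence of the run.
#' @export
glance.fp_run <- function(x, ...) {
  if (is.null(x$budget)) {
    return(tibble::tibble(tracer = character(), rel_residual = numeric()))
  }
  dplyr::mutate(x$budget[, c("tracer", "initial", "final", "rel_residual")],
                max_div = x$max_div)
}
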