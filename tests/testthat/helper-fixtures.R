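# Shared small fixtures.  Everything is generated in code; the expensive
# scenario runs used by several test files are memoised in this environment
# so one suite run pays for them once.

.fp_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fp_cache)) {
    assign(key, force(expr), envir = .fp_cache)
  }
  get(key, envir = .fp_cache)
}

small_grid <- function(nx = 12, nz = 6) {
  fp_grid(nx, nz, dx = 400, dz = c(1, 1, 1.5, 1.5, 2, 2)[seq_len(nz)])
}

# tiny closed-basin model with river forcing off
closed_model <- function(nx = 12, nz = 6, bio_on = TRUE) {
  cfg <- fp_config(
    grid = list(nx = nx, nz = nz, dx = 400, dz = c(1, 1, 1.5, 1.5, 2, 2)[seq_len(nz)]),
    river = list(base_Q = 1e-9, peak_Q = 1e-9),
    bio = list(enabled = bio_on),
    sponge = list(n = 0),
    numerics = list(spinup_days = 0))
  fp_model(cfg, case = NULL, open_right = FALSE)
}

# reduced-resolution scenario configuration used for the fast scenario tests
test_config <- function(...) {
  fp_config(grid = list(nx = 40, nz = 10, dx = 300,
                        dz = c(1, 1, 1, 1.5, 1.5, 2, 2, 2, 2, 2)),
            output = list(duration = 72 * 3600),
            river = list(t_peak = 18 * 3600, rise = 9 * 3600, fall = 18 * 3600),
            numerics = list(spinup_days = 0.5),
            ...)
}
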