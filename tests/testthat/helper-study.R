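# The study-configuration runs shared by the structural and target tests.
# One spinup + seven flood runs at the default configuration, computed once
# per suite run (lazily) and cached in .fp_cache (helper-fixtures.R).

study_nutrient_mults <- c(0.1, 1, 10)

study_sweep <- function() {
  cached("study_sweep", {
    cfg <- fp_config()
    cases <- case_grid(c(1, 4, 10), c(0.01e-3, 0.05e-3),
                       study_nutrient_mults)
    run_sweep(cfg, cases)
  })
}

study_pp <- function() do.call(fp_plume_params, fp_config()$diagnostics)

# difference series of one sweep member
study_series <- function(ssm, d) {
  sw <- study_sweep()
  i <- which(sw$runs$ssm_mult == ssm & abs(sw$runs$diameter - d) < 1e-12)
  sw$runs$series[[i]]
}

study_response <- function(ssm, d, nutrient_mult = 1) {
  fr <- flood_response(study_series(ssm, d), fp_config()$river$t_peak)
  fr[fr$nutrient_mult == nutrient_mult, ]
}
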