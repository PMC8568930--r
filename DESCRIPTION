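Package: floodplume
Title: Flood River Plumes with Suspended-Sediment Density Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation and analysis of flooding river discharge into a
    stratified coastal sea, with the density effect of suspended sediment matter (SSM)
    coupled into a two-dimensional (x-z) non-hydrostatic Boussinesq solver. Includes
    Rubey settling of sediment classes, a nitrogen-based NPZD lower-trophic ecosystem,
    a synthetic scenario generator (flood hydrograph, stratified initial ocean,
    sensitivity-case grids), and the diagnostics layer used to contrast hypopycnal and
    hyperpycnal plume regimes against a reference run without SSM: plume masking,
    plume-mean difference series, and regime maps over SSM amount and particle diameter.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    tibble,
    dplyr,
    tidyr,
    tidyselect,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
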