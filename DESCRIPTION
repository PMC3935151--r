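Package: dielmat
Title: Diel Electron Mass Balance for Phototrophic Microbial Mat Microcosms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of day/night (diel) carbon and electron cycling in
    hypersaline microbial mat microcosms. Converts concentration time series
    from sealed-vial and benthic flux-chamber incubations into area-normalized
    net fluxes, expresses dissolved inorganic carbon uptake, glycogen storage,
    and fermentation-product release (acetate, formate, propionate, hydrogen)
    in common electron-equivalent currency, and estimates the fraction of
    photosynthetically fixed electrons that is fermented at night and the
    fraction consumed by accessory (non-phototrophic) populations. Also
    provides dimer-corrected NanoSIMS delta-13C enrichment statistics with
    normality-gated significance testing, OTU-table rarefaction with Chao1
    and ACE richness estimation, cDNA:DNA ribosomal expression ratios, and a
    synthetic-data generator that emulates the measurement structure of diel
    manipulation experiments so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    broom,
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
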