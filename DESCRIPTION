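Package: dendrocomp
Title: Climate, Competition and Drought Resilience Analysis for Even-Aged Pine Stands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A dendroecological pipeline for plantation forests: distance-dependent
    (Hegyi) competition indices and their retroactive annual reconstruction from
    dated ring-width series, basal-area-increment (BAI) chronologies with regional
    curve standardization (RCS) detrending and Rbar/EPS/SNR quality statistics,
    monthly climate derivation (vapor pressure deficit, Thornthwaite potential
    evapotranspiration, multi-scale standardized precipitation-evapotranspiration
    index), monthly climate-growth correlation screens, variance-decomposition
    attribution of growth to climate, competition and site condition (LMG relative
    importance), and Lloret drought resistance, recovery and resilience indices with
    density-dependence tests. Includes a synthetic stand, climate and growth
    generator with known ground truth so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
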