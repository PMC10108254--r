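Package: standflux
Title: Biometric and Chamber-Based Forest Carbon Budgets for Managed Boreal Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assemble annual stand-level carbon budgets for managed
    boreal forests from field measurements: allometric tree biomass and net
    primary production (NPP) from repeated inventories and litter traps,
    understory NPP from clip harvests and fine-root ingrowth cores,
    heterotrophic soil respiration from closed-chamber CO2 fluxes extrapolated
    with Lloyd-Taylor temperature-response functions, and dead-wood
    respiration from decay-constant accounting. Per-stand budgets (net
    ecosystem production, NEP = NPP - RH) are aggregated by stand age class,
    fitted with log-quadratic and polynomial age-trend curves, and used for
    rotation-forestry carbon calculus (optimum rotation age, carbon
    compensation point, long-term sequestration rate) and landscape driver
    analysis (varimax-rotated PCA, Pearson correlations). Includes a
    deterministic synthetic-landscape generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
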