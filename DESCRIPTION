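Package: copt
Title: Continents, Oceans and Plate Tectonics in the Drake Equation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how rare planets with long-lived coexisting
    continents, oceans and plate tectonics (COPT planets) are expected to
    be, and what that rarity implies for the number of active communicative
    civilizations in the galaxy.  Provides an isostatic surface-water
    budget model giving the radius-dependent window of surface water mass
    fraction that permits continents, oceans and plate tectonics to
    coexist; estimators for the fraction of habitable planets with
    significant continents and oceans (f_oc) and the fraction with
    long-lived plate tectonics (f_pt); classic and modified Drake
    equations with point, interval-arithmetic and seeded Monte Carlo
    evaluation; timescale calculators for the single-lid to
    plate-tectonics transition; a constant-rate birth-death model of
    sequential speciation chains; and a seeded generator of synthetic
    exoplanet populations (radius, surface water mass fraction) for
    end-to-end pipeline checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, yaml, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
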