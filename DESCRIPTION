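Package: birdpva
Title: Stochastic Leslie Matrix Models of Bird Mortality Limits
Version: 1.0.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Age-structured (Leslie matrix) population models for assessing
    how commonly used mortality limits affect bird populations subject to
    additional human-caused mortality such as wind-turbine collisions.
    Provides postbreeding-census matrix construction from vital-rate tables,
    eigen-analysis (growth rate, stable age distribution, adult-survival
    elasticity), stochastic density-independent projections with
    environmental stochasticity drawn from clipped normal distributions,
    density-dependent models with recruitment calibrated to a target
    low-density growth rate, potential biological removal (PBR) harvesting
    with recovery-factor sweeps, and a simple allowable-mortality formula
    linking the harvestable fraction to the low-density growth rate and an
    acceptable equilibrium-density reduction. Ships the eleven
    species-population-period vital-rate sets used throughout as plain-text
    fixtures, plus a generator of random but valid synthetic life histories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
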