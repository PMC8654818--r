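Package: reefcots
Title: Fisheries Removal, No-Take Reserves and Crown-of-Thorns Starfish
    Density
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bayesian analysis pipeline linking coral reef fish biomass
    removal by fisheries to densities of the corallivorous Crown-of-Thorns
    Starfish (CoTS, Acanthaster spp.). Provides a synthetic generator for
    manta-tow surveys, belt-transect fish censuses and fisheries
    retained-catch tables with known ground truth; deterministic data
    preparation (coral-cover category conversion, duplicate resolution,
    catch aggregation, lagged pairing, length-weight biomass); hierarchical
    hurdle-gamma and negative-binomial regression fitted by MCMC with
    convergence diagnostics; and drivers for the lagged catch-density
    grid, paired-reef reserve comparisons and the zoning model of CoTS
    density, summarised as posterior medians, credible intervals and
    probability-of-direction evidence classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    coda,
    dplyr,
    ggplot2,
    jsonlite,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
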