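Package: drivebrake
Title: Eco-Evolutionary Dynamics of CRISPR Homing Gene Drives and Brake Alleles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a single population segregating for a wild-type allele,
    a CRISPR homing gene drive and a cas9-devoid brake (reversal) construct
    that targets the drive. Tracks genotype densities in continuous time with
    logistic, density-dependent reproduction, so that eradication drives feed
    back on allele-frequency change. Provides deterministic trajectories with
    a critical extinction density, numerical stability analysis of boundary
    equilibria (drive loss, fixation, coexistence, bistability and the
    associated invasion threshold), an exact Gillespie stochastic counterpart
    with replicate ensembles and outcome tallies, and the factorial scenario
    grid used to compare fitness-restoring (specific) and non-restoring
    (universal) brakes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
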