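Package: spoorstats
Title: Spoor-Count Estimation of Large-Carnivore Density Across Land-Use Types
Version: 0.1.0
Authors@R:
    person("Savanna", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for track (spoor) count surveys of large carnivores along
    vehicle transects: ingestion and validation of survey records, filtering of
    old and duplicate spoor, spoor density and frequency statistics, bootstrap
    precision analysis of inter-spoor intervals (confidence-interval and
    coefficient-of-variation curves against sampling effort), linear
    calibration of spoor density to population density and size with
    transect-level bootstrap confidence intervals, a tie-corrected
    Kruskal-Wallis comparison of spoor densities between land-use types, a
    parameterized national extrapolation of population declines under
    land-reform scenarios, and a Poisson encounter-process simulator for
    parameter-recovery studies. Includes a worked 2008 survey example from a
    southern African conservancy split across private, resettlement and
    communal land.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
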