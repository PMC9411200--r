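Package: chronotel
Title: Circadian Analysis of Locomotor Activity and Body Temperature Telemetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis battery for home-cage telemetry in circadian
    phenotyping studies: onset/offset detection and alpha, free-running
    period from onset regression, onset variability in entrained and
    free-running conditions, Lomb-Scargle periodogram power,
    non-parametric relative amplitude (M10/L5), Aschoff Type II light-pulse
    phase shifts, jet-lag re-entrainment time, food-anticipatory activity
    under restricted feeding, and the accompanying group statistics
    (3-SD outlier exclusion, pooled t tests, factorial ANOVA, Hedges' g).
    Includes a synthetic telemetry simulator with named group presets so
    every stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    car,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'schedules.R'
    'telemetry-io.R'
    'presets.R'
    'simulate.R'
    'episodes.R'
    'rhythm.R'
    'phase.R'
    'stats.R'
    'battery.R'
    'actogram.R'
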