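Package: larvagrowth
Title: Growth-Trajectory Analysis of Sexual Size Dimorphism in Larval Insects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how sexual size dimorphism (SSD) arises during
    larval growth in insects with a fixed number of instars. Simulates
    populations of last-instar larval mass trajectories with brood-level and
    individual-level random variation, reads and writes longitudinal trajectory
    tables, extracts growth-curve descriptors (maximal mass, time to maximum,
    pre-pupal mass loss, daily increments), computes differential growth-rate
    indices (absolute, relative, and allometric, i.e. the daily gain in
    cube-root-transformed mass), tests sex effects with repeated-measures mixed
    ANOVAs using larva-based denominator degrees of freedom, and decomposes SSD
    into contributions of a growth-rate difference versus an extra day of
    growth under a cubic growth model.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    tools,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    lme4,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
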