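Package: papaspt
Title: Proximity-Assisted Photoactivation Single-Particle Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis tools for single-particle tracking
    experiments that use proximity-assisted photoactivation (PAPA) of
    rhodamine dye pairs. Generates synthetic single-molecule data with
    known ground truth (fluorophore dark-state photophysics under
    programmable red/green/violet illumination sequences, two-state
    Brownian motion with localization error, camera rendering with
    Poisson noise, TCSPC decays), localizes and links particles, splits
    trajectories into PAPA and direct-reactivation classes, infers
    diffusion spectra over a fixed grid of diffusion coefficients by
    expectation-maximization, unmixes spectra into component fractions
    to estimate fold enrichment of double-labeled complexes, and fits
    ensemble reactivation kinetics and fluorescence lifetimes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
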