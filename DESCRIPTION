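Package: phagecocktail
Title: Chemostat Simulation of Bacteriophage Cocktail Infection Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Forward simulation of the population dynamics of a bacterial
    host infected by one or two interfering virulent bacteriophages in a
    chemostat. Thirteen bacterial compartments (susceptible, singly and
    doubly infected, singly and doubly resistant, and refuge populations)
    are coupled to nutrient concentration through Monod growth kinetics and
    to two free-phage pools through either mass-action ("Standard") or
    Poisson multiple-adsorption kinetics. Lysis is delayed by phage-specific
    latent periods using infection-time cohort ledgers, superinfection is
    resolved by lysis-time competition, and resistance arises at cell
    division either deterministically or by Poisson/normal sampling.
    Integration uses fixed-step Euler stepping at 60, 30, 15 or 5 second
    resolution. Includes a plain-text run-configuration format, CSV and
    PNG/SVG chart output, bundled example scenarios, and a command-line
    runner.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    jsonlite
Config/testthat/edition: 3
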