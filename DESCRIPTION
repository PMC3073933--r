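Package: dispersim
Title: Dispersion-Index Homogeneity Analysis and Chemotaxis Simulation for
    Tracked Microorganisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests complete spatial randomness of tracked organism positions
    in a microfluidic channel, frame by frame, using the variance-to-mean
    dispersion index of quadrat counts with two-sided chi-squared rejection
    bounds, swept over a range of partition scales and applied to both
    coordinate marginals.  Includes an area-normalised chemotactic index for
    band-loaded devices, generators for homogeneous and inhomogeneous Poisson
    point fields, and an agent-based drift-diffusion (Keller-Segel analogue)
    simulator of control, attractant and repellent chemotaxis experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
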