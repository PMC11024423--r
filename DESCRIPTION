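Package: fieldtrialsim
Title: Simulation of Plot Data in Multi-Environment Plant-Breeding Field Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Simulates realistic plot-level data for single- and
    multi-environment plant-breeding field trials. Plot errors are composed of
    a spatial trend component (bivariate piecewise-linear interpolation over
    random knots, or a separable first-order autoregressive process), random
    noise, and extraneous column/row-aligned variation, combined at
    user-defined variance proportions. Genetic values for multiple traits are
    simulated under unstructured, compound-symmetry, or multiplicative
    genotype-by-environment models, and phenotypes are assembled under a
    randomised complete block design. Includes the diagnostics commonly used
    to assess spatial analyses of such trials: the sample variogram,
    plot-level heritability, expected and realised prediction accuracy, and
    genetic-variance bias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ggplot2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
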