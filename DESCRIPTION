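Package: chirodyn
Title: Angular-Momentum Statistics of Molecules Desorbing from Chiral Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying dynamic diastereomerism in surface desorption:
    equipartition-based normal-mode velocity sampling at a transition state,
    a synthetic conservative chiral-surface potential with a velocity-Verlet
    NVE integrator, desorption detection, angular-momentum pseudovector time
    series in units of hbar, and distributional statistics (sign
    subpopulations, two-component Gaussian mixture fits with Cramer-von Mises
    goodness of fit, folded |Lz| distributions). Reads and writes multi-frame
    extended-XYZ trajectories with velocities so ensembles from any molecular
    dynamics engine can be analysed.
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
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
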