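Package: poreperm
Title: Selective Pore Permeability Analysis for Shell Protein Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to characterize selective permeability of protein channel
    pores, built around the analysis workflow used for bacterial
    microcompartment shell hexamers such as the carboxysome protein CcmK2.
    Provides umbrella-sampling free-energy reconstruction in one and two
    dimensions (weighted and dynamic histogram analysis methods) with
    block-splitting error bars and autocorrelation diagnostics, an
    overdamped-Langevin synthetic data generator with known ground-truth
    potentials of mean force, inscribed-sphere pore constriction profiling,
    Kabsch superposition with RMSD/RMSF analysis, distance-and-angle contact
    detection, contact-conditioned pore-diameter statistics (Wilcoxon
    rank-sum), and Arrhenius/Kramers rate-ratio computation from free-energy
    barriers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
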