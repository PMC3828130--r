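Package: cgligand
Title: Coarse-Grained Simulation of Ligand-Receptor Binding Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tunable coarse-grained model for ligand-receptor systems:
    spherical ligands diffusing in three dimensions bind membrane receptors
    through an anisotropic (patchy) Lennard-Jones potential whose strength and
    angular specificity are independently tunable, propagated by Langevin
    dynamics in a periodic box. Includes builders for dissociation,
    association and chimeric-ligand experiments, statistical estimators for
    affinity (kon) and dissociation (koff) rate constants, transport-limited
    rate decomposition, and selectivity screens for bivalent chimeric ligands
    whose subunits are joined by a worm-like-chain linker.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
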