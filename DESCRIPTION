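Package: membindr
Title: Membrane Binding Analysis of Charged Small Molecules from MD Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for molecular-dynamics trajectories of lipid
    bilayers with charged small-molecule solutes: lipid head-group C-H bond
    order parameters and their response to bound charge, bound-molecule
    assignment with data-driven selection of the binding criterion, number
    density profiles along the membrane normal and their inverse-Boltzmann
    potential of mean force, solute-lipid contact statistics including the
    phosphate-oxygen contact fraction, membrane permeation event counting,
    and electronic continuum correction (ECC) charge scaling of topologies.
    Ships a synthetic-trajectory generator with closed-form ground truth for
    every observable, so the whole pipeline is testable without running MD.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
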