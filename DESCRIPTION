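Package: sdpfit
Title: Joint SAXS/SANS Scattering Density Profile Analysis of
    Peptide-Bearing Lipid Bilayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling small-angle x-ray and neutron scattering
    from unilamellar lipid vesicles with membrane-adsorbed antimicrobial
    peptides.  Implements a composition-based scattering density profile
    (SDP) description of POPE/POPG bilayers with quasimolecular groups and
    a single peptide Gaussian, the analytic flat-bilayer form factor for
    arbitrary x-ray and D2O-contrast neutron conditions, joint
    multi-contrast ensemble fitting with a genetic algorithm and
    moment-based aggregation over independent runs, derived structural
    parameters (Luzzati thickness, hydrocarbon thickness, headgroup
    distance, peptide position, thermal area expansion), a synthetic
    four-contrast study generator with known ground truth, and a
    coarse-grained peptide dimer classifier based on marker distances.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
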