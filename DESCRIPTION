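Package: spectrobind
Title: Spectroscopic Analysis of Drug Binding to Plasma Proteins and
    Model Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of UV-Vis and fluorescence titration
    experiments that characterize small-molecule binding to plasma
    proteins and lipid vesicles. Provides inner-filter correction and
    band integration of spectra, Stern-Volmer quenching analysis with
    static/dynamic classification, 1:1 binding-isotherm fits and van't
    Hoff thermodynamics, Forster-radius and overlap-integral
    calculations for tryptophan-to-ligand energy transfer,
    membrane/water partition-coefficient fits, steady-state fluorescence
    anisotropy and lipid phase-transition fitting, first-order
    degradation kinetics, and competitive plasma drug-distribution
    estimates. Includes seeded synthetic-data generators emulating each
    experiment class and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
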