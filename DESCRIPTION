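Package: confinedrods
Title: Hard-Rod Monte Carlo and Defect Analysis for Confined Colloidal Nematics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Metropolis Monte Carlo simulation of hard spherocylinders in
    shallow disk- and annulus-shaped chambers, together with the analysis
    stack needed to characterise the resulting nematic textures:
    sub-particle-resolution local tensor order parameter fields, angular
    deficit maps, winding-number defect detection and charge assignment,
    bipolar and n-fold (D_n) pattern classification with the inscribed
    n-gon rule, and a minimal single-constant two-dimensional Q-tensor
    relaxation as the continuum baseline. Analytic defect-field generators
    make the whole analysis path testable without running Monte Carlo.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
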