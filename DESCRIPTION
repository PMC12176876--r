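Package: neurofba
Title: Entropic Flux Balance Analysis of Synaptic and Non-Synaptic Neuronal Bioenergetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based bioenergetic analysis of compartment-specific
    neuronal metabolic models, with entropic flux balance analysis (a strictly
    convex x*log(x) objective on unidirectional fluxes) solved by a built-in
    interior-point method that exposes all dual variables, including metabolite
    chemical potentials. Provides ATP-contribution accounting under energy-demand
    scans, Complex I inhibition and substrate-sensitivity scans, classification
    of control-versus-disease exchange-flux changes against cerebrospinal-fluid
    metabolomics directions, single-reaction knockout and flux-forcing rescue
    analyses, median-of-ratios count normalization with gene-weight thresholds,
    and a deterministic generator of toy dopaminergic-neuron networks in four
    condition-specific variants (synaptic/non-synaptic x control/PD).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
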