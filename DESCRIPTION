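Package: spectraldcm
Title: Dynamic Causal Modelling of Neural Oscillations from Cross-Spectral Densities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Biophysical generative models of oscillatory neural data and the
    Bayesian machinery to invert them. Implements four-population neural-mass
    and neural-field forward models that map synaptic rate constants and
    connection gains to predicted complex cross-spectral densities;
    Variational-Laplace model inversion with a free-energy (evidence bound)
    objective; Bayesian model reduction for closed-form scoring of reduced
    models; parametric empirical Bayes for hierarchical (group) analyses with
    design matrices, exhaustive model-space search and Bayesian model
    averaging; current-source-density depth profiling of laminar field
    potentials with sink localisation; and a laminar layer-assignment model
    comparison based on log-evidence differences. Ships synthetic-data
    generators for single subjects, multi-subject cohorts with second-level
    structure, two-channel laminar spectra and depth-resolved LFP profiles,
    plus plain-text interchange formats and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
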