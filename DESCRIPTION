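Package: qmribrain
Title: Digital-Phantom Quantitative MRI of Cerebral Compartments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of quantitative brain MRI for paired
    two-condition studies of cerebral compartment shifts. Provides a
    three-compartment (grey matter, white matter, CSF) digital phantom with
    proton-density-weighted, multi-gradient-echo and multi-b-value
    diffusion-weighted forward models; log-linear T2* relaxometry with
    percentile-trimmed compartment means; range-specific apparent diffusion
    coefficient (ADC) mapping and bounded Levenberg-Marquardt fitting of the
    simplified intravoxel-incoherent-motion (IVIM) kurtosis signal model;
    prior-weighted Gaussian-mixture segmentation and probabilistic
    compartment volumetry; and voxel-wise paired t statistics with
    Benjamini-Hochberg false-discovery-rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
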