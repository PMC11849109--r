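Package: oxflow
Title: Regional Brain Oxygenation from Multi-Delay pCASL and Quantitative
    Susceptibility Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates regional cerebral oxygen extraction fraction (OEF)
    and the cerebral metabolic rate of oxygen (CMRO2) by combining cerebral
    blood flow (CBF) and arterial transit time (ATT) from multi-delay
    pseudo-continuous arterial spin labelling (pCASL) with venous oxygen
    saturation (SvO2) from quantitative susceptibility maps of large
    cerebral veins and arterial saturation (SaO2) from exhaled-oxygen
    traces via the Severinghaus relation. Provides a single-blood-compartment
    kinetic forward model and voxel-wise bounded nonlinear least-squares
    fitting, vein ROI refinement and percentile-based susceptibility
    extraction, venous drainage territory composition and aggregation,
    Bland-Altman test-retest repeatability statistics, a linear mixed-model
    group stage, and synthetic phantom generators (ASL signal volumes,
    cylindrical vein susceptibility phantoms, respiratory traces, cohorts)
    so the whole pipeline can be exercised without acquired data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    pracma,
    lme4,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
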