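Package: ct2bmd
Title: Bone Mineral Density Prediction from CT Texture Features
Version: 1.0.0
Authors@R:
    person("ct2bmd", "Developers", email = "ct2bmd@example.org", role = c("aut", "cre"))
Description: Predicts volumetric bone mineral density (BMD) from routine
    clinical CT images. Second-order Haralick texture features (energy,
    entropy, contrast, homogeneity, correlation) are computed from
    gray-level co-occurrence matrices of a region of interest and fed to a
    small feedforward backpropagation network (5 inputs, 40 tan-sigmoid
    hidden neurons, 1 linear output) whose targets come from
    phantom-calibrated quantitative CT Hounsfield units. Includes a
    synthetic trabecular-bone phantom generator with matched sharp "QCT"
    and degraded "clinical CT" renderings for end-to-end validation
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
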