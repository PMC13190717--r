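Package: tremornet
Title: Metabolic Network Analysis of Thalamic DBS Tremor Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Within-subject FDG-PET analysis of deep brain stimulation (DBS)
    effects in essential tremor: stimulation-induced metabolic change mapping,
    spatial-similarity scoring against a template tremor-treatment network with
    Moran spectral randomization surrogate inference, amplitude-controlled
    clinical outcome regression, a sign-split normative-connectivity voxel-wise
    linear model with permutation cluster correction, and a simplified
    ordinal-trends covariance pattern analysis. Includes a synthetic-cohort
    generator with known ground truth for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
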