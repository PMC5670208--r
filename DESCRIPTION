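Package: cb1quant
Title: Quantification of CB1 Receptor PET, Electrodermal, Symptom and
    BOLD Effect Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale analysis pipeline for multimodal pharmacological
    imaging studies of the cannabinoid-1 (CB1) receptor system. Builds
    metabolite-corrected arterial plasma input functions from continuous and
    discrete blood data, quantifies the radioligand volume of distribution
    (VT) by spectral analysis with non-negative least squares, frame
    weighting and a free blood-volume term, scores stimulus-locked skin
    conductance responses by an explicit amplitude/latency rule, computes
    symptom time-course statistics (trapezoidal AUC, Friedman and
    Kolmogorov-Smirnov tests), estimates BOLD effects with a two-gamma
    convolution model and sum-of-squares-ratio permutation inference, and
    relates regional VT to drug-induced symptom and activation effects by
    Pearson correlation. A synthetic-data module generates every input the
    pipeline consumes so that all stages are testable without subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
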