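Package: rdsbc
Title: Radial Direction Selectivity of Retinal Bipolar Cells from Space-Time Receptive Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study radial direction selectivity (rDS) in retinal
    bipolar cells from one-dimensional space-time receptive fields (RFs).
    Generates moving-bar, 1-D noise, looming and apparent-motion stimuli;
    produces synthetic centre-surround RF populations and noisy response
    traces; smooths traces by Gaussian-process regression and computes the
    d-prime motion-preference statistic; estimates smooth space-time RFs by
    penalised spline regression and extracts latency, surround strength,
    biphasic index and centre width; clusters RFs by sparse PCA and Gaussian
    mixtures with BIC model selection; predicts motion responses by linear
    convolution with preference and motion-coherence indices; and simulates a
    biophysical ball-and-stick starburst amacrine cell dendrite with
    calcium dynamics driven by RF-based bipolar-cell inputs to measure
    direction selectivity along the dendrite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    splines,
    signal,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
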