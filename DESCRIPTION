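Package: aisquant
Title: Quantification of Axon Initial Segment Protein Distribution and
    Neuronal Excitability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the subcellular distribution of axon
    initial segment (AIS) proteins from fluorescence intensity line
    profiles: background subtraction, three-point smoothing, peak and
    15%-of-peak boundary detection, integrated sums and the axo:dendritic
    ratio; per-neuron statistical feature extraction (interquartile range,
    kurtosis, skewness, root mean square) with a repeated 70/30
    support-vector-machine classification harness; and active/passive
    feature extraction from current-clamp sweep families (rheobase,
    voltage threshold, input resistance, membrane time constant, action
    potential waveform velocities). Includes a synthetic-data generator
    producing profile cohorts, rendered images and leaky-integrator sweep
    families with known ground truth, and a reproducible end-to-end
    pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    zoo,
    e1071,
    jsonlite,
    yaml,
    minpack.lm,
    tiff
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse,
    withr
Config/testthat/edition: 3
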