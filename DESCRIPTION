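Package: punctaquant
Title: Quantification of Synaptic Fluorescence Puncta Along Neuronal Cords
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Line-scan quantification of presynaptic reporter fluorescence in
    neuronal processes: extraction of calibrated 1D intensity profiles from
    grayscale micrographs along a traced cord polyline, punctum calling by the
    peak-to-baseline (inter-punctal fluorescence) ratio rule, puncta number
    (PN) and synaptic enrichment (SE) statistics, and per-genotype group
    comparison with Student's t-tests. Includes a synthetic-scene generator
    that emulates punctate, diffuse, enlarged-puncta and cell-body-retention
    phenotypes with a Poisson-Gaussian camera noise model, providing ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
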