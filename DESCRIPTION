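Package: axovuln
Title: Quantitative Microscopy Pipeline for Comparing Axonal Vulnerability of Neuronal Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of multichannel fluorescence images of cultured
    neurons: soma census with survival normalization across hydrogen-peroxide
    doses, neurite skeletonization and morphometry, size-gated axonal varicosity
    detection with synaptotagmin-1 positivity classification, redox-sensitive
    GFP (roGFP) trace quality control and relative-oxidation quantification,
    puncta spacing metrics, and an estimation-statistics layer (bias-corrected
    and accelerated bootstrap mean differences with shared-control designs,
    plus the usual omnibus and post hoc tests). Ships a synthetic-image and
    trace generator with ground truth so the whole pipeline is testable without
    raw microscopy data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    boot,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
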