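Package: tf3dnet
Title: Spatial Co-Localization of Transcription Factor Binding Sites in 3D
    Genome Organization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies three-dimensional co-localization of transcription
    factor (TF) binding sites from population Hi-C contact maps and from
    single-cell genome structures. Computes chromatin co-localization (CCL)
    scores as sums of log observed/expected contact enrichment between binding
    sites, calls significantly co-localized TF pairs against permutation null
    models, derives signed Kullback-Leibler contact-enrichment (CE) matrices
    and TF proximity sub-networks by hierarchical clustering, and measures
    spatial density enrichment (SDE) and structural proximity enrichment (PE)
    in multi-model particle representations of single-cell genome structures.
    Includes a synthetic-data generator that plants known co-localization
    signal so every pipeline stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tools,
    cluster,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
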