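Package: cnmatch
Title: Matching Genome-Wide Absolute Copy Number Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares genome-wide absolute DNA copy number profiles between
    samples, for example a tumour or cell-line profile against a reference
    collection of cell-line profiles. Segment tables (e.g. ASCAT output) are
    rasterized onto fixed-width genomic bins, copy number boundaries are
    aligned by a window-based smoothing procedure, and profile pairs are
    scored under four similarity metrics (Pearson correlation, Manhattan
    distance, Euclidean distance, cosine similarity). The package quantifies
    the percentage genome difference between profiles, assesses match
    significance against an empirical null, ranks best matches in a reference
    collection, and additionally matches samples by copy-number-signature
    exposures via seeded k-means clustering. A seeded simulator generates
    synthetic profiles and perturbed sister cultures so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    cluster,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    optparse,
    S4Vectors,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
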