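Package: proxfpi
Title: Proximity-Labeling Proteomics with Empirical False-Positive-Rate Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for TurboID/BioID proximity-labeling experiments
    quantified by tandem mass tags (TMT). Computes per-protein log2 enrichment of
    bait replicates over a no-ligase control and a compartment-matched spatial
    control, derives log2-ratio cutoffs at a target False Positive Identification
    (FPI) rate from curated lists of proteins from irrelevant subcellular
    compartments, applies the dual filters per replicate, intersects replicates
    into a final proximal proteome, and tags results with Gene Ontology keyword
    categories. Includes a synthetic 4-plex TMT data generator with known ground
    truth so the whole pipeline is testable without mass-spectrometry downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
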