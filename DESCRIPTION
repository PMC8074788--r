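Package: cbpid
Title: Sea Turtle Species Identification from Corneous Beta-Protein Peptide Markers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Identifies the species of origin of tortoiseshell (sea turtle scute
    keratin) from proteomic peptide-spectrum matches. Provides a corneous
    beta-protein (CBP) marker database with wildcard class templates, peptide
    classification by mismatch-tolerant template matching, in-silico semispecific
    tryptic digestion, per-marker median-absolute-deviation score cut-offs,
    oxidation/dioxidation and phosphorylation site-occupancy statistics,
    cleavage-degradation summaries, marker-set species assignment, and
    PCA/self-organizing-map/k-means sample classification, plus a seeded
    generator of synthetic PSM tables emulating modern and degraded
    (archaeological) specimens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
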