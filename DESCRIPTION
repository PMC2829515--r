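Package: homeoCAPS
Title: CAPS and cDNA-AFLP Analysis of Homeolog Loss and Silencing in
    Allopolyploids
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the fate of duplicated gene copies
    (homeologs) in recently formed allopolyploid plants. Designs
    diagnostic CAPS (cleaved amplified polymorphic sequence) assays by
    in-silico restriction digestion of parental allele pairs, models
    agarose gel band patterns, classifies polyploid individuals at the
    genomic tier (additive, homeolog loss, ambiguous) and at the cDNA
    tier (expressed, silenced, absent due to genomic loss), scores
    cDNA-AFLP presence/absence fragment matrices, and tallies
    study-level loss and silencing statistics. Includes a synthetic
    data generator with known ground truth for end-to-end validation
    of the classification pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
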