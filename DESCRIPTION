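Package: crisprscreen
Title: Design and Analysis of Pooled CRISPRa/CRISPRi Secretion Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for pooled CRISPR activation/interference screens read out
    by droplet sorting: promoter-window SpCas9 guide enumeration with bin-based
    selection, genome-wide Hamming-distance off-target filtering, four-guide
    type II-S (BspQI) oligo cassette packing with restriction digest
    simulation, inline-barcode demultiplexing and exact guide counting,
    negative-binomial GLM likelihood-ratio enrichment testing with RLE
    normalization and Benjamini-Hochberg FDR control, droplet Poisson loading
    and coverage calculators, non-coding-RNA neighbor orientation analysis,
    and synthetic-data generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    DESeq2,
    optparse
Config/testthat/edition: 3
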