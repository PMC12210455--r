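Package: geveR
Title: Detection and Epigenomic Characterization of Giant Endogenous Viral Elements
Version: 0.1.0
Authors@R:
    person("geveR", "Developers", email = "gever@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide characterization of giant-virus
    endogenizations (GEVEs) in pairs of closely related host strains. Calls viral
    lateral-gene-transfer candidates from ranked homology hits by taxonomic vote,
    classifies cross-strain conservation against a whole-genome alignment, builds
    divergent and viral regions by concatenating contiguous alignment differences,
    profiles epigenetic silencing (CpG methylation, expression, Hi-C compaction),
    and computes genomic-context statistics (sub-telomeric bias, mobile-element
    composition, region-to-region similarity). Ships a two-strain synthetic genome
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    tools,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    rtracklayer
Config/testthat/edition: 3
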