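Package: splicedit
Title: Tagging Differential Splicing Events as RNA-Editing-Dependent or
    -Independent
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processes rMATS differential alternative-splicing tables and
    DEXSeq-style differential exon usage tables against A-to-I RNA-editing
    evidence. Builds fixed-width genomic windows around the splice junctions of
    each event class (SE, MXE, RI, A5SS, A3SS), filters candidate editing sites
    to well-supported addressable A-to-G(I) variants, intersects windows with
    called and database (RADAR/DARNED) editing sites, and tags each splicing
    event as editing-dependent or editing-independent. Also computes
    window-size accumulation curves with non-significant and low-dPSI null
    controls, per-site differential-editing tests, iCLIP footprint overlap
    curves, and ships a synthetic-data generator with planted ground truth so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
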