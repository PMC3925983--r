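Package: dyz1kit
Title: Repeat Profiling, Restriction Mapping and Copy-Number Analysis of
    Y-Chromosomal DYZ1 Satellite Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing ~3.56 kb HaeIII repeat units of the human
    Y-chromosomal DYZ1 satellite. Decomposes an array into TTCCA-anchored
    pentamer units by minimum-edit-cost tiling dynamic programming and
    tabulates the pentamer and its substitution derivatives; scans
    degenerate IUPAC restriction-enzyme recognition motifs, compares
    site-frequency tables between samples and performs in-silico digestion;
    calls insertion/deletion/substitution blocks between two array units
    from an affine-gap global alignment; fits qPCR standard curves over
    plasmid dilution series and quantifies absolute DYZ1 copy number.
    Includes a synthetic DYZ1-array generator (twin pairs with known
    post-twinning edits, dilution-series Ct readouts with ground truth) so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
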