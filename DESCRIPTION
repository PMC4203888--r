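Package: dendrodiv
Title: Cross-Species Dendritic Transcriptome Divergence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying cross-species divergence of neuronal
    dendritic transcriptomes assayed on species-specific microarray
    platforms. Builds reciprocal-best-hit ortholog maps and collapses
    many-to-many probe-set relationships into metagene units, summarizes
    and rescales array intensities, computes differential-expression
    tables with false-discovery-rate control, top-fraction overlap
    statistics, rank-concordance (rankmap) curves with exact binomial
    confidence bands, Li (1993)/Pamilo-Bianchi synonymous and
    non-synonymous substitution rates with Kimura two-parameter
    distances for untranslated regions, and dendrite-to-soma
    fluorescence intensity ratio profiles from traced transects.
    Includes seeded simulators for every input class so the whole
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
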