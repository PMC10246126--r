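Package: svsig
Title: Somatic Structural Variant Signature Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for somatic structural variant (SV) signature analysis in
    tumor whole-genome cohorts. Merges per-caller SV callsets into
    high-confidence consensus junctions, partitions them into clustered-complex,
    non-clustered-complex and simple events, classifies simple SVs into a
    49-subcategory catalog, extracts mutational signatures by non-negative
    matrix factorization with stability-based rank selection, applies
    deterministic final-signature assignment, tests breakpoint enrichment
    against genomic features with matched random SVs and Kolmogorov-Smirnov
    statistics, and computes hotspot, mutation-association, breakpoint-homology
    and survival summaries. Ships a full synthetic-cohort simulator so every
    stage can be exercised and validated without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    survival,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
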