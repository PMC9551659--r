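Package: tmesubtype
Title: Immune Microenvironment Subtyping of Tumor Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and prediction of tumor immune-microenvironment subtypes
    from cell-type abundance profiles. Implements resampling-based (Monti)
    consensus clustering with k-medoids on the 1-Pearson distance, nearest-
    centroid subtype prediction with minimum-correlation and minimum-gap
    quality-control rules for unclassifiable samples, rank-based single-sample
    gene-set enrichment, signature scores for tertiary lymphoid structures
    (TLSscore), the pan-fibroblast TGF-beta response (FTBRS) and a
    follicular-regulatory-T-cell centroid score (TFRscore), an exact
    Freeman-Halton r x c contingency test by enumeration, Kaplan-Meier and
    log-rank survival statistics, and a synthetic-cohort generator that
    emulates the statistical structure these analyses assume, so the whole
    pipeline is testable end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cluster,
    survival,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
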