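Package: ckorgan
Title: Organ-Resolved Cytokinin Transcriptome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for organ-resolved transcriptome profiling of
    the cytokinin response in Arabidopsis seedlings on common-reference
    (single-channel-like) spotted microarrays such as CATMA. Implements
    spots-above-background detection filtering, per-gene two-factor
    (organ x cytokinin) fixed-effects linear models with type-II F-tests and
    Benjamini-Hochberg FDR correction, fold-change based organ-specificity
    categorization (root-specific, shoot-specific, differential, similar,
    uncategorized, not regulated), a "developmental shift" gene-set analysis
    that finds genes moving toward the other organ's expression level under
    cytokinin treatment or deficiency, organ-effect normalization of condition
    means, PCA of condition profiles, and bootstrap support-tree clustering.
    Includes a synthetic-data generator with planted per-gene ground truth
    that emulates the 2 organ x 5 condition x 2 biological x 2 technical
    replicate study design, so that every stage is testable without raw array
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
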