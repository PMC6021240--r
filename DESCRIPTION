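Package: lnchet
Title: Long Noncoding RNA Heterogeneity Screens and Guilt-by-Association
    Function Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens a log2 expression cohort for long noncoding RNAs
    (lncRNAs) that track tumor features (mismatch-repair, CIMP, CIN,
    oncogene mutations, molecular subtypes) with fold-change and FDR
    gates, and for lncRNAs associated with relapse-free survival via
    univariate and multivariate Cox regression with proportional-hazards
    checking. Predicts lncRNA function by guilt-by-association:
    subtype-stratified split-half Pearson correlation ranking, pre-ranked
    gene-set enrichment with gene-set-permutation FWER control,
    both-halves consensus scoring, and an Enrichment Metascore that
    aggregates signed consensus scores over an lncRNA group against a
    random-group permutation null. Also provides microarray probe
    reannotation rules (coverage filtering, duplicate-transcript
    collapsing, max-variance probe selection, strand-specific interval
    overlap, promoter and gene-body cytosine annotation) and
    Infinium-style differential methylation calling on M-values with a
    delta-beta gate. A synthetic-cohort generator with planted ground
    truth supports calibration and recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    yaml
Config/testthat/edition: 3
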