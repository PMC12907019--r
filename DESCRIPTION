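Package: ervconcord
Title: Concordance Analysis of Endogenous Retrovirus Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing locus-resolved annotations of human
    endogenous retroviruses (HERVs) and other LTR retroelements across
    annotation sources. Reads BED-like, RepeatMasker .out and
    HERVd-style tables into a common 0-based half-open representation,
    assigns records to ERV superfamilies via a family mapping table,
    scores cross-source interval overlaps with the segment overlap
    statistic Sov together with a fragmentation-tolerant secondary
    matching criterion, and produces pairwise and three-way
    matched/shared/unique decompositions plus descriptive statistics
    (genome coverage, length histograms, destruction-degree summaries).
    Includes a synthetic annotation generator with planted ground truth
    for validating the matching procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
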