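Package: p53screen
Title: Dual Transcriptome Screening for p53 Target Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable implementation of a two-stage transcriptome screen for
    p53 target genes: a cell-line screen contrasting p53 wild-type cells after
    DNA damage against untreated and p53-null controls (median/maximum fold
    statistic with an F-test-gated two-sided t-test), a tumor-cohort screen
    contrasting p53 wild-type against p53 mutant tumors, intersection of the
    two hit lists with a Bonferroni gate keyed to the first screen's size,
    chi-squared gene-set over-representation, degenerate-consensus scanning
    for p53 response elements (paired RRRCWWGYYY half-sites with a variable
    spacer), and median-split Kaplan-Meier and log-rank survival
    stratification. Includes a synthetic-data generator that emulates the
    cell-line design, the tumor cohort and genomic sequences with planted
    binding sites, so the whole pipeline runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    survival,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
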