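Package: ciliascreen
Title: Age-Trend Screening of Cilia Gene Expression Across Brain Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens a curated panel of cilia genes for linear age trends in
    expression across human brain regions. Fits per-gene, per-region ordinary
    least squares regressions of expression on age in years, applies
    Benjamini-Hochberg false discovery rate control, and calls differentially
    expressed genes with age (DEGAs) with direction. Downstream tools compute
    co-expression correlation matrices with a clustering-derived display
    order, cross-region overlap matrices and bipartite gene-region networks,
    sub-structural compartment summaries, and analytic and Monte Carlo power
    for the slope test. Includes a reader/writer for the BrainSpan
    developmental-transcriptome CSV dialect and a simulator that generates
    BrainSpan-shaped datasets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
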