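Package: methexpr
Title: Integrative Linear Modeling of Gene Expression and DNA Methylation
    Microarray Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates probeset-level gene expression (RMA-style log
    abundance) with probe-level DNA methylation (two-colour M-values) for
    panels of cell lines. Fits a covariate-adjusted linear model to every
    probeset-probe pair of every gene (adjusting for estrogen-receptor
    status and tumour subtype), summarizes pair-level methylation
    coefficients into gene-level significance calls with separate rules for
    long and short genes, classifies probes as hyper- or hypomethylated by
    one-sample t-tests, and identifies hub genes by degree in an imported
    interaction network. Includes a synthetic-data generator with known
    ground truth so every stage of the pipeline can be validated without
    access to the original microarray data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
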