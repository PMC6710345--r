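Package: resistrisk
Title: Heavy-Metal Ecological Risk and Soil Resistome Co-Occurrence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing heavy-metal contamination and bacterial
    resistance genes along polluted soil gradients. Implements Hakanson
    potential-ecological-risk scoring (contamination factors, monomial risk
    factors, integrated risk index and per-metal contributions), processing
    of qPCR gene panels into 16S rRNA-normalized relative abundances,
    site-difference statistics (one-way ANOVA, Duncan's multiple range test
    with compact letter displays, Spearman correlation matrices), and
    Spearman-thresholded co-occurrence network inference with modularity-based
    module detection and per-module hub identification. A synthetic-data
    generator with a Gaussian copula and lognormal marginals provides
    site-structured datasets with planted correlation blocks for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
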