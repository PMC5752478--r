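Package: triomix
Title: Integrated Tri-Omics Analysis of miRNA, Protein and Metabolite Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Reusable pipeline for integrating microRNA, protein and
    metabolite abundance profiles from a treatment-versus-model cell study:
    univariate differential expression (Welch t, optional Benjamini-Hochberg
    adjustment), OPLS-DA with VIP-based metabolite selection, hypergeometric
    pathway over-representation with betweenness-centrality impact scores,
    cross-layer Pearson correlation networks with hub-miRNA ranking, and
    extracellular-flux (mito stress test) and 2^-ddCt assay arithmetic.
    Includes a synthetic tri-omics generator with planted differential
    features and latent-factor correlation blocks for ground-truth recovery
    testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    limma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
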