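Package: gcoex
Title: Gene Co-Expression Networks via Entropy Filtering and
    Population-Normalized Correlation Significance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs gene co-expression networks from a gene-by-sample
    expression matrix. Genes with little differential expression are removed
    by a Shannon-entropy filter, all pairwise Pearson correlation
    coefficients are computed with a blocked matrix-product engine into
    packed strictly-lower-triangular storage, coefficients are standardized
    against the whole coefficient population to approximate standard-normal
    test statistics, edges are called under Benjamini-Hochberg false
    discovery rate control, zero-connectivity genes are pruned, and modules
    are identified by average-linkage clustering of a topological-overlap
    similarity matrix. Includes a latent-factor synthetic-data generator
    with planted modules for end-to-end validation, tidy accessors for all
    tabular results, ggplot2 diagnostics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mclust,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
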