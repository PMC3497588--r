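Package: hgf
Title: Literature-Based Hypothesis Generation with Ontology-Mapped
    Latent Semantic Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for literature-based discovery of disease-factor
    associations. Builds a domain-specific single-word dictionary from
    Medical Subject Headings (MeSH), assembles per-factor document
    collections from MEDLINE-format citation files, constructs a weighted
    term-document matrix and its truncated singular value decomposition
    (a latent semantic knowledge space), and ranks candidate factors by
    cosine similarity to a free-text query. The resulting score
    distribution is modelled as a tri-modal Gaussian curve whose fitted
    parameters yield data-driven thresholds separating established,
    potential, and unknown associations; categorised factor sets from
    multiple queries can be assembled into disease-disease interaction
    networks. A synthetic-data generator (planted-topic corpora,
    MeSH-like heading fixtures, tri-modal score samplers) supports fully
    offline testing and benchmarking of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    minpack.lm,
    optparse,
    stats,
    stringi,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
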