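Package: lriNet
Title: Game-Theoretic Link Relevance Indexing of Gene Co-Expression
    Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Scores genes in case/control expression studies by the Link
    Relevance Index (LRI), the position value of a cooperative game played
    on the links of a gene co-expression network. Provides S4 containers
    for microarray experiment situations (built on SummarizedExperiment),
    co-expression networks and network games; three independent LRI
    implementations (closed form, star-sum form, and an exact brute-force
    Shapley oracle) in exact rational arithmetic; configurable network
    construction from expression matrices; a Welch-test differential
    expression arm with Benjamini-Hochberg correction; salient-gene
    selection, gene-set overlap and right-sided hypergeometric enrichment
    against GMT collections; and a seeded latent-factor simulator with
    planted co-expression modules and expression shifts for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'rational.R'
    'AllGenerics.R'
    'AllClasses.R'
    'network.R'
    'game.R'
    'lri.R'
    'shapley.R'
    'axioms.R'
    'mes.R'
    'build.R'
    'deg.R'
    'genesets.R'
    'enrich.R'
    'salient.R'
    'simulate.R'
    'recovery.R'
    'io.R'
    'pipeline.R'
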