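Package: MotifLandscape
Title: Subclustering Co-Expressed Genes by Upstream Motif Content and Position
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Splits a set of co-expressed genes into functionally coherent
    subsets using only their upstream DNA sequences. Statistically
    significant motifs (exact, degenerate IUPAC and gapped/bipartite
    consensi, scored by a Bonferroni-corrected exact binomial tail) are
    discovered in fixed-length promoter windows, their occurrences are
    binned into positional quartiles to form gene-motif count vectors, and
    genes are clustered by a force-directed landscape procedure that
    extracts density peaks without a preset number of clusters. Each
    subset is then characterised by motif re-discovery, hypergeometric
    functional-category enrichment against the parent set, and alignment
    of discovered consensi to a database of known binding-site matrices
    with an empirical shuffle-null E-value. A seeded synthetic-fixture
    generator (Markov background, planted motifs with controlled
    per-quartile placement) supports benchmarking of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
biocViews: MotifDiscovery, Clustering, GeneRegulation, Transcription,
    SequenceMatching
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
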