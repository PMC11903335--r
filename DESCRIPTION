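Package: multimeralign
Title: Protein Complex Alignment by Superposition-Vector Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns protein complexes chain-to-chain and derives the
    complex-to-complex alignment by clustering the rigid superpositions of
    individual chain alignments. Each chain-to-chain alignment is summarised
    as a 12-component superposition vector (9 rotation entries, 3
    translations); compatible sets of chain alignments share one superposition
    and are found by iterative DBSCAN over these vectors with
    cluster-validity checking and nearest-neighbour rescue. The best valid
    chain assignment is scored with a complex TM-score over the matched
    chains concatenated in pairing order. Includes pairwise alignment,
    many-vs-many database search, clustered-database expansion, a synthetic
    multi-chain fixture generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
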