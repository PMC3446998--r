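Package: pprank
Title: Directional PageRank Ranking of Signal-Flow Protein Interaction Networks
Version: 1.0.0
Authors@R:
    person("pprank", "developers", email = "pprank@example.org",
           role = c("aut", "cre"))
Description: Ranks proteins in a signal-directional protein-protein
    interaction network by forward PageRank (information receivers),
    reverse PageRank (information emitters/regulators) and non-directional
    PageRank (interaction count), starting from edge tables scored with
    protein interaction directional scores (PIDS). Provides the downstream
    comparison battery used to characterise such rankings: Pearson/Spearman
    correlations between ranking methods, top-k overlaps, top-vs-bottom
    fold ratios, evolutionary-conservation group summaries with one-way
    ANOVA and Duncan's multiple-range test, subcellular-location cross-tabs
    with ratio chi-square tests, a Monte-Carlo random-surfer oracle for the
    underlying Markov chain, and a seeded synthetic-network generator with
    planted emitters for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
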