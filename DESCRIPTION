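Package: pocrank
Title: Pareto Optimal Consensus Ranking of Protein Structure Decoys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Consensus ranking of protein structure decoys (loop models in
    particular) by integrating multiple scoring functions without weights or
    training. Identifies the Pareto-optimal front of the scoring-function
    space, ranks models by fuzzy dominance degrees built from bounded
    per-function score ratios, and stratifies the whole decoy set by iterative
    front peeling. Includes the classical consensus baselines (rank-by-number,
    rank-by-rank, rank-by-vote, single-function), evaluation machinery against
    RMSD ground truth (near-native false-positive summaries, Pareto-front
    coverage, ranked-data ROC/AUC, best-of-top-k RMSD), a seeded synthetic
    decoy-set generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
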