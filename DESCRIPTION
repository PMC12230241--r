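Package: sdlscreen
Title: Synthetic Dosage Lethality Screen Scoring and Candidate Prioritization
Version: 0.1.0
Authors@R: person("SDL", "Screen Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Scores two-arm (induced versus uninduced) pooled shRNA dropout
    screens with the weighted differential cumulative change (WDC) fitness
    statistic, calls synthetic-dosage-lethality (SDL) hits with permutation
    and t tests, and carries the hits through secondary CRISPR screen scoring
    (pooled in vivo sgRNA counting and arrayed confluency screens),
    co-expression / essentiality / survival / drug-response prioritization,
    single-cell CRISPR (Perturb-seq) knockout triage, and downstream tumor
    growth-kinetics, motif and mitochondrial-respiration analyses. Ships a
    synthetic-data generator with recorded ground truth so every stage is
    testable without external data, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    survival,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
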