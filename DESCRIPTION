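Package: ordbench
Title: Benchmarking Structured Reaction Extraction Against ORD-Style Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for building and scoring text-to-structure benchmarks for
    organic reaction data. Prepares prompt/completion corpora from procedure
    paragraphs paired with Open Reaction Database (ORD) style JSON records,
    applying admission rules, implicit-information scrubbing, deduplication,
    token-length filtering and train/validation/test splitting. Scores
    extracted records against ground truth with a nested-object edit distance
    and optimal bipartite matching, reporting Accurate/Removal/Addition/
    Alteration tallies at both the message and the leaf-field level, with a
    lenient equivalence routine for compounds. Also includes heuristic JSON
    repair for malformed model completions, compound-name recognition scoring,
    reaction-role classification evaluation with a popularity baseline, and a
    seeded synthetic fixture generator with a logged perturbation engine so
    every metric has a known-answer oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
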