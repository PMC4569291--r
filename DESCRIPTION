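Package: lookahead
Title: Bounded-Depth Planning and Strategy Inference on Branching Reward Lattices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying multi-step decision making on triangular lattices of
    valued disks. Provides tie-preserving optimal path search (brute force and dynamic
    programming), ideal planners parameterized by depth of computation and recalculation
    period, workload models for both search algorithms, a Metropolis annealer that designs
    maximally diagnostic stimuli by minimizing strategy redundancy, exhaustive enumeration
    and exact expected-score evaluation of per-row depth policies, synthetic actor cohorts
    (fixed-strategy, random-depth, sigmoid-choice, and value-reweighting heuristics),
    strategy-inference statistics (score advantage with zero-crossing depth estimation,
    path-overlap voting and normalized evidence, unique-overlap depths, heuristic
    reweighting analysis), and export of the task as a partially observable Markov
    decision process in the pomdp.org file format.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
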