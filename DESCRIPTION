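Package: songddm
Title: Drift-Diffusion Analysis of Grasshopper Song Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models mate-choice decisions of female grasshoppers
    (Chorthippus biguttulus) listening to artificial calling-song models.
    Songs are sequences of subunits (syllable plus pause building blocks);
    each subunit type contributes a signed weight to a noisy evidence
    integrator bounded by two absorbing decision thresholds.  The package
    builds the song-model stimulus sets, computes response probabilities by
    Monte-Carlo simulation and by exact density propagation, fits subunit
    weights and integrator parameters to behavioral response rates with a
    genetic algorithm under leave-one-out cross-validation, generates
    synthetic behavioral cohorts for parameter-recovery studies, and derives
    decision-dynamics summaries (first-passage profiles, mean clamped
    evidence trajectories, weight and noise-to-signal ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
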