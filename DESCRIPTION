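Package: neurotrait
Title: Resting-State EEG Neural Traits of Risk-Taking and Strategic
    Consistency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline linking resting-state EEG band-power maps to
    individual differences in risky decision-making. Scores the Balloon
    Analogue Risk Task (risk-taking index and coefficient of variability),
    extracts band power from cleaned resting EEG (2-s Hamming-windowed
    epochs with 75 percent overlap, seven canonical bands, artifact
    rejection, density normalization), performs mass-univariate
    voxel-by-voxel correlation mapping with max-statistic permutation
    correction for the family-wise error rate, extracts contiguous
    supra-threshold clusters and spherical regions of interest, partitions
    regression variance between two behavioural predictors by commonality
    analysis, and fits single-mediator models (personality to neural trait
    to behaviour) with percentile-bootstrap confidence intervals. Includes
    a synthetic cohort generator with planted effect clusters and a
    mediation chain so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
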