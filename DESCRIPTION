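Package: epiturn
Title: Epidermal Basal-Layer Turnover, Differentiation Trajectories and
    Neighbour Fate-Imbalance Analysis
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying gradual differentiation in the epidermal
    stem cell layer. Implements basal-layer event simulation with
    delamination-triggered divisions, synthetic 3D timelapse generation,
    height correction and drift registration of intravital stacks, the
    cumulative neighbour fate-imbalance statistic preceding divisions,
    a single-cell differentiation-trajectory pipeline (size-factor
    normalization, covariate regression, MAGIC-style imputation,
    diffusion pseudotime, delamination-point assignment, pseudotime
    binning, spliced/unspliced co-expression), transcription-factor
    module expansion and scoring, and nested cubic-model ANOVA for
    genotype trend comparison. All stages are exercisable on synthetic
    data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    FNN,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
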