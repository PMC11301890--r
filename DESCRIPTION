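Package: bigjoint
Title: Scalable Bayesian Joint Models for Longitudinal and Survival Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits Bayesian joint models linking a Gaussian linear
    mixed-effects biomarker trajectory to a proportional-hazards survival
    submodel with a B-spline log baseline hazard, using a
    Metropolis-within-Gibbs sampler. Large cohorts are handled by a
    divide-and-conquer strategy: subjects are partitioned into chunks,
    each chunk is fitted separately, and chunk-level posterior summaries
    are pooled (simple mean/standard-error combination or
    precision-weighted). Includes a synthetic-data generator with known
    ground truth, subject-level dynamic predictions (conditional survival
    probabilities and biomarker trajectories given accrued history), and
    time-dependent predictive-performance measures (Harrell-type
    concordance over time and the inverse-probability-of-censoring
    weighted Brier score).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    pracma,
    splines,
    stats,
    survival,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
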