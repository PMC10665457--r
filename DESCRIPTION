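Package: streakdecode
Title: Bimodal Posterior Representations of Motion Direction from Velocity and
    Orientation Cues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how motion direction can be represented as a
    bimodal probability distribution when fast motion leaves oriented "streaks"
    in the visual input. Implements a Bayesian observer that combines a
    velocity cue (360-degree space) with a spatial-orientation cue (180-degree
    space, hence direction-ambiguous), seeded Monte-Carlo simulation of the
    observer's posterior distributions and behavioral readouts, a
    generative-model probabilistic decoder for voxel activity patterns with
    shrinkage-regularized noise covariance, bagging and leave-one-run-out
    cross-validation, descriptive von Mises mixture fits to posterior shape by
    Jensen-Shannon divergence minimization, bivariate peak-location clustering
    compared by WAIC, and unimodal-versus-bimodal behavioral response model
    comparison by BIC. Includes synthetic-data generators for voxel and
    behavioral datasets drawn from the models' own assumptions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    MASS
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
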