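Package: kittengrowth
Title: Growth Standards, Neutering Trajectories and Body-Composition
    Modelling for Kittens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying bodyweight growth of domestic shorthair
    kittens relative to sex-specific growth standards, and the effect of
    neutering on growth and body composition. Implements the Box-Cox
    Cole-Green (BCCG/LMS) distribution with penalized-likelihood fitting of
    smooth L/M/S curves against power-transformed age, centile extraction
    and z-scoring; a longitudinal clinical-record cleaning cascade
    (eligibility filters, pound-rounding detection, extreme and population
    outlier removal, within-animal plausibility cleaning); neuter-group
    trajectory analysis on the z-score scale with a pre/post-neutering
    linear model and single-step (Tukey-type) multiplicity adjustment; and
    a Bayesian multivariate mixed model for littermate-trial morphometrics
    with litter- and cat-level correlated random effects, missing-value
    imputation, fold-change-ratio contrasts and simultaneous (sup-t)
    credible intervals. A synthetic-data module generates clinic-style and
    trial-style datasets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    splines,
    tools,
    jsonlite,
    multcomp,
    mvtnorm,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
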