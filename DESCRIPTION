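Package: gsnadr
Title: Generative Stochastic Networks for Genotype to Adverse Drug
    Reaction Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying the association between diploid CYP2D6
    and CYP1A2 genotypes and graded adverse drug reaction (ADR)
    outcomes with a generative stochastic network (GSN): a stacked
    denoising auto-encoder whose corrupt-reconstruct cycle defines the
    transition operator of a Markov chain, trained by walkback/Gibbs
    resampling and queried by clamped conditional sampling.  Includes
    dummy-variable genotype encoding, ordinal ADR coding, LASSO and
    k-nearest-neighbour multi-target baselines, the average
    accuracy-loss statistic, train/test ratio and Gaussian-noise
    robustness protocols, and a synthetic cohort generator with
    configurable planted genotype-to-ADR effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
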