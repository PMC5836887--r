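Package: latentmol
Title: Generative Autoencoders and Latent-Space Bayesian Optimization for De Novo Molecular Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps molecules given as SMILES strings into a continuous latent
    space with generative autoencoders (variational autoencoders with and
    without teacher forcing, and adversarial autoencoders matching a Gaussian
    or Uniform prior), decodes latent points back into molecules by repeated
    sampling with consensus selection, quantifies latent-space smoothness with
    a distance-binned similarity probe, and searches the latent space by
    Gaussian-process Bayesian optimization against a fingerprint-based QSAR
    activity score. Networks are trained by backpropagation implemented in
    base R matrix code; chemistry (canonicalization, validity, ECFP6
    fingerprints, ring perception) is delegated to OpenBabel via ChemmineOB
    and ChemmineR.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    e1071,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
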