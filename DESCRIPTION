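Package: countgp
Title: Gaussian Process Regression for Temporal and Spatial Counts Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gaussian process (GP) regression for gene-expression counts
    measured over time, pseudotime or 2-D spatial coordinates. Models the
    latent log-mean of a negative binomial (or zero-inflated negative
    binomial, Poisson, Gaussian) observation model with a GP prior and fits
    hyper-parameters by maximising a variational lower bound on the marginal
    likelihood. Provides one-sample and two-sample likelihood-ratio tests for
    differential expression with chi-squared or permutation p-values and
    Storey q-value FDR control, a spatially-variable-gene pipeline with
    negative-binomial scale normalisation, branching-point posterior
    inference for diverging lineages, sparse variational inference with
    inducing-point selection, and synthetic-data generators for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    Matrix,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
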