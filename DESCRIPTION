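Package: hic4d
Title: Maximum-Likelihood 4D Chromosome Modeling from Time-Series Hi-C
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs smooth four-dimensional (3D + time) models of
    individual chromosomes from time-series Hi-C contact maps. Contact
    frequencies are converted to spatial restraints through an inverse
    power law, a profiled Gaussian likelihood couples every discrete time
    frame to its temporally adjacent restraint sets, and full-batch
    gradient descent with a frame-to-frame smoothness penalty yields a
    single consensus trajectory. Fitted models reconstruct and interpolate
    contact maps at arbitrary time points and feed standard downstream
    Hi-C analyses: A/B compartment calling via observed/expected
    correlation PCA, directionality-index TAD detection with a Gaussian
    hidden Markov model, and structure comparison by Procrustes disparity
    and distance-vector correlation. A synthetic generator of toy looping
    trajectories supports end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite
Config/testthat/edition: 3
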