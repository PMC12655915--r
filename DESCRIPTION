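Package: cirl
Title: Confounder-Invariant Representation Learning for Electronic-Nose Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Disentangled adversarial autoencoders for multichannel
    chemiresistive (electronic-nose) sensor recordings. The model splits the
    latent code of a 1D convolutional autoencoder into a task-relevant
    subspace and a confounder subspace and uses a gradient-reversal adversary
    to purge relative-humidity information from the task subspace, so that
    downstream volatile-organic-compound classifiers generalize across
    humidity conditions. Includes the standard preprocessing pipeline
    (ambient normalization, truncation, zero-padding with masks, class
    weighting), a matched single-latent baseline, a stratified
    cross-validation and probe-based disentanglement evaluation harness, and
    a synthetic gas-sensor response simulator with a controllable
    class-correlated humidity confounder.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    pROC
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
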