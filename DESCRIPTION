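Package: spfn
Title: Siamese Pyramid Fusion of Registered PET and CT Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end fusion of registered PET and CT lung image slices with a
    siamese pyramid fusion network: shared-weight encoders built from a convolutional
    stem, a channel-coupling (channel attention) gate and a spatial-pyramid coupling
    block; a parameter-free cross-correlation fusion layer; and a deconvolutional
    decoder trained self-supervised with a structural-similarity objective plus L1
    weight regularization under AdaGrad. Includes a seven-statistic fusion quality
    suite (mean, standard deviation, average gradient, entropy, RMSE, normalized
    mutual information, visual information fidelity), a synthetic thorax phantom
    generator producing registered CT-like/PET-like pairs with known lesion geometry,
    preprocessing (resampling, min-max normalization, standard image formats), a
    cross-validated training loop, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    RNifti,
    withr,
    yaml
Config/testthat/edition: 3
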