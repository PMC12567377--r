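Package: mmhafnn
Title: Multimodal EEG and Facial-Expression Emotion Recognition with
    Multi-Head Attention Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a multimodal multi-head attention fusion network
    (MMHA-FNN) for four-class emotion recognition (happy, sad, fear, calm)
    from 62-channel EEG and paired facial-expression frames. Provides
    differential-entropy feature extraction over the five canonical EEG
    bands, rasterization of per-band electrode values into topographic
    maps by quadrant-wise bilinear interpolation, an MBConv/squeeze-
    excitation EEG encoder, a bottleneck-residual facial encoder, a
    Transformer fusion classifier with attention attribution, clip-wise
    and leave-one-subject-out evaluation protocols, and a synthetic
    multimodal dataset generator with analytically known class signatures
    so that every stage is testable without access to restricted
    recordings. All network layers, backpropagation and optimization are
    implemented in R on top of BLAS matrix products.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
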