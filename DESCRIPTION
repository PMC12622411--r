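Package: facevalence
Title: Valence Decoding from Mouse Facial Expressions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a prototype-based framework for
    decoding emotional valence from side-view videos of the mouse face.
    Provides histogram-of-oriented-gradients (HOG) frame descriptors with
    cosine-similarity scoring against positive and negative expression
    prototypes, landmark-based cross-animal coregistration, a ten-feature
    facial-geometry battery computed from 37 tracked keypoints, compact
    learned decoders (a residual frame classifier, a Siamese contrastive
    embedding, gradient-weighted class-activation maps, occlusion
    sensitivity, and an LSTM trajectory decoder), and dual-channel fiber
    photometry processing (asymmetric penalized-least-squares baseline
    removal, isosbestic motion correction, dF/F, peristimulus averages, and
    permutation-tested neural-facial correlations). A synthetic-cohort
    generator renders schematic mouse faces with controllable
    valence-dependent geometry so that the whole pipeline is testable
    without any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    EBImage,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
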