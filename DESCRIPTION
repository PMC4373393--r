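Package: occrobust
Title: Occlusion Robustness of Competitive Population Codes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Compares four models of primary visual cortex coding --
    FastICA, non-negative matrix factorization with a sparseness
    constraint (NMFSC), predictive coding/biased competition (PC/BC),
    and a Hebbian network with learned lateral inhibition (HNN) -- for
    the robustness of their population codes against random pixel
    occlusion. Provides IDX digit-image input, a synthetic digit
    generator, retina/LGN-style preprocessing (downscaling, spectral
    whitening, on/off channel splitting), per-model training and
    encoding, linear-discriminant classification of the codes, and
    code-stability metrics (accuracy under occlusion, cosine
    stability, Hoyer sparseness, reverse-correlation receptive
    fields, lateral-inhibition selectivity).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
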