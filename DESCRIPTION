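Package: focusfield
Title: Defocus-Blur Segmentation with Local Ternary Patterns and a
    Pulse-Coupled Neural Network
Version: 0.1.0
Authors@R:
    person("Focusfield", "Developers", email = "focusfield@example.org",
           role = c("aut", "cre"))
Description: Segments the in-focus region of partially defocused images
    (low depth-of-field photographs, microscopy fields) by combining a
    local-ternary-pattern (LTP) sharpness map with an adaptively
    parameterized pulse-coupled neural network (PCNN). Includes the full
    segmentation-evaluation metric suite (precision, recall, accuracy,
    weighted F-measure, Matthews correlation, Jaccard, Dice, specificity),
    an EDAS multi-criteria ranking module for comparing segmentation
    methods, a seeded synthetic-fixture generator for partially blurred
    images with ground-truth masks, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
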