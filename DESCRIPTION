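Package: abfp
Title: Attention Balanced Feature Pyramid for Low-Contrast Lesion Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the attention balanced feature pyramid (ABFP) detection
    neck for low-contrast lesion detection in CT slices: multi-level feature
    pyramids are rescaled to a common intermediate resolution and averaged into
    a balanced semantic map, which is refined by parallel channel and spatial
    attention gates and added back to every level. Ships a baseline top-down
    feature pyramid network, a COCO-style average-precision/average-recall
    evaluator, a deterministic generator of synthetic CT-like slices with
    low-contrast elliptical lesions, and a deliberately small anchor-based
    single-stage detector (with analytic gradients and an SGD training loop)
    that exercises the neck end-to-end on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
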