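Package: stainsan
Title: Stain Domain Adaptation for H&E Histopathology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for adapting the stain color domain of hematoxylin-and-eosin
    (H&E) histopathology image batches. Implements Stain SAN, which
    simultaneously augments training images and normalizes test images by
    resampling per-image stain color matrices from an energy-preserving
    spherical Gaussian target distribution, together with classical stain
    normalization, stain augmentation and stain mix-up as special cases of the
    same framework. Includes Beer-Lambert optical-density conversion,
    SVD-based stain matrix extraction, a packaged reference stain
    distribution, a synthetic two-domain phantom generator for validation,
    and a command-line interface for fit / apply / synth workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
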