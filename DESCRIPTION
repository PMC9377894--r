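Package: crcd
Title: Confidence-Region Contour Detection for Brain-Tumour MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts brain-tumour regions from greyscale MRI slice stacks by
    confidence-region contour detection: linear intensity-window adjustment,
    connected-component biggest-blob selection per slice, fusion of per-pattern
    blobs into a resultant blob with an RGB provenance overlay and a pixel-count
    confidence score, region-scalable-fitting (RSF) level-set refinement of the
    tumour boundary, and a confidence-interval transform (quadrant means with a
    +/- 1.96 sigma band, optional Haar smoothing, multi-level Otsu) that turns
    the score image into the final confidence-region mask. Includes Dice,
    Jaccard, MSE and PSNR evaluation, NIfTI and PNG/TIFF input-output, and a
    seeded synthetic phantom generator for validation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    png,
    tiff,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
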