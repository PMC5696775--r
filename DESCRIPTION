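Package: canopyseg
Title: Vegetation Segmentation of Canopy Images with Multi-Colour-Space
    Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pixel-wise segmentation of green vegetation in nadir RGB
    canopy photographs for fractional vegetation cover (FVC) estimation.
    Implements a multi-feature learning (MFL) segmenter: every pixel is
    described by a 21-element feature vector spanning seven colour
    representations (RGB, CIE L*a*b*, CIE L*u*v*, HSV, HSI, YCbCr, YUV),
    a two-class random-forest classifier is trained on small labelled
    image patches, and the predicted binary mask is cleaned with a
    median (majority) filter. Also provides the classical colour-index
    baselines ExG, ExGR and CIVE with Otsu or positive thresholding, a
    K-means baseline in L*u*v* space, the Qseg/Sr/Es segmentation
    accuracy metrics, FVC time-series summaries, and a seeded synthetic
    canopy-scene generator with exact ground truth for benchmarking
    under shadows, specular highlights and colour-temperature shifts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ranger,
    png,
    tiff,
    jpeg,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
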