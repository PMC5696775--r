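# canopyseg

Pixel-wise segmentation of green vegetation in nadir RGB canopy
photographs, for estimating fractional vegetation cover (FVC) in
high-throughput field phenotyping. The package implements a
**multi-feature learning (MFL)** segmenter — a supervised pixel classifier
over features from seven colour representations — together with the
classical colour-index baselines it is usually compared against, the
standard segmentation accuracy metrics, and a seeded synthetic
canopy-scene generator with exact ground truth so that every method is
benchmarkable without field imagery.

## The methods

**MFL segmenter.** Every pixel is described by a 21-element feature vector

```
F = (R, G, B,  L*, a*, b*,  L*, u*, v*,  H, S, V,  H, S, I,  Y, Cb, Cr,  Y, U, V)
```

spanning RGB, CIE L\*a\*b\*, CIE L\*u\*v\*, HSV, HSI, YCbCr and YUV. A
two-class probability random forest is trained on small labelled image
patches (plant = +1, background = 0), each resized to 20 × 20 pixels, so a
patch contributes 400 feature rows with its label. At prediction time the
per-tree class distributions are aggregated into a plant probability per
pixel, thresholded at 0.5, and the binary mask is cleaned with a 7-pixel
median (majority) filter. Redundancy across colour spaces is what buys
robustness to shadows, specular highlights and daylight colour-temperature
drift.

**Baselines.** The colour-index methods

- ExG = 2G − R − B, thresholded automatically by Otsu's method;
- ExGR = ExG − (1.4R − G), thresholded at a fixed positive threshold (> 0);
- CIVE = 0.441R − 0.811G + 0.385B + 18.78745, Otsu-thresholded (vegetation
  falls **below** the threshold: the green coefficient is negative);

and K-means clustering (k = 20) of the per-pixel (L\*, u\*, v\*) values,
where a cluster is vegetation iff its centre satisfies u\* < 0 and
v\* > 0.

**Evaluation.** Against a reference mask R, a segmentation S is scored by

- Qseg = |S ∩ R| / |S ∪ R| (intersection over union; 1 is perfect),
- Sr = |S ∩ R| / |R| (plant-region consistency),
- Es = |S ∩ !R| / |R| (misclassified plant pixels; 0 is perfect),

plus FVC = plant pixels / total pixels and day-course stability summaries
(mean, SD, CV%).

## Worked example

```r
library(canopyseg)

## a 128x128 synthetic canopy scene with shadows and specular highlights
scene <- generate_scene(scene_params(seed = 42))
scene
#> Synthetic canopy scene: 128x128 px, cover 0.252 (target 0.30), seed 42

## train the MFL classifier on synthetic patches
patches <- generate_patch_dataset(scene_params(seed = 0),
                                  n_positive = 200, n_negative = 120)
model <- mfl(patches, trees = 100, seed = 0)
model
#> Multi-feature learning (MFL) vegetation segmenter
#>   forest: 100 trees, mtry 4, seed 0
#>   trained on 200 plant + 120 background patches (20x20)
#>   pixel rows: 80000 plant, 48000 background, 21 features

## segment and evaluate against the exact ground truth
mask <- segment_mfl(model, scene$image)
evaluate_masks(mask, scene$truth)
#> Segmentation scores: Qseg = 0.9593, Sr = 0.9758, Es = 0.0172
fvc(mask)                                # estimated cover: 0.251
evaluate_masks(segment_exg(scene$image), scene$truth)
#> Segmentation scores: Qseg = 0.8251, Sr = 0.8478, Es = 0.0276
```

The MFL mask recovers 96% of the union with the truth and estimates the
cover to within 0.001, while ExG+Otsu loses shadowed foliage (lower Sr)
and picks up greenish soil residue (higher Es).

A command-line front end covering training, segmentation, evaluation,
batch FVC and scene synthesis is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "canopyseg", package = "canopyseg"))') help
```

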