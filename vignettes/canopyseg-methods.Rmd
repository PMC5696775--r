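---
title: "Multi-feature vegetation segmentation: models, conventions and design notes"
author: "canopyseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-feature vegetation segmentation: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Fractional vegetation cover (FVC) — the proportion of image pixels that
are green vegetation in a fixed nadir view — is a standard canopy trait in
field phenotyping. Estimating it from RGB photographs reduces to a
two-class pixel segmentation problem that is easy in a greenhouse and hard
in the field: daylight colour temperature drifts over the day, canopies
cast shadows on themselves and on the soil, leaves produce specular
highlights that saturate all three channels, and soils carry greenish
moss and crop residue. Single colour indices (ExG, ExGR, CIVE) project a
pixel onto one axis and inevitably confound some of these effects; the
multi-feature learning (MFL) segmenter in this package instead hands a
classifier 21 redundant colour coordinates and lets it carve the boundary.

# The MFL model

A pixel is represented by the 21-vector of its RGB values and its
coordinates in L\*a\*b\*, L\*u\*v\*, HSV, HSI, YCbCr and YUV
(`extract_features()`, column order fixed by `mfl_feature_names()`).
Training data are small image patches labelled plant (+1) or background
(0); each patch is resized to `patch_size` × `patch_size` (default 20,
bilinear) and contributes one labelled feature row per pixel, so
`n` patches yield `400 n` rows. A probability random forest
(`ranger`, default 100 trees, `mtry = 4` ≈ √21, unlimited depth, no class
weighting) is fitted on these rows; `predict()` aggregates the per-tree
class distributions into a plant probability per pixel and labels plant
where it strictly exceeds `prob_threshold` (default 0.5). The mask is then
denoised with a median filter of window 7 (`denoise_mask()`); for a binary
mask the median is the majority class of the window. `segment_mfl()` runs
the whole pipeline.

Assumptions worth stating: the model is purely chromatic — one pixel, one
decision, no texture or neighbourhood context (the median filter is the
only spatial operation); class imbalance in the patch library is left
as-is; and the classifier can only be as diverse as its patch library, so
patches must span the illumination conditions it will meet (see the
generator section — this matters).

## Tunable parameters

| parameter | default | units | notes |
|---|---|---|---|
| `patch_size` | 20 | px | patch side after resize; 400 rows per patch |
| `trees` | 100 | — | forest size; accuracy saturates well before this on separable patch libraries |
| `mtry` | 4 | — | features per split, ≈ √21 |
| `prob_threshold` | 0.5 | — | strict inequality, so 1.0 yields all background |
| `window` | 7 | px | median filter; must be odd |
| `seed` | 0 | — | forest and sampling seed; fits are bit-reproducible with `num_threads = 1` |
| `k` (K-means) | 20 | — | cluster count in L\*u\*v\* |

# Colour conventions

The conversions are fixed so independent implementations can agree:

* All transforms act **directly on the stored [0,1] values** with no sRGB
  linearization step, matching how camera output is normally fed to
  vegetation indices. Changing this would change every feature except
  R, G, B themselves.
* L\*a\*b\* and L\*u\*v\* use the sRGB→XYZ matrix with D65 white. The
  reference white is taken as the matrix row sums so that R = G = B maps
  to exactly zero chroma.
* Hues (HSV hexcone; HSI arccos form) are scaled to [0, 1); achromatic
  pixels get hue 0 and saturation 0 by convention. Hue circularity is not
  re-encoded (no sin/cos split): hue enters the forest as a plain scalar.
* HSI, rarely provided by libraries, is the classical definition:
  I = (R+G+B)/3, S = 1 − 3·min(R,G,B)/(R+G+B) (0 when the sum is 0), and
  the arccos hue with H → 2π − H when B > G.
* YCbCr and YUV share BT.601 luma but keep their distinct standard chroma
  scalings (full-range Cb/Cr offset at 0.5; analog U = 0.492(B−Y),
  V = 0.877(R−Y)), so columns 16–18 and 19–21 are genuinely different
  features.
* The L\* column appears twice (once with each CIE space). The feature
  vector is defined as 21 elements including the duplicate; a forest is
  indifferent to duplicated columns beyond a mild change in effective
  `mtry`, and dropping it would change the documented contract.

# Baselines and their conventions

`otsu_threshold()` works on arbitrary real-valued index maps: a 256-bin
histogram spanning the observed [min, max], exhaustive maximization of the
between-class variance over the 255 interior bin edges, ties broken by the
lowest edge. A constant map is a degenerate-input **error**, not a silent
all-background mask, so pipelines surface pathological images. CIVE
segments **below** its threshold (its green coefficient is negative);
ExGR uses the fixed strict threshold > 0.

`kmeans_segment()` clusters all three (L\*, u\*, v\*) channels — the plant
rule constrains only the centres' u\* and v\* signs, but L\* carries the
shadow structure that separates dark soil from dark foliage. Clustering
uses `stats::kmeans` (Hartigan–Wong) with a seeded multi-start
(`nstart = 5`, 100 iterations) rather than a hand-rolled k-means++/Lloyd
loop: the standard implementation is better tested, and with k = 20 and a
multi-start the partition of well-separated colour clusters is stable
across pixel orderings. Images with at most k distinct colours are handled
exactly (each distinct colour its own centre), which also makes degenerate
inputs (uniform images) well-defined.

## The Sr ambiguity

Sr is implemented as printed — |S ∩ R| / |R|, a true-positive rate that
cannot exceed 1. Published tables using this metric family sometimes show
Sr > 1, which is only possible for the plant-pixel **ratio** |S| / |R|;
that variant is available as `sr(..., variant = "ratio")`. The printed
form is the default, and the exact integer identity
|S|/|R| = Sr + Es links the two (tested exhaustively on all 3×3 masks).

Undefined metrics (empty reference; both masks empty) raise errors rather
than returning sentinels, so batch evaluation cannot silently average
invalid scores. CV uses the sample (n−1) standard deviation.

# The synthetic scene generator

`generate_scene()` emulates, with exact ground truth, the field effects
that make canopy segmentation hard:

1. **Soil**: a spatially correlated mixture of five palette components —
   browns, tan, grey, and a greenish moss/residue component — under a
   correlated brightness field. Every scene contains all components, as a
   real plot does. The moss component is the deliberate stressor for
   colour indices: its ExG response sits inside the shadowed-foliage band,
   while its low HSV saturation (≈ 0.37 versus ≥ 0.5 for foliage) keeps it
   separable in the 21-feature space.
2. **Foliage**: overlapping elongated elliptical blobs (canopy clumps;
   half-width ≥ 4 px, comfortably wider than the 7-px median window) with
   HSV colours drawn from hue 0.22–0.42, saturation 0.50–0.70, value
   0.38–0.60 — realistic canopy greens rather than saturated primaries.
   Blobs are placed until the realized cover is within ±0.05 of
   `target_cover` (0 and 1 are honoured exactly). The truth mask is
   recorded **before** any corruption.
3. **Shadows**: a correlated field thresholded to cover `shadow_fraction`
   (default 0.30) of the area multiplies both classes' brightness by
   `shadow_attenuation` (default 0.55, diffuse-sky fill). Multiplicative
   shadowing preserves HSV saturation, which is why saturation, not
   brightness, is the load-bearing foliage/moss separator.
4. **Specular highlights**: `specular_density` (default 2 per kilopixel)
   near-saturated white spots overwrite foliage pixels only; they stay
   labelled plant in the truth — methods are supposed to recover them.
5. **Illumination**: per-channel multiplicative gains
   (`colour_temperature_shift`) stand in for daylight colour-temperature
   changes, and Gaussian sensor noise (sd 0.02) is added and clipped.
   Full spectral rendering would be unidentifiable from three channels
   anyway; gains suffice to stress chroma-dependent segmenters.

`day_course()` re-applies a gain schedule to a fixed scene (same geometry,
same truth), emulating repeated acquisitions of one plot over a day;
`day_course_gains()` provides a 4-step cool-morning → warm-evening
schedule.

`generate_patch_dataset()` harvests square crops (side 10–16 px) that are
entirely foliage or entirely soil by the exact truth. Two design points
matter. First, the harvest is **capped per scene**, forcing the library to
span ~20+ scenes; second, each internal scene is rendered under its own
gain/brightness jitter along the warm–cool axis. Both mirror how real
patch libraries are collected across days and weathers — and without
them the forest is measurably *not* illumination-robust: trained from a
couple of neutral scenes, its day-course FVC varies more than ExG's
instead of less.

The nominal benchmark condition (the package defaults) is a 128×128 scene
at target cover 0.30 with all corruptions on. At 96×96 the erosion and
dilation of mask boundaries by the 7-px median filter — a geometric floor
of the pipeline itself, ~95% of MFL's residual error — dominates the
scores; 128×128 keeps the boundary fraction closer to field-image scale
while staying fast (the full benchmark in the test suite — training on
200 + 120 patches and scoring 20 scenes plus a 4-step day course — runs
in about a minute on one CPU).

## What the synthetic benchmark does and does not show

Scenes are drawn from the same colour distributions as the training
patches, so the benchmark is a **parameter-recovery** experiment: it shows
that the pipeline learns what its patch library contains and that the
qualitative orderings (MFL above ExG+Otsu on Qseg, below it on Es, more
stable over a day course) emerge under controlled stressors. It does not
show transfer to real canopies: no senescent organs, no weeds, no 3-D
geometry or inter-reflections, no camera PSF (blob boundaries are crisp,
with no mixed pixels), no auto-exposure feedback. Absolute scores on real
imagery will be lower and must be validated against hand-segmented
references.

# Numerical details

* Pixel order is row-major, 0-based, origin top-left; masks serialize as
  8-bit PNG with plant = 255.
* Images load as [0,1] by dividing by the container's full scale (8- or
  16-bit; 12-bit cameras deliver 16-bit containers). Greyscale replicates
  to three channels; RGBA/CMYK is a format error.
* The median filter uses edge-inclusive mirror padding and a summed-area
  table; window 1 is the identity; even windows are errors.
* Blob placement stops at the first placement reaching cover ≥ target −
  0.05; individual blobs are small enough (≤ ~2.5% of the scene) that the
  +0.05 side cannot be overshot. A bounded placement count (5000) turns an
  unattainable target into an error reporting the achieved cover.
* All randomness flows from explicit integer seeds (`seed` in
  `scene_params()`, `mfl()`, `kmeans_segment()`); patch-scene seeds are
  drawn once from the dataset seed, so the whole train→segment→evaluate
  pipeline is byte-reproducible.
* Serialized models embed a format version and the 21-name feature order;
  loading a model with a mismatched order is an error, never a silent
  reorder.

# Known limitations

* Purely chromatic features: textureless confusers (green residue with
  foliage-like saturation) are irreducible by construction.
* The median filter trades isolated-pixel noise for boundary erosion of
  structures thinner than ~4 px and dilation at concave corners; organs
  narrower than the window cannot survive denoising.
* Otsu-based baselines are undefined on constant index maps and unstable
  when the index histogram is more than bimodal — which is precisely the
  behaviour the day-course experiment measures.
* K-means via Hartigan–Wong is seeded-deterministic but its partition is
  not guaranteed to be the global optimum; `nstart` trades time for
  stability.
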