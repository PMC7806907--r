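---
title: "Object-based tree identification from UAV imagery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Object-based tree identification from UAV imagery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

treescope is a machine-vision toolchain for identifying and mapping
individual trees from drone (UAV) RGB orthomosaics and digital surface
models (DSMs). This vignette is the package's account of the science: the
models it implements, the parameters that matter, the numerical choices,
and what the synthetic benchmark does and does not demonstrate.

## The pipeline

A run proceeds in seven stages:

1. **Slope derivation.** The slope model — the maximum rate of elevation
   change between each DSM cell and its neighbours — is computed with
   Horn's 3×3 weighted finite differences and reported in degrees.
   Because a canopy surface falls off steeply at crown borders, the slope
   layer sharpens exactly the boundaries segmentation must find.
2. **Layer stacking.** RGB, DSM and slope are co-registered into a 5-band
   stack (the DSM-resolution layers are bilinearly resampled to the
   orthomosaic grid) with per-layer weights.
3. **Multiresolution segmentation.** Bottom-up region merging from
   single-pixel seeds. The cost of merging adjacent segments `a` and `b`
   is the weighted heterogeneity increase
   `f = (1 − w_shape) Δh_colour + w_shape Δh_shape`, where
   `Δh_colour = Σ_c w_c (n_m σ_c,m − n_a σ_c,a − n_b σ_c,b)` uses
   population standard deviations (defined for single-pixel segments) and
   `Δh_shape` mixes the size-weighted increases of compactness
   (`perimeter/√n`) and smoothness (`perimeter / bounding-box perimeter`)
   with weight `w_compact`. A merge executes only when the pair is
   *mutually* best fitting — each is the other's cheapest neighbour — and
   `f < scale²`. Sweeps over a seeded random scan order repeat until no
   admissible merge remains, which makes runs reproducible and
   order-insensitive in distribution. Adjacency is 4-connected so
   segments never leak across diagonal pixel contacts.
4. **Segmentation scoring.** Each segment is compared with reference
   crowns by the fraction of a crown's area it covers, and placed in one
   of five categories: *Matched* (> 80 % of one crown), *Nearly matched*
   (60–80 %), *Split* (20–60 %), *Merged* (over 20 % of two or more
   crowns; one-class or multi-class by their labels), *Fragmented*
   (nothing above 20 %). Exact thresholds close downward: a coverage of
   exactly 0.60 is Split and exactly 0.20 does not count toward Merged.
   The overlap denominator is the reference-crown area by default
   (intersection-over-union is available), because the question scored is
   whether the segment captures the crown.
5. **Feature extraction and SVM.** The orthomosaic is converted to
   luminance greyscale, rescaled from 8-bit to 5-bit (32 grey levels),
   and a grey-level co-occurrence matrix (GLCM) is accumulated in a
   sliding kernel at each pixel — distance 1, four directions (0°, 45°,
   90°, 135°), symmetric — from which five statistics are computed: ASM
   `ΣP²`, contrast `ΣP(i−j)²`, dissimilarity `ΣP|i−j|`, entropy
   `−ΣP log P` (natural log, `0·log 0 := 0`), homogeneity
   `ΣP/(1+(i−j)²)`. Each segmented object then contributes a 16-value
   feature vector: mean and population SD of each RGB band over its
   pixels plus mean and SD of each texture map over its margin-valid
   pixels. A radial-kernel SVM is tuned by grid search over decade steps
   of gamma (`10⁻¹…10⁻⁵`) and cost (`1…10⁵`) — 30 candidate pairs — with
   features z-scored by training-fold statistics (RBF kernels are
   scale-sensitive; the folds' statistics prevent leakage).
6. **CNN classification.** Object images (bounding-box crops with
   background zero-filled, the mask retained so statistics never ingest
   fill pixels) are resized to 256 and centre-cropped to 224 for
   evaluation, or random-resized-cropped to 224 for training (area
   8–100 %, aspect 3:4–4:3, one patch per image). Training images are
   augmented eightfold with the dihedral transforms, strictly after the
   train/validation/test split. The classifier is a compact
   three-stage convolutional network written in R with explicit
   forward/backward passes: a fixed 8× average-pooling stem (224 → 28),
   three 3×3 convolution stages (16, 32, 32 maps) with ReLU and 2×2 max
   pooling, global average pooling and a dense layer with one logit per
   class. The explicit backward pass is what makes gradient-based
   explanation possible without a deep-learning framework dependency,
   and the aggressive stem keeps training in CPU minutes: the scene's
   class signal (colour and broad texture) survives 8× pooling, which is
   a deliberate trade of fine detail for tractability. Large pretrained
   backbones are intentionally out of scope.
7. **Evaluation, mapping, explanation.** Test predictions are pooled over
   the four fold rotations into one confusion matrix (ground truth on
   rows) with overall accuracy (trace/total), Cohen's Kappa
   `(p_o − p_e)/(1 − p_e)`, per-class F1 and macro F1. Predictions paint
   the segment map into a classified crown map. Grad-CAM (spatially
   averaged logit gradients weighting the chosen layer's feature maps,
   rectified, bilinearly upsampled), guided backpropagation (input
   gradients with both inactive-unit and negative-upstream signals zeroed
   at every rectifier) and their elementwise product, Guided Grad-CAM,
   provide per-object attention maps.

## Fold protocol

Items are divided evenly into four subsets; each of four rotations uses
two subsets for training, one for validation (hyperparameter and epoch
selection), one for testing, with roles interchanged so every subset is
tested exactly once. With a desk-scale object set (~45 objects over 7
classes) a plain random split frequently leaves a class absent from some
training fold, which is treated as an error; the plan can therefore be
stratified by class label, and the pipeline uses stratified plans. The
unstratified split remains the default when no labels are passed.

## The synthetic forest generator

No imagery ships with the package, so `generate_scene()` builds fully
seeded study scenes: a 512×512 px orthomosaic at 5 cm GSD (~26 m across)
with 40 crowns over six tree classes on a bare-ground background, plus a
DSM and reference crown polygons. Crowns are jittered disks (radius 1–2 m,
bounded mutual overlap) with a class-specific base colour, limb darkening
toward the rim, and band-limited Gaussian noise texture whose correlation
length is class-specific (0.8–10 px) — fine speckle for deciduous
broad-leaved foliage through smooth canopies for white pine. The DSM adds
a cone per crown (apex height 6–14 m) over a gently sloping ground plane;
overlapping crowns take the maximum (canopy layering), and the reference
rasterization applies the same layering rule.

What the generator emulates: object colours, fine-scale foliage contrast,
crown-shaped elevation and steep crown rims, overlapping canopies, an
imbalanced non-forest class. What it does not: photogrammetric artefacts,
shadows, within-class colour drift across a site, seasonal change, or
non-stationary texture (branch structure, treetop highlights). Passing
benchmarks on these scenes therefore demonstrates that the chain is
implemented correctly and can exploit colour/texture/height cues it is
pointed at — not that field accuracy on real forests is achieved.

A consequence of stationary synthetic texture worth recording: with
distance-1 co-occurrence offsets, the GLCM kernel size acts as an
estimation-variance knob, and once the five statistics are averaged over
an object, a 3×3 kernel estimates class means nearly as well as 51×51. On
real canopies texture is non-stationary (sunlit and shaded foliage,
branch edges), which is why larger kernels help in practice; the kernel
sweep is implemented and tested as a validation-accuracy argmax rather
than asserting that large kernels must win on synthetic scenes.

## Defaults and tuning

* Segmentation: `scale = 240`, `w_shape = 0.1`, `w_compact = 0.5`, equal
  layer weights. The scale was tuned on the default scene the same way
  the method is tuned in practice — by sweeping and inspecting crown
  recovery — and recovers ≥ 90 % of reference crowns as Matched or
  Nearly matched across scene seeds. Note that with a nonzero shape
  weight, merge costs are positive even on constant imagery, so very
  small scales can stop short of full merging; that is a property of the
  criterion, not a defect.
* Curation: segments below 200 px (~0.5 m²) are dropped before
  classification, a rule-based stand-in for manual deletion of
  uninterpretable fragments; the threshold is logged in every run.
* GLCM: 5-bit quantization, 32 levels, kernel 51 for the benchmark
  features.
* CNN: 20 epochs, SGD with momentum 0.9, learning rate 0.02, batch 8,
  epoch selected by validation accuracy; all seeds recorded. These sizes
  keep a full benchmark run in CPU minutes while reaching macro F1 ≥ 0.9
  alongside the SVM.
* The printed entropy equation of the source texture literature omits the
  minus sign; the package implements the standard nonnegative texture
  entropy.

## Numerical choices and degenerate inputs

* Population (not sample) SD everywhere a segment statistic is
  maintained, so single-pixel segments are well defined (SD 0).
* Slope at edges uses clamp-to-edge padding, keeping the output footprint;
  all-nodata DSMs and grids thinner than 3 cells are errors.
* Merge ties (equal costs) resolve toward the smaller segment id;
  sweep order is a seeded shuffle — identical input, parameters and seed
  reproduce the label grid bit for bit.
* Polygonization traces pixel-edge boundaries; outer rings and holes are
  classified by orientation, polygon area equals pixel count exactly, and
  non-4-connected masks are rejected rather than silently mended.
* Overlap fractions clip exactly against convex references
  (Sutherland–Hodgman) and fall back to dense rasterization for
  non-convex ones; values below 10⁻¹² of the reference area are treated
  as zero to keep floating-point slivers from counting as overlap.
* Raster I/O stores byte imagery losslessly; continuous layers are
  affinely packed into 32-bit samples with the packing range recorded in
  a JSON sidecar, so they round-trip at single precision. The
  geotransform travels in an ESRI world file.

## Known limitations

* The classifier suite is desk-scale by design; no pretrained backbone,
  no GPU path.
* GeoJSON support covers simple Polygon feature collections (sufficient
  for crowns), not the full specification.
* The five-category scheme scores each segment independently; it does not
  enforce a one-to-one crown assignment, so a crown can be "captured" by
  a segment that is itself Merged.
* Guided Grad-CAM is a qualitative explanation aid; the benchmark only
  checks that attention mass concentrates inside the crown mask, not any
  stronger faithfulness property.
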