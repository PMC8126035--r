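---
title: "Marker-free hemocyte counting: model and design notes"
author: "hemocount"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-free hemocyte counting: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Invertebrate immune cells (hemocytes) lack validated molecular markers in
many species, including the apple snail *Pomacea canaliculata*, so
immunohistochemistry-based cell counting is not available. Granular
hemocytes do, however, have a distinctive appearance in routine
hematoxylin–eosin (HE) histology: a purple-staining cell body densely
speckled with stainable cytoplasmic granules. `hemocount` implements a
computer-assisted protocol that exploits exactly this colour/texture
signature to detect and count granular hemocytes in brightfield
micrographs, and to compare counts across experimental groups — for
example control animals versus animals at an early time point after
appendage amputation, when hemocytes infiltrate the regeneration blastema.

## The model

The protocol is a trained, deterministic pipeline with four stages.

**1. Background removal.** Bright non-tissue regions (empty slide, lumina
of blood lacunae) have high green *and* blue intensities, whereas
eosin-stained tissue has a suppressed green channel. A pixel is background
iff `G >= green_threshold && B >= blue_threshold` (defaults 200/200 on the
0–255 scale). The AND of the two channels protects weakly blue
hematoxylin-stained structures from removal. Background pixels stay in the
raster — neighbourhood windows remain defined everywhere — but are
excluded from model fitting, projection and object masks.

**2. Multivariate image analysis (MIA).** Each retained pixel is
represented by the colour intensities of its `(2r+1) × (2r+1)`
neighbourhood across the three channels; the default radius `r = 2`
(a 5×5 window) gives 75 features per pixel. This "unfolded" matrix is
mean-centred — no variance scaling, since all features share one intensity
scale — and decomposed by PCA using a deterministic singular value
decomposition. The model is fitted only on hemocyte pixels: annotated
rectangles around individual cells are cropped and packed into a training
mosaic whose padding is pure white sentinel, and any row whose window
touches sentinel or background pixels is dropped, so the component basis
describes within-hemocyte colour/texture variation only. Manual
annotation happens once per staining/microscope configuration; afterwards
any image is scored without operator input.

**3. Score image and threshold.** Every pixel of a new image is projected
onto one selected principal component and the scores are refolded to image
geometry. Pixels scoring at or above a threshold are candidate hemocyte
pixels. The threshold is the 0.05 quantile of the training hemocyte-pixel
scores: it keeps ~95% of hemocyte pixels and rejects tissue classes
whose scores lie below the hemocyte score distribution.

**4. Objects and shape exclusion.** The thresholded mask is consolidated
by morphological closing (disk radius 1) plus hole filling — granule-level
thresholding otherwise fragments cell interiors — intersected with the
tissue mask, and labelled into 8-connected components. Each object gets
area, bounding-box width and height, perimeter, circularity
(`4πA/P²`) and solidity (`A / convex area`). Objects failing any bound of
a shape filter are excluded, with the first failed criterion recorded in
the fixed order area, width, height, circularity, solidity. The remaining
objects are the counted hemocytes.

Counts are compared across groups with classical one-way ANOVA (each image
one observation, counts untransformed; a `log1p` option exists but is off
by default) and the Tukey–Kramer studentized-range test, whose standard
error `sqrt(MSW/2 (1/nᵢ + 1/nⱼ))` handles unequal group sizes and reduces
to the Tukey HSD form for balanced designs.

## Choices made where the design was open

**Which component, and which sign.** In the configuration the protocol
was originally developed on, the informative component was the fourth
(PC4); the index is
configuration-specific, so `hemocyte_model()` defaults to
`selected_pc = "auto"`: it ranks components by the standardized contrast
between scores of annotated hemocyte pixels and all other tissue pixels on
the calibration images, `(m_h − m_o) / sqrt((v_h + v_o)/2)`, and picks the
largest in magnitude. A fixed index (e.g. 4) can be supplied to reproduce
an established configuration. Because the training scores are centred,
their own mean carries no orientation information; the selected loading is
oriented so that hemocyte pixels score *above* other tissue, making
"score ≥ threshold" always the hemocyte side. Remaining components get a
deterministic sign fix (largest-magnitude loading element positive) so
fitted models are bit-for-bit reproducible.

**Score threshold.** The quantile rule (default 0.05) replaces the visual
threshold setting implied by the original protocol; it is explicit,
deterministic, and has a direct sensitivity interpretation at the pixel
level.

**Perimeter estimator.** Perimeter is `(π/4) ×` the number of exposed
pixel edges (crack edges). This Cauchy–Crofton-style weighting is
asymptotically unbiased for smooth convex outlines — a digital disk of
radius 10 yields circularity ≈ 1.0 — at the cost of overshooting
circularity on small axis-aligned rectangles; since the filter applies a
*lower* circularity bound to near-round cells, the overshoot is harmless
and is additionally clipped at 1.15 before filtering.

**Shape-filter calibration.** The original work states no numeric
cut-offs. `calibrate_filter()` derives them from the annotated cells
themselves: per annotation rectangle, the largest detected object inside
it is taken as that cell's descriptor (stray granule fragments are thereby
ignored); area/width/height bounds are the observed min/max widened by
50%, and circularity/solidity minima the observed minima shrunk by 50%.

**Other defaults.** Window radius 2 reads "a window of 2 pixels in any
direction" literally; image borders use replicate padding to avoid
synthetic colour edges; 10 components are retained (enough to cover any
plausible informative component at negligible cost); object connectivity
is 8, the blob-detection standard; 4-connectivity is available and is
cross-checked in the tests against an independent labelling
implementation.

## The synthetic data generator

No reference micrograph data are publicly available for this protocol, so
validation uses a generator that emulates the salient appearance of HE-stained tentacle
tissue:

* eosin-pink base (RGB 230/170/185) with smooth Gaussian-blurred texture
  (SD 6 intensity units) and ~10% bright lacuna lumina;
* **hemocytes**: purple disks (radius 6–9 px ≈ 10–15 µm cells at the
  default 0.86 µm/px) densely speckled with darker granules (~35% cover,
  ΔRGB ≈ 50), surrounded by a thin bright halo emulating the hemolymph
  space/retraction artefact that separates cells from surrounding tissue
  in real sections;
* **confounders**: small smooth dark-blue nuclei (semi-axis 1.5–2.5 px;
  hemocyte hue, no granular texture) and elongated smooth pink muscle
  fibres (tissue hue, wrong shape) — the two borderline classes reported
  for the original protocol;
* Poisson-distributed hemocyte numbers, a minimum centre separation of
  24 px, and per-pixel Gaussian camera noise (SD 2).

The default field is 256×256 px at 0.86 µm/px = 0.0485 mm², matching the
0.048 mm² field of the reference 40×/0.95 acquisition. The generator
consumes its random stream in a documented order (hemocytes, nuclei,
fibres, texture, lacunae, noise) so adding confounders never moves the
planted cells, and everything is bitwise reproducible from one seed.

With these defaults the granule-induced intensity spread inside hemocytes
exceeds the background texture amplitude more than three-fold, which is
what makes the one-component score threshold well posed; the test suite
asserts this separability on generated samples.

What the generator deliberately does *not* model: stain variability and
bleed-through, optical blur and vignetting, partially sectioned or
touching cells, and out-of-plane tissue. Passing the synthetic study
therefore demonstrates the internal correctness and statistical behaviour
of the pipeline, not its accuracy on any particular real staining batch —
on real material the calibration phase (annotation, component choice,
threshold) must be repeated per configuration.

## Numerical notes

* PCA uses LAPACK SVD; no randomized solver anywhere, so fitted models,
  persisted JSON (written with 17 significant digits) and detection
  results are bit-identical across reruns.
* Degenerate inputs: constant training mosaics give all-zero eigenvalues
  and zero scores; empty annotation sets, all-background tiles, one-group
  count tables and all-identical counts raise informative errors; an
  all-permissive filter keeps every object.
* Quantiles use the default type-7 definition; thresholding uses `>=` so
  the limiting quantile → 0 keeps all training pixels.
* Simulation sizes used by the test suite: the planted-recovery check
  runs 20 default-size fields against ground truth (sensitivity and
  precision ≥ 0.90); the group-comparison check runs 30 fields per
  condition with Poisson means 2 versus 14, where the detected fold
  change falls within the 5–9× range reported for regenerating versus
  control tissue, and Tukey–Kramer flags the pair at α = 0.05; the
  null-uniformity check of ANOVA p-values uses 2000 replicates. Unit
  tests use scaled-down 120–176 px fields.

## Known limitations

* Rectangular annotations only; cells are assumed separable by their
  bright surround — densely touching cells are not split (no watershed).
* One component and one threshold; multi-component segmentation rules and
  wavelet texture features (needed for agranular cell classes) are out of
  scope.
* Counts are treated as independent observations within groups; animal-
  level random effects are not modelled.
* The statistics assume at least two images per group and non-degenerate
  within-group variance.
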