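---
title: "Morphometric profiling of bile duct brushing cell clusters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric profiling of bile duct brushing cell clusters: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Bile duct brushings (BDBs) are the standard screening specimen for
pancreatobiliary adenocarcinoma, but their cytological interpretation is
notoriously insensitive: inflamed, reactive backgrounds and low cellularity
push many specimens into an indeterminate "atypical" category. brushmorph
implements a fully hand-crafted, interpretable image-analysis pipeline for
this setting: it quantifies each epithelial *cell cluster* on a digitized
40x Papanicolaou-stained slide with a 536-dimensional morphometric vector
(495 aggregate texture + 41 nuclear shape features), selects the most
discriminative features, and trains a class-imbalance-aware ensemble that
outputs a probability of malignancy per cluster and, by averaging, per
patient.

The cluster — not the nucleus and not the slide — is the unit of analysis:
texture is measured over the entire cluster region to capture
nucleus–cytoplasm interactions (chromatin clumping, nuclear molding,
marginal chromatin), while shape is measured per nucleus and aggregated.

## Pipeline and models

### Preprocessing (`preprocess_cluster()`)

1. **Background removal.** The slide background is bright; its intensity is
   estimated as the mean of the pixels above the Otsu split of the crop, and
   pixels brighter than 95% of that estimate are discarded. The 5% margin
   is ours: a threshold *equal* to the mean background intensity would, by
   definition of a mean, misclassify roughly half of the background pixels;
   95% sits safely between the tissue modes and the background mode for any
   realistic stain contrast.
2. **Artifact filtering.** Connected components smaller than 100 µm²
   (1600 px at 0.25 µm/px) — stain debris, bile residue, single cells — are
   removed. The inequality is strict: a 1599-px object falls, a 1600-px
   object survives.
3. **Histogram equalization**, computed over the foreground mask only
   (256 bins). Including background pixels would flatten the histogram
   against the background mode and compress the nuclear contrast the later
   steps depend on. The map is a monotone CDF lookup: intensity order is
   never inverted, though distinct inputs may merge.

Before texture extraction, slowly varying illumination is removed by
subtracting a 15×15 moving average from the image
(`normalize_illumination()`), with reflected borders so edges are not
darkened.

### Automatic cluster detection (`detect_clusters()`)

Slide-scale images are tiled into non-overlapping 1000×1000-px patches
(row-major, remainders dropped, 0-based half-open boxes). Patches with more
than 40% background are discarded; the background definition reuses the
preprocessing threshold so the pipeline has a single notion of
"background". Remaining patches are thresholded and each connected
component of at least 100 µm² becomes a cluster crop. Clusters spanning a
patch boundary are not stitched — a documented recall limitation of the
non-overlapping grid.

### Nuclear segmentation (`segment_nuclei()`)

Nuclei are the dark phase of the equalized cluster: Otsu within the
foreground, hole filling, and speck removal (< 10 µm²) give a binary
nuclear mask; touching nuclei are then split by watershed on the negative
Euclidean distance map, with markers taken as the regional maxima of the
distance transform after h-extrema suppression of depth `h_min`.

`h_min` defaults to **1 px**. At 0.25 µm/px, nuclei have 10–17-px radii and
molded (touching) nuclei meet in necks whose distance-map saddles sit only
1–2 px below the peaks; a 2-px suppression depth merges a substantial
fraction of them (on the synthetic overlap-0.3 cohort the mean
nucleus-count error is ~11% at depth 2 versus ~3% at depth 1), while 1 px
still suppresses single-pixel raster chatter (a convex blob stays a single
label). Users working at coarser resolutions should scale `h_min` with the
pixel size. Border-touching nuclei are retained: excluding them would bias
the shape statistics of small crops.

### The texture bank (`texture_features()`, 495 features)

Four per-pixel families, 99 response maps in total, each summarized over
the cluster foreground by five statistics (mean, median, population SD,
skewness, plain kurtosis with Gaussian = 3):

* **Haralick (13 maps).** The image is quantized to 64 grey levels over the
  foreground min–max range; at every pixel a symmetric grey-level
  co-occurrence matrix is pooled over the four distance-1 directions
  (0°, 45°, 90°, 135°) within a 5×5 window (clipped at the image border),
  and the 13 classical second-order statistics are computed (energy,
  contrast, correlation, variance, inverse difference moment, sum
  average/variance/entropy, entropy, difference variance/entropy, and the
  two information measures of correlation). Direction pooling into a single
  matrix (rather than averaging four per-direction statistics) is our
  choice; it is the rotation-robust variant and is what the rotation
  invariance test exercises. Entropies use natural logarithms; degenerate
  statistics (zero marginal variance, zero entropy) are defined as 0.
* **CoLlAGe (13 maps).** Gradients by central differences; in each 5×5
  window the dominant gradient orientation is the principal direction of
  the windowed structure tensor (equivalently the leading right singular
  vector of the stacked gradient matrix — the two are identical, which the
  per-window SVD oracle test verifies). Orientations (mod π) are quantized
  into 64 bins and fed through the same windowed co-occurrence machinery.
  Zero-gradient windows are flagged and assigned bin 0.
* **Gabor (48 maps).** A 6-frequency × 8-orientation grid of DC-free
  complex Gabor filters; response = magnitude. Frequencies form a geometric
  series 0.05–0.4 cycles/px, orientations 0–7π/8; the envelope scale is
  σ = 0.56/f (about one octave), truncated at 2.5σ (radius capped at
  31 px). The *count* of 48 filters is the binding contract; the exact grid
  is a package choice. Convolution is done in the Fourier domain on a
  reflect-padded canvas; because the isotropic-envelope Gabor kernel is a
  rank-1 outer product (plus a rank-1 DC correction), its frequency
  response is assembled from two 1-D FFTs, which makes the bank cheap. The
  FFT path equals direct spatial correlation with the explicit kernel to
  ~1e-14.
* **Law's (25 maps).** All ordered outer-product pairs of the classical
  5-tap vectors L5 = (1,4,6,4,1), E5 = (−1,−2,0,2,1), S5 = (−1,0,2,0,−1),
  W5 = (−1,2,0,−2,1), R5 = (1,−4,6,−4,1), applied as cross-correlation with
  reflected borders.

Maps that are constant over the foreground report skewness = kurtosis = 0
(flagged by a warning); this occurs for genuinely flat responses, e.g. the
contrast map of a constant region.

### The shape bank (`shape_features()`, 41 features)

Eight per-nucleus descriptors — area (µm²), perimeter (Crofton 4-direction
estimator), major/minor ellipse-equivalent axis lengths (from second
moments with the 1/12 unit-square pixel correction), eccentricity, solidity
(pixel count / rasterized convex-hull pixel count, regionprops-style),
circularity (4πA/P²), equivalent diameter — each aggregated over the
cluster's nuclei with the same five statistics (40 features), plus the N:C
ratio (total nuclear area / non-nuclear foreground area). The published
feature list enumerates "forty shape features" and "41 per cluster"; the
8 × 5 + 1 reading reconciles the two counts and includes every shape
feature the source results name (perimeter, solidity, minor axis length).
Single-nucleus clusters report zero dispersion statistics by convention.

### Selection and classification (`cross_validate()` and friends)

* **Univariate ranking**: two-sided Wilcoxon rank-sum (exact for small
  tie-free samples) or Welch t-test per feature; ascending p, ties broken
  by standardized mean difference, then name; constant features get p = 1.
  The top five significant (α = 0.05) features are used; if fewer than five
  reach significance the best-ranked features fill in.
* **mRMR**: greedy forward selection; relevance = |point-biserial Pearson
  correlation with the label|, candidates with |r| > 0.7 to any selected
  feature are pruned, and the survivor maximizing relevance minus mean
  absolute correlation to the selected set is added. The relevance
  functional of the original implementation is not published; the
  point-biserial form is our choice and is cross-checked against exhaustive
  admissible-pair search in the tests.
* **Multi-expert balancing**: for minority size *b* and majority size *m*,
  expert 1 trains on all *b* minority plus *b* majority samples (without
  replacement); expert 2 on the remaining *m − b* majority plus *m − b*
  minority samples. When *m − b > b* the published scheme ("sampled from
  b") is impossible without replacement, so the minority side is resampled
  with replacement in that regime (logged in the model object). Balanced
  classes collapse to a single expert. Prediction is the mean of expert
  probabilities. Base learners: LDA, QDA (MASS), or a bagged ensemble of
  100 entropy-split decision trees (rpart) standing in for bagged C4.5.
* **Cross-validation**: repeated (default 100×) stratified 3-fold splits at
  the **patient** level — no patient straddles folds, since cluster-level
  splitting would leak patient identity into the test folds. Selection is
  re-run inside every training fold. Each iteration's pooled held-out
  probabilities yield one AUC/sensitivity/specificity (trapezoidal ROC,
  `p >= threshold` called positive, operating threshold P_mal = 0.3); the
  report gives mean ± SD across iterations. "100 iterations of
  cross-validation" and "100 bootstrap replications" are read as 100
  independently re-randomized CV repeats.
* **Patient calls** (`predict_patients()`): mean of cluster probabilities
  (median/max available); the aggregation rule is not published, mean is
  the default.

## The synthetic-data generator

No clinical images ship with the package, so `render_cluster()` /
`make_cohort()` generate clusters with ground truth. Nuclei are ellipses
with sinusoidal radial perturbation (harmonics 2–5); the perturbation
amplitude is calibrated by iterated re-rendering so measured solidity
approaches `solidity_target` (zero irregularity gives exact convex
ellipses). Nuclei are placed by sequential attachment so each cluster is
one connected epithelial group; a nucleus is "touching" (centre distance
0.85 of the radius sum, later nuclei occlude earlier ones) with probability
`overlap_fraction`. Chromatin is a smoothed Gaussian noise field whose SD
is the `chromatin_heterogeneity` knob; cytoplasm is a ~2-µm dilated rim at
a fixed grey level; background is bright with mild sensor noise; default
pixel size 0.25 µm/px (typical 40× scan).

Preset phenotypes encode the reported directions of effect — the malignant
preset has a larger mean minor axis (8.5 ± 1.2 µm vs 6.0 ± 0.6 µm, i.e.
separated by >3 benign SDs), lower solidity (0.88 vs 0.97), higher
chromatin heterogeneity (14 vs 6 grey levels) and more overlap (0.25 vs
0.10). The magnitudes are our calibration: the source characterizes
directions, not distributions. Default cellularity is 8 nuclei per cluster
(realistic for an epithelial brushing group) and cohorts attach a patient
random effect (±0.15 µm axis shift, ×e^N(0,0.08) heterogeneity) so clusters
within a patient correlate and patient-level cross-validation is
meaningful.

What the generator does **not** emulate: Papanicolaou colour (grayscale
canvases; an RGB path exists only for conversion testing), out-of-focus
planes, stain variability, mucus/inflammatory background, and true 3-D
nuclear overlap (occlusion is used instead). Tests passing on this
generator therefore demonstrate internal correctness and label-recovery
power under controlled morphology, not clinical performance.

## Experiment sizes and numerical choices

The label-recovery experiment uses 30 benign + 30 malignant synthetic
patients with 5 clusters each (300 clusters per arm) and 20 CV iterations —
large enough that a chance-level AUC is estimated within a few hundredths
while keeping the whole experiment desk-scale. The published headline
performance (training AUC ≈ 0.85, validation AUC 0.79 on private clinical
slides) is *not* a target of these experiments; what is checked is that the
pipeline recovers planted separations (AUC ≥ 0.9) and stays at chance on
identical presets.

Numerical conventions collected in one place: natural logs in all
entropies; population (not sample) moments in the 5-statistic summaries,
with skewness = kurtosis = 0 for zero-variance samples; co-occurrence
windows clipped (not padded) at borders; convolution borders reflected;
quantization ranges per cluster (foreground min–max); ROC thresholds swept
over the observed probabilities with ties called positive at `>=`;
correlation of a degenerate co-occurrence matrix defined as 0; all RNG
behind a single seed with caller RNG state restored.

## Known limitations

* Watershed under-segments heavily molded or atypical nuclei; no
  remediation is implemented (none is published).
* Clusters spanning patch boundaries are not stitched.
* No stain normalization or colour texture; inputs are grayscale.
* QDA requires non-singular class covariances and can fail on tiny folds;
  LDA is the robust default.
* Probabilities are not calibrated; the 0.3 operating threshold is adopted
  from the published operating point, not re-derived.
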