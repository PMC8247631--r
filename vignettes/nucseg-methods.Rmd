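---
title: "Methods: size-normalized, style-aware nucleus segmentation scaffolding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: size-normalized, style-aware nucleus segmentation scaffolding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

nucseg packages the scaffolding that surrounds a modern nucleus instance
segmentation model: the preprocessing that makes nucleus size uniform, the
appearance clustering and synthetic-data generation that adapt a model to
unseen imaging styles, the morphological post-processing that cleans raw
detector output, and the full evaluation suite of the 2018 Data Science
Bowl (DSB). The deep networks themselves (the instance segmenter, the
pixel-probability network, the learned image renderer) are *not* part of
the package: each is an interface a trained backend can be plugged into,
and each ships with a classical, CPU-only stand-in so the whole pipeline
runs and can be tested on a desktop.

```{r setup, eval = FALSE}
library(nucseg)
```

## Data model

An `instance_set` is the currency of every stage: an ordered list of
objects on a `height x width` canvas, each object a set of pixels, each
with a unique positive label. Objects may overlap — raw detector output
can — and flattening to a label image is last-object-wins, which makes the
"object entirely inside another" cleanup rule meaningful. Pixels are
stored as R's native 1-based column-major linear indices. This coincides
exactly with the Kaggle DSB run-length encoding (1-based, column-major,
down-then-right), so RLE export is bit-exact without any coordinate
shuffling; it is also why the package indexes 1-based throughout rather
than adopting a 0-based convention that every installed image library
would have to be translated to and from.

Label images are written as 16-bit single-channel TIFF. Images with more
than 255 nuclei are routine, and of the installed writers only TIFF
round-trips 16 bits exactly (8-bit PNG output is supported for small label
counts; PNG of any depth is read). Probability maps are plain matrices
clamped to [0, 1].

## Size normalization

Detection models have a sweet spot in object size; the pipeline's is a
nucleus diameter of about 40 px. For each image the typical nucleus size
is estimated from a rough pre-segmentation as the **median
equivalent-circle diameter** $2\sqrt{A/\pi}$ over objects. The median is
chosen over the mean for robustness to debris and merged clumps; the
summary function is an argument, so the mean is one keystroke away. The
scale factor is simply $f = 40/\hat d$, the image is resampled bilinearly
and each object mask nearest-neighbour (labels are never blended), and
instances found at the normalized scale are mapped back to native
resolution before scoring, so ground truth is never resampled. Scale
estimation is per-image; a dataset-level prior can be passed when the
pre-segmenter finds nothing.

Working canvases are 512 x 512: smaller inputs are zero-padded
bottom-right (content anchored top-left), larger ones tiled with 50%
overlap so every pixel is seen at least once. Padding value, anchoring and
overlap are package conventions — any fixed, documented choice works, and
the tests pin these ones.

## Style clustering

To adapt to images "in the wild", unannotated images are grouped by
appearance. Each image is summarised by a fixed 11-dimensional feature
vector: intensity statistics (mean, sd, 1st/50th/99th percentiles),
gray-level co-occurrence texture (contrast, correlation, homogeneity,
entropy at the two unit offsets, averaged — which buys invariance under
90-degree rotation), mean gradient magnitude, and Otsu foreground
fraction. Maximal constant borders are trimmed first, so padding an image
with a uniform frame does not move its features. CellProfiler-style
feature extractors would serve equally well; a native implementation keeps
the dependency surface small and the feature list versioned.

Pairwise similarity is learned from labelled pairs (1 = same imaging
condition, 0 = different) by a single-hidden-layer network on the absolute
difference of z-scored features — symmetric in its arguments by
construction. With no labelled pairs available, similarity falls back to a
Gaussian kernel on standardized Euclidean distance with the bandwidth set
to the median squared pairwise distance. Each image's row of the
similarity matrix is its embedding, clustered by k-means (10 restarts,
seeded). The cluster count deliberately over-segments at one cluster per
15 images, `k = max(1, round(n/15))`: over-splitting a style is harmless
(each part still gets matched synthetic data), mixing two styles is not.
The divisor 15 reproduces k = 134 on a ~2000-image set. Clusters with
fewer members than a configurable floor can be excluded; style statistics
from one image are legal but weak.

## Style-matched synthesis

For each style cluster the package estimates empirical distributions —
objects per image, equivalent diameter, nearest-neighbour centroid
spacing, foreground and background intensity — and generates synthetic
mask/image pairs:

* **Shapes** come from a database of real nucleus masks (cropped,
  descriptor-annotated, resampled to the drawn diameter) with probability
  `db_fraction` (default 0.5), otherwise from a parametric simulator: an
  ellipse of the drawn diameter with a smooth low-order (harmonics 2–5)
  random radial perturbation, star-convex so always simply connected.
* **Placement** is rejection sampling with a hard non-overlap constraint
  (and a 1-px margin), up to 1000 retries per object before failing
  loudly; spatial statistics then emerge from the drawn counts and sizes.
* **Rendering** is behind a one-function interface `(mask, stats, seed) ->
  image`. The shipped baseline renderer draws pixel intensities from the
  style's empirical foreground/background distributions, smooths, and adds
  mild noise. It is a statistical renderer, not a learned one: it
  preserves first-order intensity structure and contrast polarity, not
  texture. A trained image-to-image model drops into the same interface
  without touching any other code.

Generating 20 pairs for each of 134 clusters yields exactly 2,680 pairs;
the count is `per_style * k` by construction and the tests pin it.

## Conventional augmentation and batch mixing

Geometric operators (crop, arbitrary-angle rotation, translation) apply
identically to image and mask — the mask nearest-neighbour, and rotations
by multiples of 90 degrees take an exact lossless path. Intensity
operators (percentile stretch, histogram equalization, inversion, blur,
additive noise; channel swap is a no-op on grayscale) touch only the
image. Every operator fires independently with probability 0.5 by default.
Objects clipped below 4 px by cropping or rotation borders are dropped —
a documented threshold, not a tuned one. Training batches mix a uniformly
drawn 10–50% of synthetic samples.

## Post-processing chain

Raw detector output is refined by five rules in a fixed order, governed by
six parameters with defaults `(0.17, 44, 0.9375, 1, 1, 0.8)`:

1. objects entirely inside a strictly larger object are removed;
2. an object whose boundary pixels touch a neighbour (8-connectivity) on
   more than a fraction `p1` of its boundary is merged into it. `p1` is a
   fraction — 0.17 means 17% — the only plausible reading of the tuned
   value. When several merges qualify, the most-surrounded object is
   absorbed first and the union keeps the absorbing object's label;
3. objects with area strictly below `p2` px are removed;
4. a soft margin band — `p4` px inwards to `p5` px outwards of each
   contour, square structuring element — is re-decided by the probability
   map: inside the band a pixel belongs to the object iff its probability
   is at least `p3`; outside the band membership is untouched. Pixels
   claimed by two objects go to the nearer original mask, ties to the
   lower label. Objects can shrink to nothing (then they are dropped) but
   the stage never creates objects;
5. objects with mean probability strictly below `p6` are removed.

All inequalities are strict exactly as the rules are stated. Every stage
has an off switch, and the whole chain may be skipped when boundary-level
accuracy is not needed.

The six parameters are tuned by a real-coded genetic algorithm maximising
the mean DSB score over training triples (prediction, probability map,
ground truth): tournament selection (size 3), uniform crossover, Gaussian
mutation with sigma at 10% of each parameter's range, one elite carried
over unchanged — so the best fitness is monotone in the generation — and
a fixed seed for reproducibility. The default parameter vector and an
identity-leaning chain are seeded into the initial population, so the
tuned result can never fall below either. Defaults are population 30,
generations 20; the tests use 16 x 10 on two training images, which
suffices because the fitness landscape of the planted-debris recovery
problem is a plateau bounded by the largest debris and the smallest
nucleus.

## Evaluation

Matching pairs predicted and true objects one-to-one, greedily by
descending IoU with ties broken by (ground-truth label, predicted label).
A pair is a hit at threshold $t$ iff IoU $> t$ (strictly); since an object
can have at most one counterpart with IoU above 0.5, greedy matching is
provably optimal over the DSB grid $t \in \{0.50, 0.55, \dots, 0.95\}$,
and the tests verify agreement with exhaustive search. The DSB score is

$$\mathrm{score} = \frac{1}{10}\sum_t \frac{TP(t)}{TP(t)+FP(t)+FN(t)+\varepsilon},$$

with $\varepsilon = 10^{-40}$ in every denominator, averaged over images
at set level. An image that is empty in both prediction and truth scores 1
(a perfect prediction must score 1; the raw formula would give 0) — the
one deliberate departure from the bare formula, flagged here because the
official scorer's behaviour on empty images is not documented. Precision,
recall and F1 per threshold use the same counts and epsilon and are
averaged the same way; note mF1 is the threshold-averaged harmonic mean,
not the harmonic mean of mAP and mAR. Mask-level binary cross-entropy
clips probabilities at $10^{-12}$ so saturated predictions stay finite.

Errors are also classified into a four-way taxonomy: an unmatched
ground-truth object is a **split** if at least two predictions each cover
at least 30% of its area (15% each if more than two), and **missed** if no
prediction covers even 30%; **merges** apply the same rule with roles
swapped (coverage fractions on the predicted object's area), and unmatched
predictions with no significant ground-truth overlap are **false
detections**. Unmatched objects with exactly one significant partial
counterpart are boundary errors and intentionally fall into no category.
The normalisation of the overlap fraction (covered object's own area) is
an interpretation — the rule is stated in the literature without naming
the denominator — and is configurable.

## The toy-image simulator

`make_toy_dataset()` is first-class, tested code, not a throwaway fixture:
non-overlapping perturbed-ellipse nuclei placed uniformly with a 2-px
margin, rendered as smoothed two-level intensity plus Gaussian noise,
ground truth exact by construction, everything a pure function of the
seed. It emulates what matters to the scaffolding — object size and count
distributions, contrast polarity (bright-on-dark and dark-on-bright
"styles"), touching-free instances — and deliberately not what belongs to
the networks: realistic texture, uneven illumination, overlapping or
touching nuclei, imaging artefacts. Green tests on these fixtures
establish that the machinery is correct and deterministic; they say
nothing about segmentation accuracy on real microscopy, which is entirely
a property of the plugged-in backend.

The classical fallback backend (Otsu threshold on the smoothed image,
polarity decided by which phase is the minority, opening, distance
transform, watershed) exists so the pipeline is runnable end-to-end
without weights; it resolves touching convex blobs with a clear neck and
nothing harder.

## Problem sizes and numerical choices

Test and acceptance runs use deliberately small configurations chosen as
the smallest sizes at which each property is informative: 128 x 128
canvases; 134 styles x 20 pairs for the cardinality check; 1,000 random
instances of at most 5 objects against exhaustive matching; GA at
population 16 for 10 generations on two training images; 40 images for
style recovery; diameters 10–160 for the rescale fixed point. Determinism
everywhere comes from threading a single integer seed; composite
operations derive per-unit sub-seeds (kept below $2^{31}$) so outputs are
independent of iteration order. Known limitations: no 3D/z-stacks, no
boundary-distance metrics, no learned refinement, no claim of photorealism
for the baseline renderer, and tiling reassembly is last-wins rather than
a consensus stitch.
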