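---
title: "Automated fiber selection and g-ratio morphometry: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated fiber selection and g-ratio morphometry: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(gratior)
```

## The measurement problem

The g-ratio of a myelinated nerve fiber — the ratio of the inner (axon) to
the outer (axon + myelin sheath) diameter — summarises how much myelin wraps
an axon. Values around 0.6–0.7 are considered optimal for conduction, and
deviations accompany demyelinating disease, injury and development. In
semi-thin resin sections of peripheral nerve imaged by optical microscopy
(PPD- or toluidine-blue-stained, typically digitised at 0.05 µm/px), manual
g-ratio measurement is slow and observer-dependent, and a cross-section
contains many fibers that should *not* be measured at all: fibers cut
obliquely, fibers truncated by the section or image border, and profiles too
small to delineate reliably.

`gratior` implements the full automated chain:

1. **Segmentation** of the image into background / myelin / axon, by a
   trainable encoder–decoder convolutional network or by a deterministic
   oracle backend used for pipeline testing;
2. **Post-processing** of the class probability maps: thresholding at 0.8
   and cavity filling;
3. **Fiber extraction**: connected axon components, each paired with its
   surrounding myelin;
4. **Quality selection** with the shape filters (eccentricity > 0.95,
   solidity < 0.9, area < 50 px excluded);
5. **Morphometry**: per-fiber axon diameter, myelin thickness, axon and
   myelin volume fractions, g-ratio;
6. **Reliability statistics**: ICC(3,1), Bland–Altman, Shapiro–Wilk-gated
   paired tests, one-way ANOVA across parallel sections.

A synthetic nerve-phantom generator with exact per-fiber ground truth makes
every stage testable without histology data.

## The g-ratio model

For a single fiber the reference region is the union of its axon and myelin
pixels. With $AVF = |axon|/|region|$ and $MVF = |myelin|/|region|$ (so
$AVF + MVF = 1$ by construction), the g-ratio is computed from area
fractions rather than from fitted diameters:

$$ g = \sqrt{\frac{1}{1 + MVF/AVF}} = \sqrt{\frac{|axon|}{|region|}}, $$

which for an ideal annulus with axon radius $r$ and outer radius $R$ reduces
to the classical $r/R$. The area route is robust: it needs no circularity
assumption and no boundary fit.

Two definitions of "the region" are defensible — the fiber's own
axon∪myelin support, or a bounding region that includes background. We use
the per-fiber union: it makes $AVF + MVF = 1$ an asserted invariant and
makes $g$ equal $r/R$ exactly for annuli. Axon diameter is the
area-equivalent circle diameter $2\sqrt{|axon|/\pi}\cdot s$ (pixel size
$s$ in µm/px), the fiber diameter likewise from the region area, and myelin
thickness is half their difference. Equivalent diameters were chosen over
Feret or axis lengths because they are insensitive to boundary pixelation;
the estimator sits behind a single function so alternatives can be swapped
in. A fiber with no assigned myelin is reported with $MVF = 0$, $g = 1$ and
zero thickness plus an `unmyelinated` flag — exclusion is the selection
module's job, not the morphometry module's.

## Segmentation network

The reference architecture is a U-Net with six resolution levels of 16, 32,
64, 128, 256 and 512 filters; each level applies two 3×3 convolutions, each
followed by channel normalization and a parametric ReLU, with stride-2
downsampling between levels, skip connections, and a softmax head trained
with the soft Dice loss and Adam at learning rate 1e-3 on 512×512 patches.
That configuration is constructible (`unet_config_full()`), but the package
default is a reduced 3-level 8/16/32-filter variant on 256 px patches: the
network trains on a single CPU in minutes there, and on phantom imagery it
reaches held-out Dice well above the 0.8 smoke-test bar, so the reduced
scale exercises exactly the same code path as the full one.

The implementation is a compact, self-contained CPU U-Net written with
Armadillo linear algebra; its backward pass is verified against central
finite differences to ~1e-11 in the test suite. Two design points deserve
note:

* **Normalization.** With a batch size of one, batch statistics equal
  per-patch (instance) statistics. We normalize with the current patch's
  statistics in training *and* inference, which makes prediction
  deterministic and removes any train/eval statistics mismatch. A
  consequence: a perfectly constant input carries no contrast for the
  normalized layers, so the degenerate all-background fit converges through
  bias terms only and needs many (cheap) steps — visible in the tests.
* **Dice loss over present classes.** The soft Dice term of a class absent
  from a target patch is a 0/0 plateau with a vanishing gradient. The loss
  therefore averages over the classes present in the patch; the softmax
  coupling still drives absent-class probabilities to zero.

Augmentations are flips, right-angle rotations, mild zooms (0.9–1.1,
nearest-neighbour resampling for masks), additive Gaussian noise and
Gaussian smoothing. Free-angle rotation is deliberately not applied to
masks: interpolating a 1-px-wide myelin ring can break its annular
topology, which the downstream pairing step depends on. Zoom and rotation
magnitudes are mild for the same reason. Epochs, batch composition and the
train/validation split are configuration, with the split seeded; identical
seed, data and configuration reproduce the training log bit for bit.
Model weights are never shipped — reproducibility comes from seeds plus the
phantom generator.

Tiled prediction blends overlapping tiles by linear-ramp weighted
averaging; the tiling-consistency check in the acceptance tests bounds the
interior disagreement between tilings.

## Post-processing

A pixel is assigned to the highest-priority class whose probability reaches
0.8 (priority axon > myelin > background). Where no class reaches the
threshold the pixel falls back to the per-pixel argmax rather than being
forced to background: forcing background there fragments thin myelin rings.

Cavity filling takes the "cavities larger than 5 pixels were filled" rule
literally: 4-connected background components that do not touch the image
border and have **area > 5 px** are relabelled to their enclosing class,
while smaller holes are kept. Because the more common convention is the
opposite (fill *small* speckle holes), the direction is switchable
(`fill_direction = "smaller"`); the literal reading is the default and the
ambiguity is documented rather than silently resolved. A cavity bounded by
both axon and myelin is assigned to the majority boundary class, ties to
axon (mirroring the threshold priority). Hole detection uses 4-connectivity
against 8-connected foreground, the standard duality. Filling is idempotent
and never converts foreground to background.

## Fiber extraction and pairing

Axon instances are 8-connected components, numbered in row-major discovery
order. No annotation says which myelin belongs to which axon, so myelin is
assigned by geodesic proximity *through the myelin class*: a multi-source
breadth-first propagation seeded at the axon components (equivalent to a
seeded watershed on the myelin support). Equal-distance ties go to the
smaller fiber id, deterministically. Myelin not reachable from any axon is
counted as unassigned and reported, never silently attributed. The
brute-force per-source BFS oracle in the tests confirms the partition pixel
for pixel on touching-ring cases.

Shape descriptors come from the axon region alone: eccentricity
$\sqrt{1-\lambda_2/\lambda_1}$ from the eigenvalues of the normalized
second central moments (the inertia-ellipse definition used by common
regionprops tools), and solidity as axon area over the lattice-point count
of its filled convex hull. Selection applies the three thresholds with
*strict* inequalities — eccentricity must exceed 0.95, solidity fall below
0.9, area fall below 50 px for exclusion — so the boundary values
themselves are retained, and every violated criterion is recorded per
fiber. Border-touching fibers are not excluded by default (the criteria do
not mention borders); an `exclude_border` flag exists because truncated
border fibers can inflate errors. The 50 px area threshold is kept in
pixels, with the pixel size recorded alongside, since that is how the rule
is stated at the 0.05 µm/px working scale.

## Reliability statistics

* **ICC(3,1)** (two-way mixed-effects, single rating, consistency):
  $({MS_{rows} - MS_{err}})/({MS_{rows} + (k-1) MS_{err}})$ with the 95% CI
  from the F-distribution method — the closed form used by standard
  guideline software, preferred over bootstrap for comparability. Bands:
  < 0.50 poor, 0.50–0.75 fair, 0.75–0.90 good, ≥ 0.90 excellent; the prose
  convention is ambiguous at the edges, so we fix 0.50 → fair and 0.90 →
  excellent and test those boundaries exactly. Identical columns give ICC
  1 with a collapsed CI. Note the ICC scales by between-subject variance: a
  population designed with a constant g-ratio has none, and the ICC is
  legitimately near zero there no matter how accurate the measurement — the
  agreement scenarios therefore use varying designed g-ratios.
* **Bland–Altman**: bias = mean difference, limits of agreement =
  bias ± 1.96·SD at the 5% level (the classical 1.96 constant exactly;
  `qnorm` for other levels), and proportional bias assessed by regressing
  differences on pair means.
* **Paired comparison**: Shapiro–Wilk on the differences gates between the
  Wilcoxon signed-rank test (zero differences dropped per Wilcoxon's rule;
  exact distribution up to 25 untied nonzero pairs, normal approximation
  with continuity and tie corrections above) and the paired t-test. The
  signed-rank machinery is base R's `wilcox.test`; the test suite checks it
  against full $2^8$ sign enumeration at $n=8$.
* **Parallel sections**: fixed-effects one-way ANOVA across sections from
  the same nerve, with a seeded type-I calibration (rejection rate at
  $\alpha = 0.05$ over 200 same-population repeats) in the acceptance
  tests.

Automated and ground-truth fibers are paired by maximal axon overlap
(`match_fibers()`); unmatched fibers are dropped from paired analyses and
visible in the counts.

## The phantom generator

`generate_scene()` is first-class, tested code, not a fixture: it defines
the study conditions for every quantitative check. Fibers are elliptical
annuli — the myelin outer ellipse is the axon ellipse scaled by
$1/g$, so the designed g-ratio is exact by construction — placed disjointly
by rejection sampling, rasterized by a pixel-center-inside test so that
pixel-count oracles agree with the mask exactly. Defaults: axon semi-minor
radii uniform in 8–20 px (0.8–2 µm diameters at 0.05 µm/px, the dominant
size range in mouse sciatic nerve), designed g-ratio 0.6 (the
conduction-optimal value), near-circular aspect ratios (≤ 1.1), additive
Gaussian noise with SD 0.02 on a [0, 1] intensity scale and optional
Gaussian blur — mild imaging degradations of the kind the training
augmentations also emulate.

Designed defects sit *strictly beyond* the selection thresholds so that
designed rejections are exact rather than marginal: oblique fibers use axis
ratio 0.18 (continuous eccentricity ≈ 0.984), incomplete fibers have a
110° wedge cut through axon and myelin (axon solidity ≈ 0.8; the wedge cuts
the axon because selection filters on axon morphometrics), and undersized
fibers use r = 3 px (≈ 29 px axon area). Two stain styles provide the
contrast structures of PPD-like (dark ring / mid-gray axon / light
background) and TB-like (softer ring contrast, textured background)
appearance.

What the phantoms do **not** emulate: Schwann cell nuclei, blood vessels
and other non-fiber structures; stain-specific texture inside myelin;
uneven illumination; annotation noise; the spatial packing statistics of
real fascicles (density is a free parameter, not fitted). Passing phantom
tests therefore demonstrates that the pipeline's geometry, selection logic
and statistics are correct, and that the network can learn this contrast
structure — not that the shipped defaults segment real histology at the
published accuracy; that requires training on annotated sections.

## Numerical choices and degenerate inputs

* Coordinates are row-major with the origin at the top-left; continuous
  coordinates are 0-based (pixel $(i,j)$, 1-based in R, has center
  $(i-1, j-1)$), and on-disk tables use the 0-based convention.
* Probability maps must sum to 1 per pixel within 1e-5; Dice of two empty
  masks is defined as 1.0 (the 0/0 convention, documented and tested).
* Argmax ties and threshold ties resolve by class priority axon > myelin >
  background; component ids and BFS ties resolve to the smaller id — every
  tie-break is deterministic, which is what makes byte-identical reruns an
  invariant worth testing.
* Empty inputs: an all-background mask yields an empty fiber set (not an
  error); an empty training set, mismatched shapes, missing ICC cells and
  length-mismatched paired vectors fail fast with actionable messages.
  Degenerate statistics (all differences zero; zero subject variance) are
  flagged, not fudged.
* Problem sizes in the shipped tests are desk-scale by design: 64–1024 px
  phantoms, 50-fiber recovery scenes, a 15-train/5-test 256 px training
  run, 200-repeat type-I calibration. The vignette's numbers are computed
  by those tests and the acceptance script, never copied in.

## Known limitations

* The exact diameter and thickness estimators used in published pipelines
  are usually unstated; estimator choice matters for axon diameter in
  particular, and the equivalent-diameter default here, while robust, is
  one of several defensible conventions.
* Whole-slide formats (NDPI) and viewer integrations are out of scope; the
  pipeline consumes extracted PNG/TIFF patches.
* The network backend ships untrained; users must train on their own
  annotations (or phantoms) before the `network` backend is meaningful.
* Merged axons are not split: connected-component instancing assumes the
  segmentation separates adjacent fibers, which held in the imagery this
  design targets.
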