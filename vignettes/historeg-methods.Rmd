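---
title: "Methods: composite atlas registration and cell quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite atlas registration and cell quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Anatomical analysis of coronal mouse-brain histology needs every experimental
section mapped onto a reference atlas so that signals (labeled cell bodies,
ISH-positive pixels) can be counted per brain region. Sections are cut with
small, unknown deviations from the true coronal plane, and mounting introduces
both global (rotation, scale, shift) and elastic (local stretch, tears)
distortion. `historeg` models this with three components: an oblique *pose*
locating each section inside the 3D atlas, a *composite transformation*
(affine followed by a B-spline free-form deformation) aligning the atlas slice
to the tissue, and a tiled blob detector plus per-region tally that turn
alignments into counts.

## Section pose and oblique slicing

A pose is `(x_angle, y_angle, ap_index)`: the slicing-plane normal is the
anterior–posterior (AP) axis rotated first toward left–right by the x cut
angle, then toward dorsal–ventral by the y cut angle; `ap_index` is the
(fractional) position along the AP axis, 0 anterior. Angles live in
[-10°, 10°] and normalize affinely to [0, 1] (`(a + 10) / 20`); the AP index
normalizes by its maximum (1,324 for a 10 µm full-brain volume). The rotation
pivots at the section's center point on the AP axis; the paperless details —
sign convention, order (x then y), and pivot — are fixed here and tested by a
supersampled brute-force plane sampler. Intensity is sampled trilinearly,
labels by nearest neighbor, and out-of-volume samples are zero-filled to match
the zero-padded registration margins.

The learned pose predictor of a full deployment is abstracted as a callable
`256×256 image -> normalized triple`. Two implementations ship: a constant
stub, and a weights-free nearest-template matcher (normalized
cross-correlation of Sobel-gradient thumbnails against evenly spaced atlas
slices) that recovers the AP position and leaves cut angles to user
fine-tuning, which is file-based: users edit `poses.json` between the
`predict` and `align` steps. Per-section angle estimates are pooled by their
arithmetic mean and re-applied to all sections, since sections from one brain
share the blockface angles.

## Preprocessing

Registration compares *gradient* images: both images are resized to the
360×360 working size (area averaging when shrinking, bilinear when
enlarging; the aspect ratio is deliberately not preserved), converted to
Sobel gradient magnitude, min–max normalized to [0, 1], zero-padded by 50 px
to mitigate boundary effects, and the moving (atlas) gradient image is
histogram-matched onto the fixed one: a piecewise-linear remap through 10
quantile match points over 1,024 histogram levels, applied only to pixels
above the moving image's mean so the (background) lower intensity range is
preserved. Histogram matching operates on the gradient images, not the raw
intensities — an ordering the source material leaves open; matching gradient
distributions is what the mutual-information metric actually compares, so we
match there and flag the choice here.

The ISH signal chain is separate: invert, quantize to 8 bit
(`round(255·(1 − (x − min)/(max − min)))`, round-half-even; constant images
map to 255), and threshold strictly above 125.

## The composite registration

**Transform convention.** The affine stage is stored push-forward — a moving
point `x` lands at `A(x − c) + c + b`, so a moving image shifted +10 px is
aligned by `b = (−10, 0)` — and images are resampled through its closed-form
inverse. The B-spline stage is the standard pull-back free-form deformation
`out(x) = in(x + u(x))`, with `u` a cubic B-spline field over a 4×4-cell mesh
spanning the padded working frame ((mesh+3)² control points including the
cubic boundary padding). The composite is affine resampling followed by
B-spline resampling; ground-truth transforms from the synthetic generator use
the same representation, so recovery can be compared either in parameter
space or (preferred, since B-spline parameterizations are not unique) by
label Dice.

**Metrics.** The affine stage minimizes negated Mattes-style mutual
information: a joint histogram over 32 bins per axis with first-order
(linear) Parzen windows on both marginals. The linear window is chosen so
that a two-valued image placed at the bin ends yields point masses, making
`MI(x, x) = H(x)` exactly — an oracle-checkable identity a cubic window never
satisfies. The B-spline stage minimizes negated mean local (neighborhood)
correlation: the Pearson correlation in a 7×7 window (radius 3 px at working
resolution) around every pixel, border-clipped, averaged over windows whose
intensity variation is non-negligible. A `bspline_metric = "mi"` switch is
provided because the source descriptions of this stage's metric conflict;
neighborhood correlation is the default. Windows whose sum of squared
deviations falls below 1e-6 are excluded: the threshold sits far above the
cancellation error of the integral-image window sums (~1e-11 at this image
size) so numerically flat windows can never inject `1/sqrt(var)` noise into
the metric or its gradient.

**Optimization.** "Gradient descent with learning rate 0.01, 300 iterations,
convergence when the metric changes less than 1e-8 over a 20-iteration
window" is implemented as scaled gradient descent with backtracking step
relaxation: parameters are scaled so a unit step moves image content by about
one pixel (matrix entries scale with the image half-diagonal, translations
and control points with 1), the initial step length is `learning_rate ×
image width` pixels, an accepted step grows the length 1.2×, a rejected
(metric-increasing) step is undone and halves it, and the stage stops at the
iteration cap, when the accepted-metric standard deviation over the
convergence window drops below 1e-8, or when the step underflows 1e-4 px.
Affine gradients are central finite differences over the 6 parameters (the
metric uses every pixel — no stochastic sampling — so the whole registration
is deterministic); B-spline gradients are analytic, chaining the metric's
per-pixel derivative through the warped image's sampled gradient onto the
control points. The affine stage runs over a 3-level pyramid (shrink 4, 2, 1;
Gaussian smoothing sigmas 2, 1, 0); the B-spline stage runs at full
resolution only. After the affine stage the *moving* (atlas) image is
resampled and the B-spline stage continues from it; the alternative reading
(resampling the fixed image) appears to be a slip in the source description
and is not followed.

**Masking.** A damage mask is a fixed-frame exclusion map: masked pixels are
dropped from both metrics' sample sets (for local correlation, from both the
window centers and the window statistics), and the corresponding pixels of
the warped atlas are zeroed in the output. The zero-padding margin itself
always counts as valid background.

**Output geometry.** The composite is defined on the padded 360+2·50 working
frame. Warped atlas intensity (linear) and annotations (nearest-neighbor —
warped label images can contain no ids absent from the source annotation) are
cropped back and resized to the fixed section's native resolution; the
affine-only warp of the labels is returned too, so the contribution of the
deformable stage is measurable per section.

## Tiled detection and quantification

Large signal-channel images are tiled into 640×640 tiles with 50% overlap
(edge tiles anchored at the border; sub-tile images zero-padded), a pluggable
detector runs per tile, boxes are remapped to global coordinates, clipped,
confidence-filtered and merged by greedy non-maximum suppression at IoU 0.5
(ties broken by earlier index). The plug-in contract (`tile -> detections`)
lets a trained object detector drop in without code changes; the shipped
default is classical: a scale-normalized difference-of-Gaussians stack over
the blob radius range with 26-neighborhood maxima. Its two defaults are
calibrated from the blob model, not tuned to any test: a Gaussian blob of
amplitude A has DoG response ≈ 0.44·A nearly independent of radius, while
pure sensor noise of SD 0.1 peaks below ≈ 0.13, so the response threshold
0.17 separates half-contrast blobs (≈ 0.22) from the noise ceiling, and
confidence = response / 0.44 approximates blob contrast. The per-experiment
confidence threshold (default 0.25) remains the user's knob for learned
detectors.

Counting is by box center: each detection is tallied under the label id at
its center pixel, with background centers reported as "unassigned" rather
than dropped, so per-region cell counts plus unassigned always sum to the
number of detections; the analogous conservation holds for signal-mask
pixels. Ontology roll-up walks parent links to the nearest requested
ancestor in integer arithmetic, preserving totals exactly.

## The synthetic phantom

Every stage is testable without external data through a phantom study. The
phantom volume is a smooth ellipsoidal "brain" whose dorsoventral extent
tapers toward the anterior pole (so AP positions are identifiable, as in a
real brain), carrying `n_regions − 1` concentric layer labels plus one
bilateral deep nucleus; intensity is a smoothed region-dependent value field
with seeded noise. Deformed "experimental" sections are produced by slicing
at a known pose, optionally resampling to a microscope-like section size
(deformation amplitudes are expressed in section pixels), applying a known
affine and a seeded random B-spline field, then gamma and additive noise to
the intensity only — the exact transform and its warped labels are returned
for closed-loop scoring. Synthetic cells are Gaussian blobs with minimum
center spacing inside a region mask; a blob of radius r has sigma r/2 and
ground-truth box center ± r.

The default study conditions used by the test suite and the acceptance
script are: a 48×72×72 phantom with 5 regions; sections rendered at 360 px;
deformations up to 5° rotation, 10 px translation and 6 px elastic control
amplitude with 2% additive noise (the "moderate mounting distortion" regime);
150–200 synthetic cells of radius 4–7 px and contrast 0.5–1.0 over noise of
SD 0.05 (SNR 10–20). Ten registration seeds and an eight-section end-to-end
fixture keep the full suite within a desk-scale compute budget; the phantom's
geometry is far cleaner than real histology (no staining variation, no tears
beyond the simulated masks, no out-of-plane curvature), so passing these
tests demonstrates correctness of the machinery and recoverability of known
ground truth, not performance on real tissue.

## Numerical choices and degenerate inputs

* Constant images: zero Sobel output, MI defined as 0 (no information),
  all-zero moving images fall back to geometric-center initialization with a
  warning.
* Mattes MI intensity binning maps the observed min/max to the first/last of
  the 32 bins; masked or out-of-domain samples contribute nothing.
* Fractional AP indices are allowed (linear interpolation between planes) so
  fine-tuning can move in sub-index steps.
* Label images are resized/warped by nearest neighbor everywhere; every
  label-processing path asserts the no-invented-ids property.
* The hemisphere crop used by the training-sample generator takes the left
  or right half of the width axis with equal probability; poses are recorded
  pre-crop.
* All randomness flows through one explicit seed per operation (`with_seed`
  saves and restores the session RNG); the registration itself contains no
  randomness.
* JSON transform files store doubles with 17 significant digits and
  round-trip bit-exactly.

## Known limitations

* Only coronal sections of a single-volume atlas are supported; sagittal or
  horizontal slicing and multi-atlas support would need new pose
  conventions.
* The affine/B-spline capture range is bounded: initial pose errors beyond
  the pyramid's coarsest level (~1/4 of the field of view) or elastic
  distortions far beyond the 4×4 mesh's spatial scale will not be recovered;
  that is what the fine-tuning loop is for.
* The default blob detector assumes roughly isotropic, roughly Gaussian cell
  bodies on a level background; heavily textured backgrounds need a trained
  detector via the plug-in interface.
* Whole-tissue Dice against the Otsu tissue mask is the default alignment
  quality measure; per-region evaluation is available (`label_dice`) but
  depends on the annotation granularity.
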