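---
title: "Quantifying vesicle co-trafficking by binary pixel overlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vesicle co-trafficking by binary pixel overlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesicoloc)
```

## The measurement

The package quantifies how much of one fluorescent label travels with
another inside a cell — for example, how much internalized
cholesterol-conjugated siRNA shares endosomes with EGF versus
transferrin. The measurement is deliberately simple and object-free:

1. **Vesicle-matched filtering.** Each 2D plane is convolved with a
   difference of Gaussians (DOG): a narrow Gaussian of unit area
   (σ = 150 nm) acts as a matched detector for a near-diffraction-limited
   spot, and a wider inverted Gaussian of negative unit area (σ = 300 nm)
   estimates and subtracts the local background. Both σ are physical
   (nm) and converted to pixels via the image calibration, so the same
   parameters work across instruments.
2. **Global thresholding and binarization.** The filtered image is
   thresholded with a single global threshold and every pixel above it
   is set to 1, all others to 0, giving a binary detection mask per
   channel.
3. **Pixel-overlap percentage.** For binary images A and B at time *t*,
   the percent co-localization of "B with A" is
   `100 · ΣΣ[A(x,y,t)·B(x,y,t)] / ΣΣ B(x,y,t)` — the fraction of B's
   detected pixels that also carry A. The normalization is asymmetric;
   `coloc_percent()` always computes and stores both directions, and
   `coloc_threeway()` extends the numerator to a triple product.
4. **Rotation null.** Chance overlap is estimated by rotating one
   binary channel by 180° in-plane and re-evaluating the same equation.
   At realistic detection densities this control should stay below 1%;
   values near the genuine signal indicate that overlap is driven by
   sheer mask density, not co-trafficking.
5. **Whole-cell integration.** Z-stacks are analysed as 500 nm optical
   slabs (consecutive slices maximum-projected); numerator and
   denominator pixel counts are pooled across slabs before the ratio is
   formed, then per-cell percentages are aggregated per time point as
   mean ± SEM over cells and compared with a two-tailed two-sample
   t-test.

## Parameters that matter

| Parameter | Default | Unit | Notes |
|---|---|---|---|
| `sigma_small_nm` | 150 | nm | spot-matched detector width |
| `sigma_large_nm` | 300 | nm | local-background estimator width |
| `truncation_sigmas` | 4 | σ_large | kernel half-extent; each truncated Gaussian is renormalized to sum exactly 1, so the kernel is zero-sum to machine precision |
| `threshold$method` | `"otsu-positive"` | — | Otsu's criterion restricted to strictly positive filtered values |
| `threshold$scope` | `"stack"` | — | one threshold per channel per stack |
| `slab_nm` | 500 | nm | optical-slab thickness |
| `flank_px` | 10 | px | perinuclear readout distance outside the nucleus |

## Design choices where the procedure was open

**Automatic thresholding.** The original thresholds were chosen by eye
and are unrecoverable, so the default is deterministic: Otsu's
criterion applied to the strictly positive filtered values only. After
zero-sum DOG filtering the background fluctuates around zero; the
positive tail is a two-component mixture (noise shoulder vs. spot
responses) that Otsu separates cleanly. Every threshold actually used
is recorded on the mask, in the per-slab table and in the run log, and
a fixed per-channel value can be forced through the config.

**Threshold scope.** One global threshold per channel per *stack*
(pooling the filtered values of all slabs) is the default, not one per
slab. This matters: in a tall stack many slabs contain no vesicles at
all, and a per-slab Otsu would happily split pure noise, flooding
empty slabs with speckle that both inflates the apparent overlap and
destroys the rotation null. With the stack-wide threshold, slabs devoid
of signal produce empty masks. Per-slab thresholding remains available
(`threshold$scope = "slab"`) for sensitivity analysis.

**Pooling, not averaging.** "Integrated for the whole cell" is
implemented by summing numerator and denominator pixel counts across
slabs and forming a single ratio. This weights each slab by its signal
content and is well defined when some slabs are empty; averaging
per-slab percentages (available via `aggregate = "mean"`) would weight
a nearly-empty slab as heavily as a dense one.

**Projection.** Slices within a slab are combined by maximum
projection before filtering, preserving punctate peaks for a detector
tuned to spots; a mean projection would dilute a vesicle present in
one slice of five. Filtering each slice first and max-projecting the
filtered responses is exposed as `filter_per_slice = TRUE`.

**Rotation on the mask.** The 180° control rotates the *binary mask*
(index reversal on both axes, exact for any parity) and re-applies the
identical equation, since the equation itself operates on binary
images. Rotating the raw image and re-thresholding would entangle the
null with threshold stability.

**Undefined, never zero.** A zero denominator yields an undefined
(`NA`) percentage that is excluded (and counted) during aggregation. A
cell with an empty channel must not masquerade as "0% co-localization".

**Boundary handling.** Convolution uses symmetric reflection padding.
Zero padding would manufacture bright rims — spurious "vesicles" — at
the image border of any image with non-zero background.

**Statistics.** The default two-sample test pools variances (classic
Student's test), with Welch's variant one flag away. No
multiple-testing correction is applied by default, matching the
per-timepoint starring convention (* P<0.05, ** P<0.01, *** P<0.001);
corrections can be applied downstream on the emitted p-values.

**Coordinates.** All pixel coordinates are 1-based `(y, x)` per R
convention; stacks are stored `(channel, z, y, x)` with a singleton z
for 2D images.

## The synthetic-scene generator

Because the pipeline's accuracy cannot be validated on real images
without ground truth, `simulate_scene()` renders calibrated scenes
with known answers: puncta as isotropic 2D Gaussians (σ = 130 nm,
near-diffraction-limited and consistent with the 150 nm matched
detector) at uniform-random positions, a designated fraction of the
paired channel's puncta sharing positions (optionally jittered to
model registration error), a constant offset (10 counts) plus a broad
membrane-like Gaussian field (peak 5 counts), then Poisson shot noise
and Gaussian read noise (σ = 2 counts). Peak amplitude defaults to the
value giving peak SNR 10 (`amplitude_for_snr()`). A minimum
within-channel separation of 5 PSF σ guarantees that a
`coloc_fraction = 0` scene contains no accidental co-location, so the
ground truth is exact. Scenes are fully determined by their seed, and
`scene_battery()` derives distinct per-scene seeds from one master
seed.

What the generator does *not* emulate: 3D PSFs (puncta live on single
z-slices; the pipeline only ever analyses 2D slabs), vesicle motion and
photobleaching, structured-illumination reconstruction artifacts,
camera fixed-pattern noise, and the crowded, heterogeneous vesicle
populations of real cells. Passing the validation suites therefore
shows the measurement chain is correct and calibrated on idealized
punctate scenes — not that biological images will be as clean.

## Validation suites and problem sizes

The test suite validates each stage against independent brute-force
oracles (dense convolution loops, pixel-by-pixel overlap counting,
hand-computed t statistics), then exercises the full chain:

- *Recovery*: 512×512 single-plane scenes, 50 puncta/channel, SNR 10,
  20 replicates at true co-located fractions {0, 0.25, 0.5, 0.75, 1}.
  The mean measured percentage must increase strictly with the true
  fraction, exceed 90% at fraction 1 with zero jitter, stay below 2%
  at fraction 0, and object-level (centroid-matching) recovery must
  track the true fraction within 0.1 mean absolute error.
- *Null calibration*: 20 whole-cell scenes in the target acquisition
  geometry — 10 µm stacks, 100 nm slice spacing, 512×512 at
  100 nm/pixel, 50 puncta/channel placed independently between
  channels — analysed as 500 nm slabs with whole-cell pooling. The
  180° rotation null must stay below 1% in at least 95% of scenes. The
  whole-cell geometry is essential here: chance overlap between two
  sets of only 50 objects on a *single* plane is dominated by rare
  single-spot collisions, each contributing 1–2% on its own; pooling
  over ~20 slabs dilutes such collisions exactly as integrating over a
  real cell volume does.

`scripts/acceptance.R` re-runs the null calibration from scratch at a
caller-supplied seed and reports the 95th percentile of the per-scene
null percentages.

## Known limitations

- The Otsu-positive threshold assumes at least some genuine spots per
  stack; on a truly empty channel the mask is empty by construction
  (threshold +Inf) rather than estimated.
- Pixel overlap is resolution-dependent: percentages measured at
  different pixel sizes or PSF widths are not directly comparable.
- The rotation null estimates density-driven chance overlap only; it
  does not control for structured backgrounds that are themselves
  centro-symmetric.
- Non-integer intensity data round-trips TIFF storage at 32-bit float
  precision (integer data up to 16 bits round-trips exactly).
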