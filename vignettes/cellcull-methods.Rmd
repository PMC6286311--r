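---
title: "cellcull: models and methods of the in-silico laser purification loop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cellcull: models and methods of the in-silico laser purification loop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The system being modelled

Spontaneously differentiated cells appearing inside otherwise
undifferentiated hiPSC cultures are a persistent quality problem: they are
rare, scattered, and removing them by dissociation-based sorting sacrifices
yield and cell state. An indirect photothermal approach solves this in situ:
the culture grows on a thin azobenzene-polymer layer that converts a scanned
405 nm laser beam into sharply localised heat (the cells themselves absorb
almost nothing at the working fluence), so sweeping the beam at
100 mm/s while switching it on only over target regions kills the targeted
cells through the substrate without touching their neighbours. Targets are
found label-free: a small convolutional classifier reads 70 x 70 pixel
patches of phase-contrast images and flags differentiated morphology,
trained beforehand against ground truth provided by an rBC2LCN fluorescent
probe (which binds undifferentiated cells), so the probe is needed only at
training time, never at deployment.

`cellcull` reproduces this entire loop in software: a seedable synthetic
microscope, the patch classifier and its two-round hard-example-mining
training procedure, a gated scan-path planner with dose accounting, a
finite-difference photothermal model of the substrate, a calibrated kill
rule, and a flow-cytometry-style purity readout of the survivors.

## Synthetic culture fields

`generate_field()` renders a phase-contrast / fluorescence frame pair with a
per-pixel ground-truth mask (background, undifferentiated, differentiated)
and a matched point-cell population. Design choices:

* **Geometry.** Frames default to 1920 x 1200 px, the native tile geometry
  of whole-dish imaging devices for adherent culture. No optical
  magnification is fixed by the model, so the physical pitch
  `pixel_size_um` is an explicit parameter defaulting to 1 um/px, which
  makes a frame about 1.9 x 1.2 mm and keeps geometric arithmetic
  transparent. All modules share one coordinate convention: origin at the
  top-left pixel center, x rightward, y downward, micrometers = pixel index
  x pitch.
* **Colonies** are wobbled discs (low-order angular modulation of the
  radius) kept strictly disjoint by rejection-sampling their centers against
  pairwise separations. Disjointness matters: overlapping colonies would
  make the realised differentiated area fraction systematically deviate
  from its target, and that fraction is the controlled variable of the
  purification benchmark. Radii default to 150-280 um, typical of hiPSC
  colonies a few days after passage.
* **Differentiated patches** are contiguous wobbled sub-discs of area
  fraction `differentiated_fraction` (default 0.2) placed inside each
  colony. The per-colony area ratio is deterministic, so the realised
  fraction tracks the target closely (empirically 0.200 +- 0.001 across
  seeds).
* **Texture.** The classifier must have a learnable phase-contrast signal,
  so the two classes differ in granularity and local contrast:
  undifferentiated texture is fine-grained Gaussian-filtered noise
  (sigma 0.8 px, sd 4500 counts) with a bright halo ring at the colony rim,
  mimicking phase-contrast edge artefacts; differentiated texture is
  coarser (sigma 3.5 px) and of lower contrast (sd 2200). Additive sensor
  noise (default sd 300) covers both channels.
* **Fluorescence** is high (default 30000) exactly on undifferentiated
  colony pixels and low (3000) elsewhere, mirroring an rBC2LCN-type probe;
  thresholding it at the class midpoint recovers the mask essentially
  exactly at default noise.
* **Cells** are Poisson-sampled in colony footprints at 0.005 cells/um^2
  (about 50 cells in a 100 um square, a dense monolayer of ~10 um cells),
  typed by the mask at their center.

What the generator deliberately does *not* emulate: photorealistic
phase-contrast optics, feeder cells, colony growth, gradual differentiation
boundaries, or imaging artefacts such as vignetting and stitching seams.
Tests passing on these fields therefore demonstrate the correctness and
internal consistency of the pipeline, not classifier performance on real
microscopy.

## The patch classifier

The architecture is the fixed chain: 70 x 70 single-channel input, 32
convolution filters of 5 x 5, max pooling 3 x 3, 32 filters of 3 x 3, max
pooling 2 x 2, and a fully connected layer to 2 class logits trained with
softmax cross-entropy. With unpadded ("valid") convolutions and pool stride
equal to the pool kernel, the spatial chain is 70 -> 66 -> 22 -> 20 -> 10,
giving the head 10 x 10 x 32 = 3200 features. Those two conventions, the
ReLU activations after each convolution, and the direct-to-2-classes head
are implementation conventions chosen because they yield this clean size
chain; they are recorded here rather than asserted as facts about any
particular hardware classifier.

Training specifics the architecture does not fix are collected in
`train_hyper()`: Adam at 1e-3, batch 32, 8 epochs per round, per-patch
standardization to zero mean / unit variance, and inverse-frequency class
weighting in the loss (randomly cropped patches are dominated by the
undifferentiated class, roughly 4:1 at the default fraction). Every
stochastic step (initialisation, cropping, shuffling) draws from R's RNG
under a caller-supplied seed, so training is bit-reproducible.

The implementation is the package's own: im2col unrolling plus BLAS matrix
multiplication in C++ for the forward and backward passes, with the Adam
update in R. Its forward pass is verified in the test suite against an
independent plain-loop implementation to 1e-6, and its gradients were
verified against central finite differences during development.

**Two-round hard-example mining.** Round 1 trains on randomly cropped
patches. The fitted model is then applied to non-overlapping grid patches of
the training frames, and every undifferentiated patch it misclassifies as
differentiated (probability >= 0.5) is added to the training set; training
then *continues from the round-1 weights* on the augmented set. Retraining
from scratch would also be defensible; fine-tuning was chosen because it
makes the second round a strict corrective step and empirically never
increases the false-differentiated count, which is the property the
procedure exists for (over-eager differentiated calls translate directly
into killed healthy cells).

**Inference** uses the phase channel only. `predict_map()` tiles the frame
with 70 px windows at a configurable stride, writes each window's
differentiated probability to all pixels it covers, averages overlaps, and
fills the uncovered right/bottom margins from the nearest covered pixels.
Stride 70 reproduces block-wise assignment; the closed loop defaults to
stride 35, which smooths the map across patch boundaries at 4x cost.

## Scan planning, gating and dose

The beam deposits `P/v` joules per mm of line (0.01 J/mm at 1 W and
100 mm/s) and, spread over its width `w` (default 50 um), a flux of
`P/(v w)` = 0.2 J/mm^2. These identities, their linearity, and the
invariance of dose across equal-`P/v` pairs are closed-form and tested
exactly.

`plan_pattern()` builds line families over rectangles or discs: `raster`
(one family at the line interval, the purification pattern at 25 um),
`lattice` (two orthogonal families, the sectioning pattern at 450 um),
plus outline and single-line patterns. Lines are clipped to the region, so
a circular dish yields chords whose total length converges to area/interval
(within 1% at 100 um on a 5 mm disc). Serpentine ordering minimises travel
and affects no reported statistic.

Per-line turnaround overhead is real on hardware but unpublished, so the
default is 0 s and the device's printed totals (86 s for whole-dish
sectioning, 667 s for whole-dish purification) are treated as upper bounds
on the computed active time; a `turnaround_s` knob exists for matching real
devices. The effective scannable dish area is taken as 9 cm^2 modelled as a
disc of that area.

`gate_path()` switches the beam on exactly where its centerline crosses
target pixels (probability >= threshold, default 0.5, or the differentiated
mask class). By default the target is first dilated by half the beam width
so edges receive full-width coverage - a conservative choice that trades
yield for purity. Gating is resolved by sampling the centerline at half a
pixel, so ON interval ends are accurate to ~0.5 px.

`accumulate_dose()` rasterizes the ON spans: every pixel within `w/2` of an
ON span accrues the path flux, and overlapping passes sum.

## Photothermal model

The substrate surface is modelled in 2-D:
`dT/dt = D lap(T) - lambda (T - T_amb) + S`, integrated by explicit FTCS
with Dirichlet ambient boundaries on a domain padded well beyond the
trajectory. The 2-D choice is justified by the thin-layer geometry: the
published observables (diffusion coefficient ~0.1 mm^2/s, ambient 29.5 degC,
comet timing) are all surface quantities. The automatic time step is 0.4 of
the stability bound `h^2/(4D)`; a user-supplied step violating the bound
aborts with the admissible value. The source is a top-hat disc of the beam
diameter by default (matching the planner's width assumption; Gaussian
optional), carrying the absorbed power `P (1 - 10^-A)` with A = 0.25 at
405 nm.

The layer's areal heat capacity and interface losses are not published, so
they are collapsed into two constants: `coupling` (degC mm^2/J) and
`loss_rate_s` (1/s). `scripts/calibrate_thermal.R` fits them once against
the two observed behaviours of the coated dish under a 0.3 W, 80 mm/s,
50 um beam - peak surface temperature above 50 degC at the spot, and
relaxation of a scanned point back to physiological 37 degC on the ~10 ms
scale. The frozen defaults are `coupling = 700`, `loss_rate_s = 30`, which
give a 57 degC peak, a 0.55 ms rise (10% to 90% of peak excess; the beam
crosses a point in w/v = 0.625 ms at this speed, and at Peclet number
v w / D = 40 diffusive pre-heating ahead of the spot is negligible), a
9.3 ms decay to 37 degC, and a comet tail length equal to speed x decay
time within a few percent - the kinematic identity of a steadily moving
source. Zero coupling reproduces the uncoated-dish control: the field stays
exactly at ambient.

Numerical verification in the suite: agreement with the continuous
point-source closed form `dT = Q/(4 pi D) E1(r^2/(4 D t))` to better than
2% at 5 um grid; conservation of excess heat to 3e-5 relative over 1e4
steps with losses off; monotone decay of extrema; peak change under grid
halving ~1%; and locality - 200 um off the scan line the field never
exceeds 30 degC at the calibrated settings, consistent with the absence of
neighbour damage.

One observation the model does not resolve: reported kill conditions at
high speed (4.4 W at 1000 mm/s, dose 0.0044 J/mm) succeed with *less*
dose per length than the 100 mm/s threshold (0.8 W, 0.008 J/mm), so dose
alone cannot be the kill criterion across speeds. The package therefore
exposes both a dose-threshold rule and a peak-temperature rule rather than
asserting a mechanism; the closed loop runs at the single deployed speed,
where the calibrated dose threshold is exact by construction.

## Kill rule and purity readout

`calibrate_kill()` sets the dose threshold to the flux of the lowest
reliably killing condition, 0.8 W at 100 mm/s over 50 um = 0.16 J/mm^2.
Death is binary at the cell center - no partial damage, no bystander death -
mirroring sharply local killing; the ~50 um death swath emerges from the
beam width, not from an extra parameter. A 0.7 W pass at the same speed
(0.14 J/mm^2) is sub-threshold and kills nothing, reproducing the
sub-threshold lanes of a power-series scan.

`purity_report()` and `flow_analog()` score the survivors the way a
TRA1-60 flow readout would: dead cells are excluded from the harvest
(assumed washed away before collection - a documented assumption of the
analogy), and purity is the undifferentiated fraction among live cells. A
population with no survivors yields an explicitly flagged undefined purity,
never a division error.

## The closed loop and what its numbers mean

`run_closed_loop()` chains everything: synthesise training fields and a
held-out field (all seeds derived deterministically from one run seed),
train with two-round mining, render the held-out probability map from phase
contrast only, gate a 25 um raster at 0.8 W / 100 mm/s, rasterize dose,
kill, and report. Oracle targeting (gating on the ground-truth mask) gives
the upper bound; it reaches 100% purity up to boundary-cell effects.

At the default study conditions - 20% differentiated area, ten seeds - the
CNN-targeted loop purifies from ~80% to above 99% survivor purity, which is
the package's in-silico analogue of a >= 97% TRA1-60-positive flow readout
after automated elimination. The analogy's limits are stated above: the
synthetic textures are easier than real morphology, so the loop should be
read as validating the machinery (geometry, gating, dose, accounting) and
the training procedure, not as a claim about classifier accuracy on real
dishes. Survivor *yield* is deliberately sacrificed by the conservative
dilation and 0.5 threshold; purity, not yield, is the figure of merit here.

Problem sizes were chosen to keep a full verification run on a single CPU
comfortable: unit tests run on 700 x 500 px fields, while the benchmark and
closed-loop checks use the native 1920 x 1200 geometry with 2 training
fields, 250 random crops per field and 8 epochs per round (about a minute
per seed).

## Known limitations

* The texture model is the weakest link to reality; anyone applying the
  classifier to real frames should retrain on real probe-labelled data via
  `extract_patches()` + `train_with_mining()` - the pipeline is agnostic to
  where its frames come from.
* The thermal model is 2-D and lumps unknown layer physics into two fitted
  constants; it reproduces surface observations but is not predictive
  across substrates.
* The planner models ideal kinematics: zero turnaround by default, no
  acceleration profiles, no focus dynamics.
* The kill mechanism across speeds is left open (see above); only the
  deployed-speed calibration is used for scoring.
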