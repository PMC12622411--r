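---
title: "Decoding facial valence in mice: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding facial valence in mice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(facevalence)
```

`facevalence` implements a complete pipeline for reading emotional
valence off the mouse face: appearance descriptors and valence
prototypes, cross-animal registration, keypoint kinematics, learned
decoders with interpretability probes, and coupled fiber-photometry
analysis. This vignette explains the science behind each stage, the
parameters that matter, and the choices made where the design was
genuinely open. It states no empirical result that the package's tests
and acceptance script do not themselves compute.

## The synthetic cohort generator

No public recordings exist for this paradigm, so the package ships a
generator that emulates the study's conditions and provides ground truth
for every downstream claim.

**Faces are schematic, not photorealistic.** Every analysis in the
pipeline consumes either geometry (keypoint coordinates) or local
intensity gradients (HOG, motion energy, CNN features). A vector-drawn
face — head ellipse, ear quadrilateral, eye with pupil, nose, mouth
polyline, three straight whiskers — provides both, with the decisive
advantage that the 37 keypoints are the exact construction points: angle
and distance oracles recover the generating parameters to machine
precision, which turns "does the pipeline recover the truth?" into a
sharp test.

**The phenotype has ten fields**, one per measured facial feature: ear
angle (pinna direction vs the +x axis, degrees), ear length, ear width,
ear fold (interior angle at the pinna tip), mouth inclination (interior
angle at the inner eye corner between the nostril centre and the lower
lip), snout–mouth length, nose extension, whisker angle (vs the −x
axis), pupil diameter and eye opening. Lengths are pixels of the 256-px
reference canvas and scale linearly with the render canvas; angles are
canvas-invariant. Image coordinates are y-down; all angles are defined
in the y-up mathematical frame, a convention fixed once and used by both
the generator and the geometry oracles.

**Valence structure.** Per-stimulus additive offsets encode the
qualitative pattern reported for real mice: sucrose and NaCl share
offset signs, bitterness and shock share the opposite signs, the ear
angle moves in opposite directions for the two valences, and the pupil
dilates under every non-neutral stimulus. The source figures report
directions and significance, not effect sizes, so the default
magnitudes (for example +20°/+14°/−16°/−22° of ear angle for
sucrose/NaCl/bitterness/shock) were chosen once for clear recoverability
at desk scale and are scaled globally by `effect_scale`. Each mouse
receives a Gaussian identity offset (SD 1.5 units) drawn once and
applied to all its trials; each frame receives white feature noise
(SD 0.4 units). Within a trial every feature follows baseline →
latency-delayed saturating rise toward baseline + offset → exponential
return (decay 2 s). Latencies follow the reported ordering: whiskers
0.1 s, mouth/snout/ear 0.3 s, pupil and eye 1.0 s.

**Photometry.** The 470 nm channel is a slow photobleaching trend
(exponential toward a floor), a shared low-pass motion artifact,
per-event calcium transients (instant rise, 1 s decay) and white noise;
the 410 nm isosbestic channel carries the scaled trend and the *same*
artifact but no transients. Both channels run at 15 Hz; the hardware's
interleaved 30 Hz acquisition is not modeled, only its per-channel
output. Transient amplitudes follow the neuron type: dopaminergic
amplitudes are ordered sucrose > NaCl > water > bitterness/shock,
GABAergic the reverse, glutamatergic by arousal ({sucrose, shock} >
{NaCl, bitterness}), pan-neuronal flat.

**What passing tests do and do not show.** The generator produces
cleanly separable classes, rigid faces, exact keypoints and white
feature noise. Success on it demonstrates that the estimators are
implemented correctly and recover known structure; it does not
demonstrate robustness to fur, lighting, occlusion, tracking failures or
behavioral states absent from the model.

## Appearance descriptors and expression space

HOG descriptors use 8 unsigned orientation bins and 16 × 16 px cells at
the 1024-px reference input, with the cell size scaling proportionally
at smaller canvases so the descriptor length (32 768) is
scale-invariant. With 1 × 1 cells per block, block normalization
degenerates to per-cell L2 normalization; a zero-norm guard (ε = 1e−12)
leaves gradient-free cells at zero. Frame similarity is plain cosine
similarity, which is scale-invariant and undefined (an error, not NaN)
for zero vectors.

Apex frames are selected in two steps: rank the stimulus frames by mean
cosine similarity to all other frames of the same stimulus and keep the
top 10 ("typical" frames), then return the shortlist member least
similar to the neutral baseline. The one-step reading — jointly maximal
within-stimulus and minimal baseline similarity — is underdetermined
(the two criteria trade off), so the package implements the two-step
procedure, which satisfies both lexicographically; ties break toward the
earliest frame. Subprototype selection reuses the same machinery and
keeps the k best shortlist members.

The unsupervised view reduces HOG matrices to 400 principal components
and embeds them in 2-D. No UMAP implementation is available among the
package's R dependencies, so the embedding is a compact in-package
member of the same family: a fuzzy k-nearest-neighbor graph (n_neighbors
= 45, per-point bandwidths calibrated so the effective neighborhood mass
is log2 k) optimized by attraction along edges and repulsion against
negative samples from a PCA initialization, fully seeded. k-means then
runs on the 2-D coordinates — not the 400-D scores — matching the
convention of drawing cluster centers in the embedding plane; k defaults
to the number of stimulus conditions present, and degenerate inputs
(all frames identical) collapse to a single cluster rather than erroring.

## Registration

Six landmarks (nose tip, inner and outer eye corners, anterior lower
lip, cheek, posterior pinna edge) anchor a least-squares affine fit to
the prototype template, refined by a 4-parameter similarity transform
(translation, rotation, isotropic scale) optimized from the affine
initialization; the refined objective never exceeds the
initialization's. The mentioned contour-similarity term of the original
procedure is not operationalized there, so refinement here minimizes
landmark distances only. Frames are warped by inverse mapping with
bilinear interpolation (out-of-canvas samples take the frame median);
the warp is implemented in-package rather than through an external image
routine because the x/y axis convention of the keypoint tables must
match the image path exactly — the round-trip and composition tests
guard precisely that seam. The red/cyan overlay (unaligned in red,
aligned in green+blue) plus its mean |R−G| colorfulness score provide
the registration QC.

## Prototypes and the drug valence index

The positive prototype is the element-wise mean of the sucrose and NaCl
subprototype HOG vectors, the negative prototype of bitterness and
shock. Prototypes come from a designated prototype mouse recorded in the
cohort manifest and excluded from all evaluation. Scoring a frame stream
yields per-frame `sim_pos`, `sim_neg` and their difference `diff`;
drug-session frames are aligned to the template before scoring by
default.

The drug-session summary classifies each frame positive (`diff > 0`) or
negative (`diff < 0`); exact zeros are excluded (a measure-zero event in
floating point) rather than split. The "normalized similarity
difference" of the drug analysis has no published formula; it is
implemented — in one isolated function — as the epoch mean of `diff`
minus the pre-injection baseline mean, divided by the baseline standard
deviation of `diff`, with a flagged fallback to the unscaled difference
when the baseline variance is zero.

## Kinematics

Tracking QC follows the published recipe: coordinates with confidence
below 0.9 are replaced by linear interpolation between the nearest
confident frames (edges held at the nearest valid value; interpolation
never crosses trial boundaries because tracks are per-trial), then a
5-frame rolling median removes jitter. The median filter is applied
once, as published; a single pass is idempotent only on signals that are
already filter roots, which the tests state precisely rather than
claiming exact idempotency on arbitrary noisy input.

The ten features use Euclidean distances, interior angles at the middle
vertex, and directional angles measured in the y-up frame and folded
into [0°, 180°] (the source never distinguishes clockwise from
counterclockwise; signed variants sit behind a flag). Open details were
resolved as follows: the nostril reference for mouth inclination is the
centroid of the three nostril points; the whisker angle uses the first
whisker's base-to-tip vector; the ear-angle vector originates at the ear
root. Change scores are proportional to the mean of the 4 s pre-stimulus
baseline; the per-trial "peak" is the signed extremum (largest absolute
change), since a pure maximum would hide decreases. Water correction
subtracts the temporally nearest water trial's change, ties breaking
toward the earlier trial. Response latency is the first post-onset
crossing of 2 baseline SDs sustained for 3 frames.

## Decoders

**Frame classifier.** The backbone is a reduced residual network — conv
+ relu, average pool, two residual blocks, global average pooling, dense
head — on 32-px inputs with 8 channels, trained with SGD (momentum 0.9,
L2 penalty 1e−4, the coefficient being unstated in the reference and
config-exposed here). The reference protocol's learning rate of 0.001
suits a deep pretrained network at full data scale; the from-scratch
desk-scale backbone sees orders of magnitude fewer and smaller steps, so
the desk default is 0.05 with the reference value reachable by config.
Frames are normalized by subtracting the per-pixel training mean — which
removes the static face and leaves the expression-dependent deviations —
and dividing by the global SD of the centered frames. Following the
reference protocol, training trials are split 80/20 into fitting and
validation portions at the trial level; validation cross-entropy is
monitored and the best-validation model restored. Splits are always at
the trial level (holdout, stratified k-fold, or one-trial-per-mouse-and-
stimulus holdout mirroring the reference evaluation); no trial ever
spans train and test. The label-shuffle control permutes training-side
labels at the trial level while evaluation labels stay intact; with the
reference protocol's random resize/±10° rotation augmentation applied to
training frames, the permuted labels carry no learnable structure and
the selected model sits at the chance plateau.

**Siamese embedding.** Twin copies of the same backbone with shared
weights embed each pair member; the pairwise margin loss (prefactor
1/2N) pulls same-valence pairs together and pushes different-valence
pairs beyond the margin. Pair mining enforces the cross-mouse strategy —
same-valence pairs always span two mice, different-valence pairs always
stay within one mouse, neutral frames excluded, balanced 50/50, capped
per mouse — so the embedding must encode valence rather than identity.
The source states the empirical margin both as the average pairwise
distance and as the average squared distance; both are implemented, the
unsquared variant being the default.

**Saliency.** Class maps backpropagate the target-class logit to the
last convolutional layer, weight each channel by its spatially averaged
gradient, rectify and upsample. Similarity maps backpropagate −d for
same-valence pairs (features supporting similarity) and +d for
different-valence pairs, per branch; identical inputs (d = 0) return a
flagged zero map. Maps are normalized to [0, 1] per image.

**Occlusion.** Region masks (bounding boxes of the region's keypoints,
padded, filled with the dataset mean gray — the "neutral color" here)
are applied to every frame, and the classifier is retrained from scratch
per fold under trial-level k-fold cross-validation; the reported drop is
the no-mask control's accuracy minus the masked accuracy.

**Trajectory decoder.** For each region the four keypoints with the
highest variance across trials are tracked over a 2.5 s window (0.5 s
pre to 2 s post onset) at 30 fps, z-scored per channel, and downsampled
by keeping every third frame: 25 timepoints × 8 channels = 200 values
per trial. A stacked LSTM (reference: 3 × 256 units, dropout 0.3; the
desk default halves the width, and the tests use smaller configurations
still) classifies the five stimulus conditions under stratified
trial-level 10-fold cross-validation, trained with cross-entropy,
adaptive-moment estimation and early stopping on the training loss —
the reference being silent on the LSTM optimizer.

## Photometry

Photobleaching is removed per channel by adaptive iteratively reweighted
penalized least squares: a sparse Whittaker smoother whose weights decay
exponentially where the trace exceeds the current baseline, so positive
transients are ignored while drift is followed. Defaults: λ = 1e8 at
15 Hz, at most 50 reweighting iterations (no parameters are published).
The detrended channels retain their median level so the subsequent
ordinary least-squares fit of the 410 nm control onto the 470 nm signal
— over the full session by default, with a transient-masked variant
selectable — and the division ΔF/F = (signal − fitted control)/fitted
control stay on the physical scale. Peristimulus traces subtract each
trial's 4 s pre-onset mean, so baseline-window means are zero by
construction; per-trial peaks are post-onset maxima, and stimulus
responses are normalized by the mean water-trial peak.

The neural–facial analysis pools all 15 Hz timepoints within 2 s
post-onset windows, z-scores both series per session (the published
z-scoring scope is ambiguous; per-session is the default with pooling
optional), computes the Spearman rank correlation, and builds the
one-sided null by shuffling the pooled facial samples (a circular-shift
alternative is retained for autocorrelation robustness). The p-value
uses the add-one estimator, so it is never zero. Facial similarity at
30 fps maps to the 15 Hz neural clock by frame-pair averaging.

## Numerical and scale choices

Problem sizes throughout the tests were chosen so the full suite runs on
a single core in well under half an hour: cohorts of 3–10 mice with 2–5
trials per stimulus, 128-px renders downsampled to 32-px classifier
inputs, 64-px HOG canvases (the 1024-px reference configuration is
exercised once to pin the descriptor length), a few hundred contrastive
pairs, and 200-replicate permutation calibrations. The chance-level
calibration of the frame classifier runs at the full stated scale
(10 mice × 25 trials × 60 frames). All randomness flows through a
single seeded generator per unit of work (trial, mouse, stage), derived
deterministically from one master seed, so cohorts regenerate
bit-identically and stage reruns are independent yet reproducible.

## Known limitations

Schematic faces lack texture, lighting and non-rigid deformation; the
registration stage therefore solves an easier problem than real
cross-animal alignment. The embedding is an in-package approximation of
the UMAP family, adequate for cluster structure but not guaranteed to
reproduce another implementation's layouts. The photometry generator
shares one artifact process between channels and uses a single
transient kernel; pathologies like channel-specific artifacts or
bleaching nonstationarity are out of scope. The LSTM and classifier are
desk-scale models: their absolute accuracies are not comparable to
full-scale results on real video, only their orderings and controls are.
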