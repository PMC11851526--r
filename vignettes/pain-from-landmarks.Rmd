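---
title: "Detecting expressed pain from anonymized 3D face landmarks"
author: "painAU package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting expressed pain from anonymized 3D face landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painAU)
```

## The problem

Automatic pain assessment from video matters most where patients cannot
self-report — post-operative care, dementia, sedation. Clinical video is
also maximally identifying, which makes data sharing and model reuse
difficult. This package implements a privacy-preserving compromise: the
video is reduced, frame by frame, to a fixed-topology cloud of 3D face
landmarks (478 points in the common dense face-mesh topology, 83 in the
expert-annotated topology of the BP4D+ corpus). The landmark cloud
retains facial *geometry* — and therefore expression — while discarding
the texture that identifies a person. Everything downstream of that
reduction operates on geometry alone.

The pipeline has three stages:

1. **Anonymizer** — an external pre-trained face-mesh extractor turns
   each frame into an `Ns x 3` landmark matrix. The package wraps such
   extractors behind `extractLandmarks()` (gap interpolation, segment
   splitting) but deliberately does not reimplement one; all training
   and evaluation operate on landmark containers.
2. **AU detector** — per frame, a fully-connected network maps the
   flattened landmark vector to facial Action Units (AUs), the
   elementary muscle actions of the Facial Action Coding System (FACS).
   Eight AUs are detected as present/absent (AU 5, 6, 8, 9, 10, 12, 14,
   18 — the most prevalent and most pain-relevant ones); five (AU 6,
   10, 12, 14, 17) are additionally regressed on the continuous FACS
   intensity scale 0–5.
3. **Pain detector** — a Transformer encoder (or a two-layer LSTM
   baseline) classifies a fixed-length window of per-frame AU vectors
   as pain vs. non-pain.

## Models

### AU detection and intensity estimation

Given normalized landmarks $L \in \mathbb{R}^{N_s \times 3}$, the
detector computes $A = g_\phi(\mathrm{vec}(L)) \in \mathbb{R}^{8}$ with
one hidden layer of 128 ReLU units and a logistic output per AU,
trained with per-unit binary cross-entropy (the standard multi-label
treatment, matching F1-based evaluation). The intensity head is the
same architecture with 5 linear outputs under squared-error loss;
reported intensities are clamped to $[0, 5]$ and may be rounded to FACS
levels with `roundIntensity()` (ties round away from zero). Training
follows the reference recipe: Adam ($\beta_1 = 0.9$, $\beta_2 =
0.999$), learning rate 0.01, batch size 64, up to 500 epochs, no early
stopping by default (a patience knob exists but is off).

One implementation note: the input coordinates ride on a large constant
offset (the face itself); the training-set mean is subtracted from the
inputs and stored with the weights. This is plain input centering — it
changes conditioning, not the model class.

### Landmark normalization

The raw coordinates of any extractor carry arbitrary pose and scale
(and an unspecified depth unit). Before the AU networks see a frame it
is Procrustes-normalized against a canonical template: centroid to the
origin, isotropic rescaling to the template's mean point-to-centroid
distance, then the least-squares rotation (Kabsch, no reflection) onto
the template. The result is invariant (within `1e-6`) to any rigid
motion plus uniform scaling of the input, which makes the detector
pose-invariant by construction; the depth-unit ambiguity is absorbed by
the scale step. Normalizing both topologies uniformly is a deliberate
choice — nothing in the architecture requires it, but an
unnormalized input would entangle head pose with expression.

### Temporal pain classification

A segment's AU series is cut into windows of $T = 350$ frames (about
14 s at 25 fps). The Transformer encoder projects each 8-dimensional AU
vector to $d = 1024$, adds fixed sinusoidal positional encodings, and
applies two post-norm encoder blocks (4-head self-attention, add &
norm, position-wise feed-forward, add & norm). An MLP head (one hidden
layer of 256 units, dropout 0.1 — both package choices, the reference
recipe names neither) reads the representation of the **last non-padded
frame** and emits a logistic pain probability; the decision is
`round(probability)`. The LSTM baseline stacks two layers of hidden
dimension 512 with a logistic head on the final valid hidden state.
Optimizer settings: Adam with learning rate $10^{-5}$ (Transformer) or
$10^{-3}$ (LSTM), batch size 16, up to 150 epochs.

All three networks are implemented in R with BLAS matrix operations and
hand-derived backpropagation (including attention, layer norm and BPTT);
the test suite verifies every gradient path against central finite
differences at tolerance `1e-5` and the attention weights against a
brute-force softmax oracle at `1e-6`.

### Windowing policy

Windowing is not specified by the architecture, so the package fixes
it: non-overlapping windows at stride $T$, plus one right-aligned
window when the leftover tail is at least `tailFrac * T` frames
(`tailFrac = 0.4`; a 500-frame segment at $T = 350$ yields windows
1–350 and 151–500). Segments shorter than $T$ are right-zero-padded
with a padding mask (masked positions receive zero attention and do not
move the LSTM readout); segments shorter than 10 frames are skipped
with a warning. Segment-level decisions aggregate window decisions by
majority vote with ties deciding *pain* — the clinically conservative
direction.

## The simulator

The corpus the method was designed for is access-restricted, so the
package ships a forward simulator making every stage trainable and
testable. It emulates the corpus structure: 140 subjects by default,
each with one pain segment and three non-pain segments (happiness,
embarrassment, fear — the annotated elicitation tasks), segments of
about 20 s at 25 fps with ±15 % duration jitter, giving the
characteristic 1:3 pain:other frame ratio.

The forward model is linear, mirroring FACS's description of AUs as
additive muscle actions: a frame at AU intensities $I$ is

$$ \mathrm{frame}_t \;=\; \mathrm{Pose}_t\!\left( \mathrm{subject} +
   \textstyle\sum_k \tfrac{I_{t,k}}{5}\, F_k \right) + \varepsilon_t, $$

where each $F_k$ is a smooth displacement field localized at the AU's
anatomical site (cheek raiser near the cheeks, lip corner puller at the
mouth corners, ...), mirror-symmetrized so bilateral AUs act on both
face halves, and orthogonalized across AUs so that the 20 simulated AUs
remain statistically identifiable (all pairwise cosines < 0.3).
$\varepsilon$ is isotropic Gaussian landmark noise (default SD 0.01
template units) and the pose is a smooth random rotation/translation
walk.

Activation timecourses are onset–apex–offset pulses: class-prototype
AUs (from the FACS emotion–AU map; the embarrassment set
{7, 12, 14, 15, 24} follows the FACS literature on self-conscious
displays, as the usual emotion tables omit it) fire 1–4 pulses per
segment with apex levels skewed toward low intensities, plus a
continuous offset so apexes do not sit exactly on a labeling boundary;
onsets and offsets last 0.15–0.5 s, as facial actions do; the
frame-to-frame intensity change is bounded at 1 level. Three further
design points matter for realism *and* identifiability:

- **Muscle actions do not move the head.** Each deformation field is
  projected onto the orthogonal complement of the similarity-transform
  tangent space at the template (net translation, infinitesimal
  rotation and scale components vanish). Physically a muscle action is
  an internal deformation; numerically this makes the rendered
  deformation commute with Procrustes normalization to first order, so
  normalization cannot silently cancel part of an AU's signal.

- **Background activity.** The detectable AUs that belong to no
  simulated emotion prototype (AU 8 and 10) fire frequent
  class-independent background pulses — they are among the most present
  AUs without being class-informative; class-informative AUs get only
  rare trace-level background. Rare non-detectable AUs appear as
  occasional distractor pulses.
- **Identity vs. expression.** Per-subject shape offsets are projected
  onto the orthogonal complement of the AU field span: face proportions
  vary across people, but an identity offset must not mimic an AU.
  Per-subject expressiveness scales the activation intensities
  themselves (capped at 5) rather than the geometry alone — FACS
  intensity is appearance-defined, so labels scale with what a coder
  would see.

Ground-truth labels derive from the timecourse: presence is intensity
≥ 1 (FACS level 0 denotes absence), intensities are recorded for the
five intensity AUs, and the full per-AU presence matrix is kept for the
all-AU pain-detection mode ("all AUs" means every AU the dataset
carries; the simulator's universe is the 20-AU union of the emotion
sets and the label schema).

**What passing tests do and do not show.** The simulator produces
geometry whose labels are exactly recoverable up to noise, pose and
subject variation — by design. Success on it demonstrates that the
implementation learns what it should (parameter recovery), not that the
method reaches any particular accuracy on real faces: real AU
annotation noise, correlated AU co-activation, occlusion, extractor
error and demographic variation are all absent. The shipped reference
tables (`referenceBenchmark()`) document the published real-data
results this implementation is modeled on.

## Evaluation harness

All protocols are subject-independent: folds partition *subjects*
(sizes differing by at most 1), never frames, and every run asserts
train/test subject disjointness. AU detection and intensity estimation
use 3-fold cross-validation; pain detection uses 10-fold (reduced fold
counts are exposed for desk-scale runs). Metrics follow the standard
definitions; empty precision/recall denominators yield 0 by default
(the common convention for rare classes; `undefined = NA` is
available). Per-AU F1 is averaged over folds and the reported AVG is
the unweighted mean of the per-AU values — every emitted report
re-checks this self-consistency on construction. Pain reports sum the
per-fold segment-level confusion matrices and derive aggregate
accuracy/F1 from the summed matrix; percentages are printed to two
decimals with half-up rounding. In `predicted8` mode the AU detector is
retrained inside each fold on that fold's training subjects, so no
stage ever sees a test subject.

Rare-AU augmentation operates in landmark space: horizontal flip via
the topology's mirror map, small rotations (±15°), framing jitter
(translation ±5 %, scale 0.9–1.1 — the landmark-visible effect of a
crop, which cannot remove points because the network needs all inputs)
and shear (±0.1). One transform is drawn per segment to preserve
temporal coherence. Augmented copies are created only from
training-tagged splits; calling the oversampler on a test split is a
hard error. Note an interaction: rotation, translation and scale are
exactly cancelled by Procrustes normalization, so when augmentation
feeds the normalized pathway only flip and shear add diversity; the
transforms are applied before normalization so robustness-oriented
(unnormalized) training can still use all of them.

## Numerical choices and degenerate inputs

- Decision thresholds: AU presence 0.5 (configurable); pain
  `round(probability)`.
- Intensity reporting: clamp to [0, 5]; rounding half away from zero.
- Procrustes: degenerate frames (all points coincident) are an error;
  reflections are never chosen (determinant-corrected Kabsch).
- Fully padded windows bypass the encoder and return the
  bias-determined constant.
- Extractor gaps: linear interpolation up to 5 consecutive missing
  frames, longer gaps split the recording.
- Determinism: every stochastic routine takes a seed; one global seed
  fans out through a deterministic splitter (`deriveSeed()`). Dataset
  determinism is defined on a canonical content hash
  (`datasetHash()`) rather than raw container bytes, since HDF5 files
  may embed write-time metadata.

## Problem sizes used by the shipped tests and acceptance script

The package defaults are the reference-scale settings (478-point
topology, $d = 1024$, 500/150 epochs). The test suite and
`scripts/acceptance.R` run the same code at desk scale, chosen once and
documented here: the 83-point topology, 8 s segments, every 2nd frame,
100 simulated subjects (detector recovery; 80 epochs), 30 subjects in
3 folds with a $d = 64$ Transformer / 48-unit LSTM and 150-frame
windows (pain recovery), and a 24-subject low-background simulation for
the rare-AU augmentation contrast. These sizes keep a complete
train-and-evaluate cycle within minutes on a single CPU while leaving
every algorithmic path identical to the full-scale configuration.

## Known limitations

- The simulator's linear forward model cannot represent saturating or
  interacting muscle actions; nonlinearity is out of scope.
- Landmark-space augmentation approximates image-space augmentation;
  exact equivalence is impossible because the original method
  re-extracted landmarks from augmented images.
- The anonymizer is wrapped, not implemented: video input requires an
  external face-mesh extractor.
- Per-AU base rates of the real corpus are published only as a figure;
  the simulator's rates are configurable but not calibrated to it.
- No significance testing between models is provided (none is
  published for the reference results either).
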