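---
title: "Multimodal EEG/facial emotion recognition with attention fusion: models and methods"
author: "mmhafnn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal EEG/facial emotion recognition with attention fusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mmhafnn)
```

# The problem

Hearing-impaired people rely more heavily than hearing people on visual and
physiological channels when expressing and perceiving emotion, and their
emotion-related cortical responses emphasize parietal and occipital regions.
This package implements a four-class (happy / sad / fear / calm) emotion
recognizer that fuses two complementary modalities recorded simultaneously
while a subject watches short film clips:

* **62-channel EEG at 200 Hz**, summarized per 1-second window as
  differential-entropy (DE) features over the five canonical bands and
  rendered as topographic images, and
* **facial-expression frames**, one per second, as 3-channel images.

The multimodal classifier (MMHA-FNN: multimodal multi-head attention fusion
network) couples an MBConv/squeeze-excitation EEG encoder (EFEM), a
bottleneck-residual face encoder (FEFEM) and a Transformer fusion module
(FFM) whose multi-head self-attention lets the two modalities reweight each
other per window.  Because the kind of paired clinical corpus this method is
designed for is typically restricted, the package also ships a synthetic
dataset generator with analytically known class signatures, so that every
stage of the pipeline — features, rasterization, encoders, fusion, protocol
— is verifiable offline.

# Feature model

## Differential entropy

For a continuous signal with density $f$, the differential entropy is
$h(X) = -\int f(x)\,\ln f(x)\,dx$.  A band-limited EEG window is modelled
as Gaussian $\mathcal N(\mu,\sigma^2)$, for which the integral reduces to
the closed form

$$h(X) = \tfrac12 \ln\!\big(2\pi e\,\sigma^2\big).$$

Numerical choices, made once and frozen:

* **Log base**: natural logarithm; all DE values are in nats, the standard
  unit in which the $2\pi e$ form is written.
* **Variance estimator**: the maximum-likelihood $1/n$ sample variance.
  This makes the amplitude-scaling law $h(cX) = h(X) + \ln|c|$ exact, which
  the test suite asserts at machine precision.
* **Degenerate windows**: a zero-variance window has no defined DE; it
  returns a $-\infty$ sentinel, and the rasterization stage clamps inputs
  to a configurable floor (default $-10$ nats, two orders below typical
  synthetic values) so that one dead channel cannot poison training.

## Band decomposition and windowing

DE is extracted per band from delta (1–4 Hz), theta (4–8), alpha (8–12),
beta (12–30) and gamma (30–50 Hz).  The bands only are part of the method
definition; the filter is a package choice: a 4th-order Butterworth
band-pass applied forward and backward (`signal::filtfilt`), i.e.
zero-phase, so filtering cannot shift features across the 1-second window
grid.  The test suite verifies that a symmetric pulse keeps its center of
mass, that a 10 Hz tone lands in the alpha band, and that the five-band
bank reconstructs a band-limited input to better than 10 % relative L2
error away from the outermost crossovers (exactly at 1 Hz or 50 Hz a
two-sided bank necessarily halves the amplitude).

Windows are 1 s, non-overlapping, trailing partial seconds dropped.

## Face preprocessing

Frames are center-cropped to a square and bilinearly resized to a fixed
raster.  Each pixel/channel feature is then min–max normalized **per
subject** over all of that subject's frames,
$(F - \min)/(\max - \min)$, mapping every non-constant feature onto
$[0, 1]$ (constant features map to 0).  The formula as written yields
$[0,1]$; because normalization to $[-1,1]$ is also common for this step, an
optional signed rescale ($2x-1$) is available, but the default is the
formula as printed, which is the checkable object.

# Topographic rasterization

A 62-value DE vector is painted onto a raster (224×224 at reference scale)
by bilinear interpolation between the **four electrodes surrounding each
pixel**.  Electrodes are scattered, not gridded, so "surrounding four" is
made precise as: the nearest electrode in each of the four open quadrants
(NW/NE/SW/SE) around the pixel, combined with the classical area-product
weights

$$\omega_q \;\propto\; \lvert x_p - x_{\bar q_x}\rvert \cdot
  \lvert y_p - y_{\bar q_y}\rvert,$$

where $\bar q_x$ and $\bar q_y$ are the E/W- and N/S-mirrored corners,
normalized to sum to one.  On a rectangular electrode grid this reduces
*exactly* to textbook bilinear interpolation — that is the sense in which
the scheme honors its defining equation, and the suite proves it against
both a textbook oracle on grids and an exhaustive quadrant-search oracle on
random layouts.  Properties that hold by construction and are asserted:
partition of unity (a constant vector paints a constant map), exactness at
electrode positions, and convexity (interpolated values bounded by the
electrode extremes).

Conventions the source method leaves open, fixed here and recorded in the
feature-file attributes:

* **Raster frame**: the electrode unit disc maps to the central
  $(200/224)\cdot S$ box of an $S\times S$ raster, pixel centers at
  half-integer coordinates, nose up.
* **Border**: any pixel lacking four-quadrant coverage (outside the
  electrode hull margin) is exactly zero — the dark border of published
  topography figures.
* **Degenerate stencils**: a pixel within $10^{-6}$ of an electrode takes
  that electrode's value with weight one; if all four area products vanish
  (collinear corners) the four electrodes are averaged equally.
* **Montage**: the shipped default places the 62 extended-10/20 electrodes
  (Neuroscan convention, CB1/CB2 included) on great-circle arcs of a
  spherical head and projects them azimuthal-equidistantly onto the unit
  disc.  Any montage can be supplied as a `name,x,y` CSV; features are tied
  to their montage by a content hash.

# The networks

All layers, backpropagation and the AdamW optimizer are implemented in R on
top of BLAS matrix products (per-offset slice/multiply convolutions); there
is no compiled model code. Finite-difference gradient checks on every layer
type are part of the development suite, and the shipped tests verify the
algebraic identities below.

**EFEM (EEG encoder).** Stem: 3×3 stride-2 convolution → BatchNorm → GELU →
3×3 stride-2 convolution; then four MBConv stages, each entered through a
2×2 max-pool: 1×1 reduction, two depthwise-separable convolutions,
squeeze-excitation reweighting (reduction ratio 0.25), residual add when
shapes match.  The final feature map is flattened to tokens and projected
to the fusion width through a GELU-separated two-layer head.

**FEFEM (face encoder).** Stem: 7×7 stride-2 convolution, BatchNorm, ReLU,
3×3 stride-2 max-pool; then four bottleneck-residual stages (1×1 down, 3×3,
1×1 up, projection shortcut and stride 2 at stage starts).  A basic-block
(18-layer-residual-style) variant is available by configuration
(`block_type = "basic"`); the bottleneck form is the default because the
method's description of its face branch is explicitly a bottleneck
("reduce and restore the channels").  Tokens as above.

**FFM (fusion).** The two token sequences receive learned modality-type
embeddings, a class token is prepended, and $L_T$ pre-LN Transformer
blocks are applied:

$$\dot X_l = G_{msa}(G_{ln}(X_{l-1})) + X_{l-1}, \qquad
  X_l = G_{mlp}(G_{ln}(\dot X_l)) + \dot X_l,$$

with multi-head attention
$\mathrm{softmax}(QK^\top/\sqrt{d_k})\,V$ per head, heads concatenated and
mixed by $W^O$.  The classifier reads the final class token.  There is no
intra-modality positional encoding, so class-token logits are invariant to
permuting tokens within a modality (asserted by test).  Per-layer attention
weights are recorded for attribution.

**Per-band EEG tokens.** In the fusion model the EFEM trunk is applied to
each frequency band separately with shared weights (implemented as a
batched single-channel pass), so every EEG token belongs to a known band.
This is what makes band-level attention attribution well-defined: the
class-token attention row of the last block, averaged over heads and
windows, is summed within each band group and renormalized; facial tokens
are grouped by a geometric forehead/eyes/cheeks/mouth/other partition of
the token grid.  The two group vectors are normalized separately, each
summing to one.

**Baseline fusion heads**, sharing the same encoders: feature
concatenation (mean-pool each modality, concatenate, two-layer MLP) and
decision-level fusion (equal-weight average of the two unimodal
posteriors).

## Reference configuration and the complexity budget

The source method prints no layer table; the only printed architectural
constraint is its complexity budget (15.2 M parameters).  The reference
configuration is therefore: $d_{model} = 256$, $h = 8$ heads, $L_T = 2$,
MLP ratio 4; EFEM stem 32, stage widths (32, 64, 128, 256), two blocks per
stage, expansion 4, SE ratio 0.25; FEFEM bottleneck widths
(60, 120, 240, 480), two blocks per stage, expansion 4.  One declared
calibration knob — the token-projection hidden width — was tuned once so
the full model's trainable-parameter total, in millions to one decimal,
equals the published budget; the resulting value (430) is frozen as the
default.  `count_params_flops()` counts parameters exactly and MACs by
layer-shape arithmetic (1 MAC = 1 FLOP), which reproduces the standard
18-layer residual baseline's published 11.7 M / 1.8 G.

A note on the depthwise parameter count: the textual description
accompanying such methods sometimes includes spatial dimensions in the
depthwise parameter formula.  Standard convolution algebra gives
$k^2 d$ (+$d$ bias) parameters for a depthwise $k\times k$ layer over $d$
channels, and that is what the counting utility implements; the test suite
pins it.

## Optimization

Cross-entropy loss, batch size 32, initial learning rate $10^{-3}$, cosine
annealing
$$\eta_t = \eta_{min} + \tfrac12(\eta_{max}-\eta_{min})
  \big(1 + \cos(\pi\,T_{cur}/T_{max})\big),$$
updated once per epoch with $T_{max}$ equal to the epoch budget (a
per-batch mode is available; "updated once per iteration" is ambiguous
between the two, and per-epoch matches an iteration count equal to the
stated 100 training iterations).  The optimizer is AdamW by default with
decoupled weight decay on weight matrices only; plain Adam is a flag, since
descriptions of this training setup name both.  All randomness — fold
assignment, weight initialization, batch shuffling — sits behind one seed.
Ties in the argmax decision rule break toward the lowest class index.

# Evaluation protocol

* **Subject-dependent, clip-wise 5-fold CV**: the cross-validation unit is
  the stimulus clip, with each fold holding exactly one clip per emotion
  per subject, so windows of one clip never straddle train and validation.
  Split integrity (zero clip leakage) is asserted programmatically on
  every experiment run.
* **LOSO**: leave-one-subject-out splits for subject-independent
  evaluation; subject leakage is likewise asserted to be zero.
* **Reports**: accuracy (%), row-normalized 4×4 confusion matrices,
  per-subject accuracies, and two-sided paired t-tests on per-subject
  accuracies between methods (identical vectors give $t=0, p=1$;
  zero-variance non-zero differences are flagged rather than silently
  dropped).

# The synthetic data generator

`synth_dataset()` emulates the *structure* of the target corpus — per
subject, $4 \times$ `clips_per_emotion` clips with balanced labels,
62-channel EEG at 200 Hz in 1-second windows, one face frame per window —
with controllable class signatures:

* **EEG**: background is independent Gaussian noise per channel shaped
  into the five bands with equal base variance (spectral synthesis, so the
  Gaussian DE model is *exactly* true by construction).  Each emotion
  multiplies the variance of one (band, montage-region) pair by $m$
  (default $m=4$), giving an analytic expected DE offset of
  $\tfrac12\ln m \approx 0.693$ nats on targeted channel–band entries — an
  oracle the tests check.  Regions come from coarse montage groupings
  (frontal/central/parietal/occipital/temporal), echoing the
  parietal-occipital emphasis reported for the target population without
  claiming forward-model fidelity.
* **Subject effects**: log-normal per-channel gains drawn once per
  subject (SD 0.1), exercising per-subject normalization and the
  subject-dependent protocol.
* **Faces**: procedurally drawn templates (ellipse head, eye and mouth
  primitives) whose eye openness and mouth geometry deform with the
  emotion, scaled by `face_signature_strength`; deformations are
  multi-pixel even on small rasters so that generalization, not template
  memorization, is what a classifier must achieve.  Pixels are quantized
  to the 8-bit grid at generation so PNG round-trips are bit-exact.  At
  strength 0 all emotions share one template; with strength high and noise
  off, a nearest-centroid pixel classifier is perfect (both asserted).

What the generator does **not** emulate: realistic EEG spectra, artifacts,
volume conduction, inter-channel correlation structure, facial identity
variation, head pose, lighting, or temporal dynamics within a clip.
Passing the end-to-end tests therefore shows that the pipeline can recover
a known multimodal signal under its own assumptions — it says nothing
about accuracy on real recordings, which this package cannot reproduce.

# Study problem sizes

Two configurations are built in:

* **Reference** (`model_config()`): 224×224 topographic maps, 256×256
  faces, the calibrated 15.2 M-parameter model.  Used for counting and
  architecture checks; training it is out of desk-scale scope.
* **Desk scale** (`desk_model_config()`): the same architecture at reduced
  width — 64×64 maps, 48×48 faces, $d_{model}=48$, 4 heads, one block per
  stage, projection width 48 (about 0.1 M parameters).  The synthetic
  recovery study uses the generator defaults (4 subjects, 5 clips per
  emotion, 20 s clips → 1600 windows), one validation fold of the clip-wise
  5-fold split, 10 training epochs, batch 32.  These sizes were chosen once
  as the package's desk-scale study conditions; the label-shuffled control
  uses 2 epochs and batch 64, since a model trained on clip-permuted labels
  has nothing to learn and only needs to be shown sitting at chance.
  Because clips, not windows, are the independent units under clip-level
  shuffling, the control's chance band uses the validation *clip* count.

# Known limitations

* The networks run on one CPU thread through BLAS; the reference-scale
  model is practical to count and to forward on single batches, not to
  train here.
* EDF ingestion and HDF5 feature files are not provided; the package's
  containers are raw float64 + JSON sidecar (EEG, features, checkpoints),
  PNG (frames) and CSV (manifest, montage, results).  The sidecars carry
  the same attributes an HDF5 layout would (band edges, montage hash,
  clamp floor, config hash).
* Artifact rejection, re-referencing, ICA, face detection and landmarking
  are out of scope; frames are assumed pre-cropped to the face.
* The low-arousal class is called *calm* throughout; descriptions of such
  four-class protocols sometimes alternate between "calmness" and
  "neutral" for the same class.
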