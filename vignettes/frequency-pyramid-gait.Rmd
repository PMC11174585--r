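---
title: "Frequency-pyramid graph convolutions for pathological gait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-pyramid graph convolutions for pathological gait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fpgait)
```

## The problem

Pathological gaits — hemiplegic, steppage, festinating, ataxic and the
like — differ from normal walking along two axes that a skeleton-based
classifier has to capture jointly: *when* things move (cadence, rhythm
irregularity, walking-speed variation between and within pathologies) and
*where* they move (which joints, with what amplitude, how symmetrically
left and right). Fixed-window temporal convolutions see only a few frames
at a time, so they adapt poorly to the large cadence differences between
pathologies. This package implements a classifier that instead learns its
temporal structure in the frequency domain, on top of an anatomical joint
graph, and reads the skeleton at three spatial granularities at once.

Input data are skeleton sequences: real tensors of `C` coordinate
channels × `T` frames × `V` joints (2D or 3D pose-estimator output), with
integer class labels. Two joint layouts ship with the package
(`kinect25`, `coco17`) as editable YAML files; joint indices are 0-based
everywhere.

## The spectral graph-convolution layer

One layer performs four steps on a `(C, T, V)` feature map:

1. **Channel projection.** A pointwise linear map mixes channels
   (`W_proj`, plus bias); this is where width changes between layers.
2. **Spatial graph aggregation** (`spatial_aggregate()`). Each joint
   receives the degree-normalised, edge-weighted sum of its graph
   neighbourhood through a LeakyReLU:
   `x_i' = mu( (1/d_i) * sum_{j in N(i)} W_E(ij) x_j )`.
   Every joint carries a self-loop with its own learnable weight, so a
   node's feature always contributes and no degree is zero.
3. **Spectral weighting** (`to_frequency()`, `apply_spectral_weights()`,
   `from_frequency()`). The `(C, V)` axes are flattened (channel-fastest)
   into a spatial axis of length `S = C·V`, an orthonormally scaled 2D
   DFT is taken over (space, time), and each complex coefficient at bins
   `(s, t)` is multiplied by the real factor
   `theta(mean(theta(W_E)) · W_A(s)) · theta(W_F(t))` — a learnable
   per-bin spatial mask, modulated by the normalised summary of the edge
   weights, times a learnable per-bin temporal mask (`theta` is
   LeakyReLU). The inverse transform returns to the joint–time domain.
4. **ReLU** between layers.

Only the `floor(T/2) + 1` non-negative temporal frequency bins are stored
— the rest are redundant by conjugate symmetry of real signals. (Both
`ceil` and `floor` conventions appear in the literature; `floor(T/2)+1`
is what a real-input transform actually produces, for even and odd `T`.)

Two numerical decisions matter here:

* **Masks scale magnitudes, not phases.** The masks are real, so they
  only weight frequency magnitudes. For the masked spectrum to remain
  Hermitian (and hence the inverse exactly real, with no discarded
  imaginary part), the activated spatial mask is averaged with its
  frequency-reversed copy before multiplication; the temporal mask is
  symmetric by construction once expanded to the full axis. This
  symmetrised-mask operator is identical to taking the real part of the
  naively masked inverse, but makes the intended linear operator — a real
  circular filter along each axis — explicit, keeps the half-spectrum API
  path and the batched training path numerically identical, and yields
  exact equivariance to circular time shifts (tested).
* **Initialisation.** `W_E`, `W_A`, `W_F` start at 1 and the LeakyReLU
  slope is 0.01, so an untrained layer is a near-identity spectral filter
  and early training is stable. Projections use seeded Glorot draws.

The fixed-window baseline (`tcn_baseline_forward()`) is the comparison
layer: a per-channel temporal kernel of length `s_d` summed over the
graph neighbourhood, zero-padded at the sequence end (boundary handling
is unspecified in the literature; zero padding is the simplest choice).

## The three-pathway pyramid

The full classifier (`model_config()`, `fpgcn_init()`) runs three
pathways over partition-restricted copies of the skeleton graph:

* **global** — all joints, one connected graph;
* **half** — upper and lower body (sharing the pelvis), edges crossing
  the halves removed;
* **limb** — two arms, two legs and the torso as five disconnected
  components.

All pathways retain all `V` joints (the partitions cover the joint set),
so features align across pathways by joint index and no interpolation is
needed for fusion. Capacity decreases from coarse to fine (default widths
64/48/32; the reduced benchmark model uses 16/12/8), which realises the
"heavier global pathway, light limb pathway" ordering.

**Cross-domain fusion** (`cross_domain_fuse()`) injects coarser features
into finer pathways at every depth: the fine pathway's previous-depth
feature and the coarser pathway's current-depth feature are each passed
through a linear weight, concatenated along channels, and projected back
to the fine width. Fusion weights initialise to a pass-through of the
fine branch (identity + zero block), so an untrained fusion is invisible.
Injection is strictly coarse→fine (global→half→limb); no fine→coarse
feedback.

**Head.** Each pathway's final feature map is mean-pooled over frames and
joints; the three embeddings are concatenated, standardised (see below)
and mapped by a single linear layer to `K` class scores. The loss is
label-smoothed cross-entropy (`epsilon` default 0.1; smoothing constant
unreported in the source literature) with targets `1 - epsilon` /
`epsilon/(K-1)`.

### Why the embedding is standardised

Mean pooling of a near-identity network annihilates the oscillatory part
of the signal: at initialisation the pooled embedding is essentially the
(class-independent) static pose, and the class-informative part sits
3–4 orders of magnitude below it, so plain SGD stalls at chance. Two
standard skeleton-pipeline steps fix this and are on by default:

* **Motion centring** (`center_temporal()`, `train_config(detrend=)`):
  subtracting each joint coordinate's temporal mean leaves pure motion
  around zero, so rectifying activations convert oscillation amplitude
  into pooled signal.
* **Embedding standardisation**: the pooled embedding is standardised per
  dimension (batch statistics during training, with the exact backward
  pass; training-set statistics recomputed after every epoch and frozen
  into the model for inference), then scaled/shifted by learnable
  `gamma`/`beta` before the linear head.

Neither changes the graph/spectral computations; they are documented head
and preprocessing choices, pluggable behind the configuration.

### Ablation variants

`model_config(variant=)` exposes the two single-component ablations by
construction: `fgcn_only` keeps only the global pathway (a plain stacked
spectral classifier, no fusion); `pgcn_only` keeps the pyramid but
freezes both spectral masks at identity (the identity spectral filter is
skipped rather than computed, which is mathematically equivalent and
cheaper — asserted against the full model by parameter surgery in the
tests). `tcn` swaps the spectral step for the fixed-window baseline with
matched widths and depth.

## Training

`train_model()` runs seeded mini-batch SGD with momentum (default 0.9,
unstated in the source protocol) on the label-smoothed cross-entropy, no
learning-rate schedule (only an initial rate is ever specified), records
per-epoch train/validation loss and accuracy, and returns the parameters
of the best-validation-accuracy epoch (earliest on ties; reported
metrics are always test-split metrics). Splits are stratified 8:1:1 by
default and deterministic given the seed. Training is bit-reproducible
on a single CPU thread: every random draw (initialisation, batch order,
generator noise) derives from the configured seeds.

The published full-scale protocol (learning rate 1e-4, 200 epochs, batch
64) belongs to multi-hour GPU training on thousands of real videos and is
kept as the documented `train_config()` default learning rate only. The
shipped synthetic benchmark uses its own protocol (below).

## The synthetic gait simulator

`generate_sequence()` is phenomenological, not biomechanical: limb joints
oscillate along the walking direction as sinusoids at the class cadence,
left and right legs in phase opposition, arms counter-phased to the
ipsilateral leg, distal joints swinging more (per-joint weights in the
layout file). A class is a `gait_class_spec()`: cadence (Hz), per-group
amplitudes (m), left/right asymmetry ratio in (0,1] applied to the left
side, fractional speed drift (one slow sinusoidal cadence-modulation
cycle per sequence), optional tremor overlay (a second sinusoid), and a
static trunk lean. Pose-estimation noise is applied last: i.i.d.
Gaussian jitter and per-joint-per-frame dropout with hold-last (default,
tracker-like) or zero fill. `generate_dataset()` adds mild per-sequence
cadence/amplitude jitter (log-normal, 3%/5%) and random initial phase to
emulate inter-trial variation.

Nine illustrative phenotype specs named after commonly described gait
classes ship with the package (`default_gait_classes()`); they encode
coarse clinical phenomenology (festinating = fast + small steps + trunk
lean; hemiplegic = strong asymmetry; chorea = tremor + rhythm
irregularity) and are **not** clinically validated.

What the simulator does *not* emulate: ground contact and double-support
kinematics, joint-angle limits, camera projection and occlusion,
view-point changes, tracking identity switches, or realistic
pose-estimator noise correlation. Passing tests on this data demonstrate
that the architecture and optimiser work as specified and that the
spectral layer exploits frequency structure — not clinical performance.

## The shipped benchmark and desk-scale experiments

`benchmark_protocol()` freezes the study conditions used by the package's
own experiments: four classes whose cadences (0.7/1.1/1.7/2.6 Hz) are
spaced by a geometric factor > 1.5 — so even a ±20% cadence perturbation
leaves the class bands disjoint — with a secondary asymmetry cue
(1/0.9/0.8/0.65) and equal amplitudes; 100 sequences per class, 120
frames at 30 fps on `kinect25`, 1 cm jitter, 2% dropout; the reduced
model (widths 16/12/8, depth 2); momentum SGD at rate 0.2, batch 32,
5 epochs (validation accuracy saturates within 1–2 epochs at these
sizes; the protocol allows up to 30), 8:1:1 split.

* `run_ablation()` trains `fpgcn` / `fgcn_only` / `pgcn_only` under
  identical seeds and splits. On this benchmark the pyramid-only variant
  has no frequency-selective operation at all (pooling is
  time-invariant), so it can only use the amplitude/asymmetry cue and
  lands far below the spectral variants — a deliberately sharpened
  analogue of the published ablation ordering.
* `run_speed_robustness()` trains the spectral classifier and the
  width/depth-matched fixed-window baseline on clean data and evaluates
  both on a test set whose per-sequence cadence is scaled by a uniform
  factor in [0.8, 1.2] — walking-speed variation unseen in training, the
  failure mode fixed-window analysis is known for.

Problem sizes throughout (tiny graphs for gradient checks, 400-sequence
benchmark, 5-epoch runs) were chosen once as the smallest sizes at which
each property is cleanly measurable on a single CPU.

## Numerical choices and degenerate inputs

* Orthonormal DFT scaling throughout (energy-preserving; Parseval
  asserted to 1e-10 relative).
* Round-trip identity of the transform asserted to 1e-6 absolute on
  random maps up to `C=4, T=120, V=25`.
* All backward passes are hand-derived and checked against central
  finite differences over *every* parameter of tiny models (tolerance
  1e-4 relative; observed < 1e-5). Checks jitter parameters off the
  identity initialisation because pass-through inits put ReLU inputs
  exactly at the kink, where finite differences are meaningless.
* Validation guards: empty joint sets, duplicate/out-of-range edges,
  cadence at/above Nyquist, mask/graph shape mismatches, epsilon ≥ 1,
  ratio splits that leave an empty stratum, non-finite losses (training
  aborts with a diagnostic rather than continuing).
* Degenerate graphs: a single joint with its self-loop is valid
  everywhere; the limb pathway's graph is intentionally disconnected.
* Ties in model selection resolve to the earliest epoch.

## File formats

One JSON archive holds sequences of one layout/fps/shape: a version
field, a header (shape, class map) and full-precision payloads; reading
reproduces tensors bitwise. A long CSV dialect (`frame`, `joint`, one
column per coordinate) supports interoperability at a declared precision.
Model checkpoints are versioned JSON with every parameter array and the
frozen embedding statistics. Run configuration is YAML with `model:` and
`train:` sections; there are no knobs outside the documented schema.
Coordinates are stored un-normalised; pelvis-centring and torso-length
scaling (`normalize_sequence()`) are explicit pipeline steps, on by
default in training.

## Known limitations

* The simulator's phenotypes are caricatures; no clinical claims.
* Single-threaded CPU training limits practical model sizes; the
  compiled spectral kernel (Armadillo/FFTW) is the only hot path moved
  out of R.
* Frequency-domain weighting assumes approximately stationary rhythm;
  strongly aperiodic movement (e.g. unpredictable tremor) is exactly the
  regime where this style of analysis is known to lose accuracy.
* The checkpoint format stores layout-based models only (custom ad-hoc
  graphs are for in-session experimentation).
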