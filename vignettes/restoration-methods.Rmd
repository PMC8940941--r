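---
title: "Models and methods behind fiberdl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fiberdl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fiberdl` restores high-speed spiral-scan two-photon fiberscopy movies with a
two-stage conditional GAN and evaluates the restoration with the standard
image- and calcium-signal metrics. This vignette documents the models, the
parameters that matter, the synthetic phantom that stands in for real
recordings, and the design decisions taken where the published protocol
leaves choices open.

## The acquisition model

A resonant spiral scanner traces `scanning_speed` spirals per second; a frame
gathers `scanning_density` spirals along the radial direction, and only the
open (acquiring) fraction `duty_ratio` of each scan cycle contributes:

    frame rate = duty_ratio * scanning_speed / scanning_density.

Radial down-sampling by an integer factor `M` keeps every M-th spiral,
reducing the effective density to `ceiling(density / M)` and multiplying the
frame rate by up to M. With the reference operating point — 3360 spirals/s,
density 512, duty 0.5 — the package computes ~3.3 fps at full density and
26.25 fps at M = 8, a ~38 ms frame period. The duty ratio is a configuration
value; 0.5 sits inside the usual 50–80% band of such scanners and reproduces
the reported rates.

`build_ring_map()` realizes the radial geometry on the Cartesian frame as
concentric annuli of uniform width `R_corner / density` centred on the
central pixel (`floor(H/2)`, 0-based). Two consequences drove that centring
choice: the innermost ring actually contains a pixel (so ring 0 is
non-empty), and at the admissible maximum density — the frame side length,
e.g. 512 rings on a 512×512 frame — every ring label is populated. Densities
whose ring width falls below the pixel diagonal are rejected, since some
rings would then hold no pixel. Uniform ring width is a declared
simplification (resonant scanners are radially non-uniform); it is isolated
in `build_ring_map()` so a measured spacing law can replace it.

`radial_downsample()` keeps rings with index divisible by M bit-identically
and fills the rest by one of three policies: `nearest_ring` (replicate the
closest kept ring; the default, resembling a low-density reconstruction),
`zero` (ring-striped raw view), or `linear_radial` (linear interpolation in
radius). The regridding the original instrument software used is not
documented, so all three are switchable; every policy preserves kept-ring
pixels exactly, which the tests assert pixel by pixel.

## The phantom generator

The phantom emulates the two kinds of data the training protocol needs:

* **Ex-vivo-like anatomy** — elliptical somas placed by rejection sampling
  (never overlapping), each with smoothed random-walk dendrites of Gaussian
  cross-section, on a near-dark background. Run with `spike_rate = 0`, the
  scene is static, like an immunostained slice.
* **In-vivo-like activity** — per-neuron Poisson spike trains, each event
  drawing a relative amplitude, convolved with a causal single-exponential
  kernel; a neuron's soma and dendrites are modulated multiplicatively by
  `1 + a(t)`. This is a linear indicator model, adequate for fidelity
  testing, not a biophysical GCaMP model (no saturation, no rise time).

Defaults and their reasoning:

* `background_level = 2` (8-bit units). Real two-photon images have a
  near-dark background; the visible "background" of a fast scan is mostly
  noise. This is what makes soma SNR speed-dependent (below).
* `soma_intensity_range = c(40, 150)`. Wide, so that static training scenes
  span the brightness range that active neurons reach during transients;
  a denoiser trained on a narrow brightness band compresses transient peaks
  and distorts ΔF/F traces.
* `noise_model(photons_per_unit_at_ref_speed = 4, ref_speed = 165,
  read_noise_sigma = 2.5)`. Acquisition noise is Poisson shot noise on the
  expected photon count plus zero-mean Gaussian read noise, clipped to
  [0, 255]. The photon yield scales as `ref_speed / speed` (dwell time is
  inversely proportional to scanning speed). Because the Poisson part is
  unbiased, the mechanism that degrades the *mean-ratio* SNR at speed is the
  interaction of read noise with clipping on a dim background: the mass of
  zero-photon pixels grows with speed, so the clipped noise floor rises.
  These values put the simulated floor in a regime where denoising visibly
  raises SNR, as observed on the real instrument.
* `activity_model(spike_rate = 0.1, decay_tau = 4)` — events per frame and
  decay in frames, calibrated to a full-density acquisition at ~3.3 fps:
  roughly 0.3 Hz firing and ~1.2 s indicator decay, typical of cortical
  GCaMP6m recordings.

What the phantom does **not** model: vascular/neuropil background, motion
(the protocol explicitly excludes motion correction), indicator
nonlinearity, and the spiral trajectory itself (down-sampling acts digitally
on reconstructed frames, as in the original pipeline). Passing tests
therefore demonstrate the pipeline's mechanics and its statistical behaviour
under this generative model, not performance on real tissue.

## The restoration networks

The engine is a purpose-built reverse-mode implementation (RcppArmadillo
im2col convolutions, double precision throughout, Adam optimizer). The
generator is a U-Net: stride-2 4×4 convolutions with leaky ReLU (0.2) down,
a 3×3 bottleneck, and a decoder of nearest-neighbour upsampling followed by
3×3 convolutions with skip concatenations — the "resize-convolution" variant
of the pix2pix decoder, chosen over transposed convolutions to avoid
checkerboard artifacts and keep the hand-written backward pass simple. The
final tanh maps to the canonical normalized range; intensities are scaled
8-bit ↔ [-1, 1] symmetrically on the way in and out. No batch or instance
normalization is used: the desk-scale networks are shallow, and omitting
normalization keeps training exactly reproducible for a given seed.

The discriminator is a PatchGAN over (candidate, condition) pairs: stride-2
4×4 convolutions, then two stride-1 4×4 layers emitting a per-patch logit
field. The number of stride-2 levels is chosen so the receptive field best
matches `patch_scale` (16, 34, 70, 142, ... px); larger patches mean
spatially smaller decision fields.

The objective is the standard conditional-GAN value function — the
discriminator maximizes `mean log D(x, y) + mean log(1 − D(G(z, y), y))` —
combined with `l1_weight` times the mean absolute deviation from the ground
truth for the generator. The generator uses the non-saturating update by
default (`-mean log D(G, y)`), with the literal minimax form selectable,
since published descriptions of such systems are usually written in minimax
form while implementations descend from the non-saturating convention. The
noise input z is realized as decoder dropout during training (rate 0.5 by
default); inference is deterministic. Losses are computed at the logit level
through softplus for numerical safety; analytic gradients are verified
against central finite differences at 1e-4 relative tolerance in the tests.

Hyperparameter defaults follow the pix2pix lineage: `l1_weight = 100`,
`patch_scale = 70`, `lr = 2e-4`, Adam (0.9, 0.999), batch size 1. The
desk-scale test tasks use `lr = 5e-4`, which converges faster on the small
32–64 px networks.

## The two-stage transfer protocol

Stage 1 (`make_dnn1_dataset` + `train_gan`): per static field of view, the
ground truth is the k-frame average (k = 10 by default, emulating a slow
high-SNR acquisition) and the input one randomly chosen frame with
augmentation noise drawn at a random speed from `augment_speed_range`.
One pair per field of view is the protocol's default; `pairs_per_stack`
enlarges small synthetic datasets. It matters that stage-1 scenes are
static: with dynamic scenes the time-averaged ground truth teaches the
denoiser to pull instantaneous brightness toward the temporal mean,
systematically flattening calcium transients. This is exactly why the
original protocol uses anatomical (ex vivo) data for its denoiser.

Stage 2 (`make_dnn2_dataset`): each frame of a second, dynamic dataset is
enhanced by the trained stage-1 network, and that output — never the raw
frame — is the intermediate ground truth, paired with the same frame
radially down-sampled by M. One stage-2 network is trained per M. Under
`init_scheme = "pretrain"` the stage-2 generator and discriminator start
from the stage-1 weights (the learning-transfer mechanism); `scratch` uses
fresh initialization, and the two reach comparable validation error on the
phantom task, which the tests assert within 25% relative. A `single_stage`
mode trains one network directly from static pairs to denoise and inpaint
simultaneously — the ablation known to be suboptimal — for comparison.

Desk-scale problem sizes: the end-to-end suite runs 64×64 phantoms (8 static
fields of view for stage 1, 3 pairs each, 80 epochs; 6 dynamic stacks of 8
frames for stage 2 at M = 8, 15 epochs), which trains both stages in about
two minutes on one CPU while leaving clear margins on the improvement
properties. Parity-scale runs at 512×512 use the same code paths.

## Metrics

* **SNR (dB)**: `10·log10` of mean soma intensity over mean adjacent
  background intensity. Background ROIs are annuli around each soma,
  restricted to structure-free pixels, with a 2-pixel inner margin so the
  measurement is not contaminated by soma-edge spill-over (standard ROI
  hygiene; the published definition says only "adjacent to the neuron").
* **ΔF/F**: soma mean minus adjacent-background mean per frame; the baseline
  is the 10th percentile of that subtracted trace (configurable — the
  protocol states background subtraction but no percentile); the trace is
  divided by the baseline and then peak-normalized to 1. The whole-trace
  maximum is used for normalization.
* **NRMSE** (trace and image): RMSE divided by the range of the *evaluated*
  signal — not the reference. That asymmetric form is the published
  definition and is kept literally; a regression test pins the asymmetry.
* **MS-SSIM**: canonical five-scale weights (0.0448, 0.2856, 0.3001, 0.2363,
  0.1333), 11×11 Gaussian window (σ 1.5), K1 = 0.01, K2 = 0.03 on the 8-bit
  dynamic range; contrast/structure at every scale, luminance at the
  coarsest; 2×2 mean pooling between scales. With fewer scales (needed below
  176×176) the leading weights are renormalized. Negative contrast terms are
  clamped at zero before exponentiation. The implementation is cross-checked
  against an independently coded reference to 1e-6.

## Numerical and degenerate-input choices

Intensities are stored as doubles on the 8-bit scale and only quantized at
TIFF write time; frame averages are returned at full precision. Logs in the
GAN losses are evaluated through softplus (no log of a raw probability);
probabilities reported to users are clamped to (0, 1). All-zero traces are
returned as zeros rather than an error; constant evaluated images or traces
make NRMSE undefined and raise a data error, as do non-positive ΔF/F
baselines and zero-mean backgrounds in SNR. Every stochastic stage draws its
randomness from a seed derived deterministically from one global seed, so a
single integer reproduces scene placement, spike trains, noise, weight
initialization, shuffling and dropout; reruns are bit-identical on a fixed
backend.

## Known limitations

The networks are desk-scale by default; parity with a GPU-trained 512×512
system is a matter of compute, not code paths, but has not been run here.
The phantom's noise model covers shot and read noise only; detector
afterpulsing, line artifacts and motion are absent, so real-data performance
claims cannot be made from these tests. The uniform ring spacing
approximates the true resonant spiral geometry. MS-SSIM requires frames of
at least 11·2^(scales−1) pixels, so small phantoms are evaluated with 2–3
scales rather than the canonical 5.
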