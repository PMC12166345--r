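---
title: "Model-free axial localisation for 3D SMLM: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-free axial localisation for 3D SMLM: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Two-dimensional single-molecule localisation microscopy (SMLM) recovers the
lateral position of sparse blinking emitters to tens of nanometres, but the
axial (Z) position is not directly observed. On microscopes with an
engineered astigmatism the PSF ellipticity encodes Z; on a standard
(unmodified) microscope the intrinsic aberrations still deform the PSF with
defocus, weakly and in a way that varies across the field of view. `smlmz`
learns this instrument-specific signature empirically — no PSF model is
assumed — from calibration Z-stacks of sub-resolution fluorescent beads, and
then assigns a Z value to every 2D localisation produced by standard
software.

The pipeline has five stages, each usable on its own:

1. **simulate** — seeded synthetic bead stacks, SMLM movies and
   nuclear-pore-like structures with ground truth (so the whole pipeline is
   testable without a microscope);
2. **calibrate** — turn full-FOV bead Z-stacks into a quality-controlled,
   Z-aligned, augmented training set;
3. **zmodel** — train the two-branch convolutional regressor
   (image, field position) → Z;
4. **localize** — crop per-localisation ROIs, predict Z, correct axial
   drift;
5. **analyze** — per-structure axial KDE profiles, peak detection and the
   double-ring "success" benchmark.

# The regressor

The model maps a `64 × 64` localisation image (intensities divided by the
16-bit camera maximum, 65535) plus the normalised field position
`(u, v) ∈ [−1, 1]²` to the axial position. An image branch (a convolutional
backbone) embeds the crop; a coordinate branch (two dense layers, 64→64)
embeds the position, so the network can represent *field-dependent*
shape→Z mappings; the concatenated embedding passes through dropout (0.2 by
default; the package's benchmark uses 0.1) and dense layers to a single
scalar. Training minimises mean squared error
with AdamW; the learning rate is halved when the training loss plateaus,
and training stops early once the validation loss stops improving (the
best-validation weights are restored).

Two backbones are available:

* `tiny_cnn` (default for everything in this package): a 4×4 average pool
  (lossless here, because the 64×64 input is a bilinearly upsampled 15×15
  crop) followed by two small convolutions (16 and 32 channels) and a
  128-dimensional embedding, ~170k parameters. It trains in minutes on one
  CPU core.
* `mobilenet_v3_small`: a structural implementation of the
  MobileNetV3-small feature extractor (inverted residual blocks with
  depthwise convolutions, squeeze-excitation, hard-swish), ~2–3M
  parameters. Normalisation layers are folded into per-channel affine
  transforms, and no pretrained weights are shipped — the backbone starts
  from a random initialisation. It exists to document the architecture at
  full scale; the package's own experiments use `tiny_cnn`.

Design choices worth stating explicitly:

* **Target scaling.** Z is regressed in units of the working half-range
  (default 1000 nm), so targets lie in roughly `[−1, 1]`; predictions are
  rescaled to nm. The scaling is stored with the model and checked at
  prediction time.
* **Input gain.** Bead images normalised by 65535 occupy only ~1% of
  `[0, 1]`; a fixed gain of 100 applied inside the network restores a
  dynamic range that ReLU stacks optimise well on. This is an architecture
  constant, not a data-dependent normalisation, and is saved with the
  model.
* **The engine.** The layers, backpropagation and AdamW optimiser are
  implemented in base R on BLAS-backed matrix algebra (convolution via
  precomputed im2col index maps; the backward scatter as a sparse-matrix
  product). Every layer's gradient is validated against central finite
  differences in the test suite. All randomness (initialisation, dropout,
  shuffling) goes through R's RNG, so a seed reproduces a run bit for bit.

# Calibration preprocessing

Starting from a full-FOV bead Z-stack (stage scan, fixed step):

1. **Focus frame** — the frame holding the global maximum pixel value.
2. **ROI extraction** — 15×15 crops about each bead position through all
   frames; beads within 7 px of the border are rejected (no padding, which
   would distort the PSF shapes the model trains on).
3. **Quality control** — in order: co-localisation (another bead centre
   within 15 px), minimum SNR (max/mean of the whole ROI stack ≥ 2), axial
   noise (normalised RMS residual of a 1D skew-Gaussian fit to the
   per-frame maximum-intensity profile ≤ 0.18), lateral noise (2D
   skew-Gaussian fit to the focus frame, residual ≤ 0.08). Each bead gets
   exactly one verdict; a non-converging fit rejects the bead rather than
   erroring. The two residual thresholds are not published numbers; they
   were calibrated once on the package's simulator so that clean beads sit
   well below and heavily corrupted beads well above (see
   `qc_thresholds()`).
4. **Relative offsets (δZ)** — every bead is aligned to a reference bead
   by an exhaustive integer frame-shift search. The objective combines the
   mean squared difference of (3×3-box-smoothed, max-normalised) pixel
   intensities with the same criterion applied to the smoothed axial
   sharpness profile, the two terms range-normalised and summed. The pixel
   term alone is biased when the two beads sit in differently aberrated
   field regions, and is shot-noise dominated for dim beads; the profile
   term anchors the shift to the axial intensity structure. Candidate
   shifts must overlap by at least half the stack depth (spurious minima
   otherwise appear at extreme shifts). No sub-frame interpolation is
   done: δZ is an integer number of frames times the stage step.
5. **Reference bead and absolute Z = 0** — the reference is the
   highest-SNR bead within the central quarter of the FOV (a dim
   nearest-centre bead makes every downstream label noisy; the plain
   nearest-centre rule is available via the `reference` argument). The
   Z = 0 frame defaults to a *consensus*: each bead's own sharpness-peak
   frame is mapped back to reference coordinates through its δZ and the
   median is taken, which averages single-bead noise out of a quantity
   that offsets every label in the field. The single-reference rule
   remains available (`z0 = "reference"`). Sharpness is gradient energy
   computed on a 3×3-box-smoothed frame — raw gradient energy is dominated
   by the noise floor on dim beads — with the per-frame score profile
   smoothed over 5 frames; the metric is injectable.
6. **Dataset** — one datapoint per (bead, frame) with |Z| ≤ 1000 nm;
   per-bead 70/15/15 train/val/test split (never per frame, so no bead
   leaks across splits); images resized to 64×64 and divided by 65535;
   coordinates mapped to `[−1, 1]`; the training split augmented to
   exactly three times its original size.

**Augmentation semantics.** Each augmented copy receives additive Gaussian
noise (μ = 0, σ = 0.005), a multiplicative brightness factor drawn
uniformly from `[1 − 0.075, 1 + 0.075]`, and Poisson resampling with
λ = 226. A Poisson rate of 226 applied to a `[0, 1]` image is ill-posed as
stated, so it is implemented as `pixel ← Poisson(λ·pixel)/λ`, which
preserves the intensity scale and the mean while injecting shot-noise-like
fluctuations; the augmentation chain is applied after the 64×64 resize.
Augmented copies keep their source's exact Z label and coordinates.

# Applying the model and drift correction

Inference reuses the calibration geometry: 15×15 crops about each
localisation's pixel, the same resize and 16-bit rescale, the same
coordinate normalisation; border localisations are skipped with a recorded
reason, never silently dropped (record counts are conserved). A model
refuses tables whose FOV or pixel size differ from its calibration.

Axial drift is estimated from the mean Z of localisations in blocks of 500
sequential frames (the last partial block keeps its own mean), a smoothed
cubic spline fitted to block means versus block-centre frames (centre =
median frame of the block's records; effective degrees of freedom
≈ n_blocks/3, at least 2; a linear fit replaces the spline below four
blocks), and each record corrected by the spline offset relative to the
global mean Z — so a constant offset is deliberately *not* removed, and a
second pass is a near no-op.

# Nuclear-pore benchmark

The nucleoporin Nup96 forms two parallel rings of 8 protein clusters,
46 nm apart — a de facto axial resolution standard. For each picked
structure the axial density is modelled as a Gaussian KDE,
`d(g) = Σ φ((g − zᵢ)/h)/h` with h = 15 nm by default, evaluated on a 1 nm
grid spanning the data ± 3h. The density is deliberately *not* divided by
the localisation count (units: localisations/nm), so the published minimum
peak prominence of 0.0001 is interpretable per localisation; the
N-normalised convention is selectable. Peaks are local maxima ranked by
topographic prominence (height above the higher of the two minima
separating the peak from higher ground on each side); a structure is
"successful" iff its two most prominent peaks are separated by 40–60 nm
inclusive. The render threshold for X/Z images is the mean of the mean
peak height and the density at the local minimum between the two most
prominent peaks.

A caveat worth understanding: a Gaussian KDE pulls the modes of two
overlapping components toward each other. With localisation noise
σ_z = 15 nm and h = 15 nm the effective per-ring smoothing is
√(15² + 15²) ≈ 21 nm against a half-separation of 23 nm — barely bimodal —
so recovered separations for small pores (~30 localisations) sit a few nm
below the geometric 46 nm, a substantial fraction of pores yield a single
merged peak, and well under half classify "successful". This is a property
of the estimator at those noise levels, not an implementation artefact;
at σ_z ≤ 5 nm the recovered separation is within ~2 nm of truth and the
success rate is high. The success-versus-bandwidth curve shows the
expected oversmoothing decline at large h.

# The simulator

The simulator is the package's source of ground truth. The PSF is an
elliptical Gaussian, pixel-integrated exactly (products of error
functions), with widths
`σ_{x,y}(z, u, v) = σ₀ + a_{x,y}(u, v)·z + c·z²` (z in µm). Defaults,
chosen once to emulate a standard microscope with weak intrinsic
aberrations: σ₀ = 150 nm; a_x = 70 + 40u − 25v and
a_y = −70 − 35u + 30v nm/µm (opposite signs make the ellipse orientation
flip through focus, i.e. the Z-sign signal; the lateral variation is the
field dependence the coordinate branch must learn; the two rates are
nowhere equal, so Z is encoded everywhere); c = 45 nm/µm², which keeps
both widths positive at all defocus because 4·c·σ₀ exceeds max(a²);
photon budget 5000 per emitter per frame with a per-bead brightness
factor U[0.4, 1.6] emulating the spread of exposures and excitation
powers used for real calibration acquisitions; background 20
photons/pixel; Gaussian read noise (σ = 2); baseline 100 counts; 16-bit
clipping; pixel size 110 nm; 256×256 px FOV. Bead stacks follow the
standard acquisition geometry (symmetric range, fixed step,
`round(range/step) + 1` frames; −3..+3 µm at 10 nm gives 601 frames),
with per-bead focal offsets (σ = 150 nm) standing in for coverslip tilt
and bead height variation — these are what δZ alignment must recover.
Blinking movies draw a Poisson number of active emitters per frame;
nuclear pores are two rings of 8 clusters at z₀ ± 23 nm with Poisson
cluster occupancy (each ring guaranteed at least one localisation) and
Gaussian localisation errors.

What the simulator does **not** emulate: vectorial/Zernike PSF structure,
dipole orientation effects, sCMOS pixel-dependent gain maps, fluorophore
photophysics beyond per-frame blinking, lateral drift, and sample
background structure. Passing the package's tests therefore demonstrates
that the pipeline recovers what this generative family encodes — it does
not certify performance on any particular real instrument, where
calibration quality and aberration strength differ.

# Problem sizes and numerical choices

The package's own benchmark (used by the test suite and the acceptance
script) calibrates on ~300 beads across 10 simulated fields, ±1 µm at
50 nm steps, trains the `tiny_cnn` backbone (AdamW, initial learning rate
2×10⁻³, batch 128, dropout 0.1, up to 110 epochs with plateau halving and
early stopping), and evaluates on the held-out bead split; the nuclear-pore
benchmark uses 100 pores with ~2 localisations per cluster and
σ_z = 15 nm. These sizes keep a full run in the minutes range on a single
CPU core while leaving the learning problem non-trivial (field-dependent
astigmatism, 4× brightness spread, shot noise).

Numerical details that matter: focus/sharpness ties break to the lowest
frame (logged); the δZ search window is capped so overlaps stay ≥ half
the stack depth; KDE peak positions are grid-resolution limited (1 nm
default); prominence ties break by height then lower position; the
skew-Gaussian QC fits use moment-based starting values with
median-background subtraction (raw-minimum baselines inflate the width
estimate and can push Levenberg–Marquardt into divergence); degenerate
inputs (constant stacks, empty tables, all-NA Z) raise errors naming the
problem rather than propagating NaN.

# Known limitations

* δZ alignment is integer-frame; at coarse stage steps (50 nm) label
  granularity contributes visibly to per-bead evaluation error.
* The regressor gives no per-localisation uncertainty; downstream
  analyses treat all Z values equally.
* Drift correction assumes the field drifts together (one spline for the
  whole FOV) and cannot separate real axial motion of the structure from
  stage drift.
* The KDE peak-pull bias described above means ring-separation estimates
  at high localisation noise are conservative (biased low).
* Training on CPU in R is minutes-scale for `tiny_cnn` but not intended
  for the mobilenet backbone at full dataset sizes.
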