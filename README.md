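# smlmz — model-free axial localisation for 3D SMLM

Single-molecule localisation microscopy (SMLM) resolves fluorophores
laterally to tens of nanometres, but a standard (unmodified) widefield
microscope does not measure depth. `smlmz` recovers the axial (Z)
coordinate from the information that is already in the data: the
microscope's intrinsic, field-dependent aberrations deform the point
spread function (PSF) as an emitter defocuses, and that deformation can be
learned empirically from calibration Z-stacks of sub-resolution beads —
no PSF model, no cylindrical lens, no hardware changes.

The package is aimed at microscopists and methods developers who run 2D
SMLM with standard tools (ThunderSTORM- or PICASSO-style localisation
tables) and want 3D reconstructions plus a quantitative axial resolution
benchmark, and at anyone who needs a fully synthetic, seeded test bed for
axial-localisation pipelines.

## The model

A two-branch convolutional regressor estimates the axial position of one
emitter:

    ẑ = f_θ( I, (u, v) )

* `I` — the 64 × 64 crop around the localisation, intensities divided by
  the 16-bit camera maximum;
* `(u, v) ∈ [−1, 1]²` — the localisation's normalised position in the
  field of view, passed through its own dense branch so the network can
  express *spatially varying* shape→depth mappings;
* training data — calibration bead Z-stacks: each quality-controlled bead
  contributes one image per stage position, with its per-bead focal
  offset (δZ) removed by aligning it to a reference bead and the field's
  Z = 0 set by an image-sharpness consensus;
* fitting — AdamW on a mean-squared-error loss, learning-rate reduction
  on plateau, early stopping on the validation beads.

Downstream, Z-drift is corrected with a smoothed cubic spline through
500-frame windowed means, and double-ring structures (nucleoporin
standards, rings 46 nm apart) are scored by a Gaussian-kernel density
estimate of their axial profile: a structure is "successfully" resolved
when its two most prominent peaks (topographic prominence ≥ 0.0001) are
40–60 nm apart.

A seeded simulator (field-dependent elliptical-Gaussian PSFs with exact
pixel integration, Poisson + read-noise camera model, blinking emitters,
double-ring structures) provides ground truth for every stage.

## A worked example

```r
library(smlmz)

## a synthetic microscope and one calibration acquisition
psf   <- field_psf_model()                       # 256x256 px @ 110 nm
stack <- generate_bead_stack(psf, n_beads = 30, z_min_um = -1,
                             z_max_um = 1, z_step_nm = 50, seed = 1)

## calibration preprocessing: extract, QC, align
beads <- extract_bead_rois(stack, stack$truth, roi = 15)
qc    <- qc_filter(beads)
al    <- align_z_offsets(qc$kept, z_step_nm = 50)
ds    <- build_dataset(al$beads, z_range_nm = 1000, seed = 1)
ds
#> Calibration dataset: 2692 datapoints (30 beads), 64 x 64 images
#>        augmented
#> split   FALSE TRUE
#>   train   782 1564
#>   val     195    0
#>   test    151    0

## train and evaluate the regressor
reg <- zreg_build(backbone = "tiny_cnn", seed = 1)
reg <- zreg_train(reg, ds, train_config(max_epochs = 40, lr = 2e-3, seed = 1))
zreg_evaluate(reg, ds, "test")
#> RMSE 107.00 nm over 151 datapoints (4 beads)
#> predicted-vs-true slope 0.983, intercept -44.2 nm
```

(One field of 30 beads is the minimal demo; the package's own benchmark
calibrates on ~300 beads across ten fields and reaches a held-out RMSE
well under 120 nm — see below.) The RMSE is the root-mean-squared
difference between predicted and stage-derived axial positions on beads
the model never saw; the slope near 1 says predictions track the stage
movement rather than regressing to the mean.

The structural benchmark:

```r
npc <- generate_npc_localisations(100, npc_geometry(), seed = 2)
rep <- analyse_pores(npc, success_criteria(bandwidth = 15))
mean(rep$separation_nm, na.rm = TRUE)   # mean two-peak separation (nm)
#> [1] 40.80488
table(rep$classification)
#>   successful unsuccessful
#>           26           74
```

At the default axial localisation error (15 nm) the 15 nm KDE bandwidth
sits at the edge of what can resolve a 46 nm double ring — peaks are
pulled together and many pores merge into a single peak, so the recovered
separation is biased a few nanometres low and only a minority classify as
"successful"; at lower axial noise both recover sharply (see the methods
vignette for the analysis).

## Command line

A thin wrapper over the same functions lives in `inst/cli/smlmz.R`:

```sh
Rscript inst/cli/smlmz.R simulate  --config cfg.yaml --seed 7 --out run1
Rscript inst/cli/smlmz.R calibrate --config cfg.yaml --out run1
Rscript inst/cli/smlmz.R train     --config cfg.yaml --out run1
Rscript inst/cli/smlmz.R analyse   --config cfg.yaml --out run1
```

All stage parameters live in one YAML configuration (see
`default_config()`); every artefact is written with a provenance sidecar
(seed + configuration hash), and a rerun with the same seed reproduces
the artefacts bit for bit.

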