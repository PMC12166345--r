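# Shared fixtures, memoised per session so expensive simulations and model
# fits are built once and reused across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Small PSF model on a reduced FOV: keeps full-FOV renders cheap in unit
# tests while retaining field-dependent astigmatism.
fix_model <- function() memo("model", function() {
  field_psf_model(fov_px = c(128, 128))
})

# One small calibration acquisition: 12 beads, +/-1.1 um, 100 nm steps.
fix_stack <- function() memo("stack", function() {
  generate_bead_stack(fix_model(), n_beads = 12, z_min_um = -1.1,
                      z_max_um = 1.1, z_step_nm = 100, seed = 42)
})

fix_aligned <- function() memo("aligned", function() {
  st <- fix_stack()
  beads <- suppressMessages(extract_bead_rois(st, st$truth, roi = 15))
  qc <- suppressMessages(qc_filter(beads))
  suppressMessages(align_z_offsets(qc$kept, z_step_nm = 100))
})

fix_dataset <- function() memo("dataset", function() {
  suppressMessages(build_dataset(fix_aligned()$beads, z_range_nm = 1000,
                                 seed = 7))
})

# Full-scale calibration + training run shared by the acceptance tests and
# the model property tests: ~300 beads over 10 fields, +/-1 um at 50 nm
# steps, field-dependent astigmatism and shot noise, tiny_cnn backbone.
# Alongside the dataset (whose labels come from the calibration pipeline)
# the fixture records each kept bead's generator focal offset, so per-bead
# accuracy can also be measured against the simulator's ground truth.
fix_benchmark <- function() memo("benchmark", function() {
  seed <- 20240901
  model <- field_psf_model()
  kept <- list()
  z0_true <- list()
  stage_z <- NULL
  for (f in 1:10) {
    st <- generate_bead_stack(model, n_beads = 30, z_min_um = -1,
                              z_max_um = 1, z_step_nm = 50,
                              seed = seed + f, fov_id = f)
    stage_z <- st$stage_z_nm
    beads <- suppressMessages(extract_bead_rois(st, st$truth, roi = 15))
    qc <- suppressMessages(qc_filter(beads))
    al <- suppressMessages(align_z_offsets(qc$kept, z_step_nm = 50))
    for (b in al$beads) z0_true[[paste0(f, ":", b$id)]] <- st$truth$z0_nm[b$id]
    kept <- c(kept, al$beads)
  }
  ds <- suppressMessages(build_dataset(kept, z_range_nm = 1000,
                                       seed = seed))
  reg <- suppressMessages(zreg_build(seed = seed, dropout_rate = 0.1))
  cfg <- train_config(max_epochs = 110, lr = 2e-3, lr_patience = 5,
                      early_stop_patience = 15, seed = seed)
  reg <- suppressMessages(zreg_train(reg, ds, cfg))
  snr <- vapply(kept, function(b) b$snr, numeric(1))
  names(snr) <- vapply(kept, function(b) paste0(b$fov_id, ":", b$id),
                       character(1))
  list(model = model, dataset = ds, regressor = reg, beads = kept,
       snr = snr, z0_true = z0_true, stage_z = stage_z, seed = seed)
})

# Per-bead RMSE of predictions against the generator's true defocus for a
# benchmark bead key, over frames within the working range.
bench_bead_rmse_vs_truth <- function(bench, key, z_range = 1000) {
  ds <- bench$dataset
  b <- bench$beads[[which(names(bench$snr) == key)]]
  idx <- which(ds$bead_key == key & !ds$augmented)
  frame_k <- match(round(ds$z[idx]), round(b$z_rel))
  z_true <- bench$stage_z[frame_k] - bench$z0_true[[key]]
  keep <- abs(z_true) <= z_range
  pred <- predict_z(bench$regressor, ds$images[, , idx],
                    ds$coords[idx, , drop = FALSE])
  sqrt(mean((pred[keep] - z_true[keep])^2))
}

# Minimal hand-built calibration dataset wrapper (used for memorisation and
# degenerate-label tests, where per-bead splitting is deliberately bypassed).
make_dataset <- function(images, coords, z, split, bead_key = NULL) {
  structure(list(images = images, coords = coords, z = z,
                 split = factor(split, levels = c("train", "val", "test")),
                 augmented = rep(FALSE, length(z)),
                 bead_id = seq_along(z),
                 bead_key = bead_key %||% rep("b1", length(z)),
                 meta = list(z_range_nm = 1000, image_size = 64,
                             fov_px = c(128, 128), pixel_size = 110)),
            class = "calibration_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
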