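## Seeded generators for calibration bead stacks, blinking SMLM movies and
## synthetic nuclear-pore localisation sets, each with ground truth. These
## emulate the acquisitions the pipeline is calibrated and benchmarked on:
## bead Z-stacks over a symmetric range at a fixed step, and double-ring
## nucleoporin structures 46 nm apart used as an axial resolution standard.

## Draw n points uniformly over the FOV with a minimum pairwise spacing
## (rejection sampling). Spacing default 2x the crop width so that the
## co-localisation QC rule is not triggered by construction.
place_beads <- function(n, fov_px, pixel_size, min_spacing_px, border_px) {
  if (n == 0) return(cbind(x_nm = numeric(0), y_nm = numeric(0)))
  min_d2 <- (min_spacing_px * pixel_size)^2
  xs <- numeric(n); ys <- numeric(n); placed <- 0L; tries <- 0L
  lo_x <- border_px * pixel_size
  hi_x <- (fov_px[1] - border_px) * pixel_size
  lo_y <- border_px * pixel_size
  hi_y <- (fov_px[2] - border_px) * pixel_size
  while (placed < n) {
    tries <- tries + 1L
    if (tries > 200L * n)
      stop("could not place beads at the requested spacing; reduce n_beads ",
           "or min_spacing_px", call. = FALSE)
    x <- runif(1, lo_x, hi_x); y <- runif(1, lo_y, hi_y)
    if (placed == 0L ||
        all((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2 >= min_d2)) {
      placed <- placed + 1L
      xs[placed] <- x; ys[placed] <- y
    }
  }
  cbind(x_nm = xs, y_nm = ys)
}

## Camera sampling of an expected-photon frame -> integer counts.
camera_sample <- function(expected, model) {
  n <- length(expected)
  counts <- rpois(n, lambda = pmax(as.vector(expected), 0)) +
    rnorm(n, sd = model$read_noise_sd) + model$baseline
  matrix(pmin(pmax(round(counts), 0), INT16_MAX), nrow = nrow(expected))
}

## Add one emitter's expected-photon patch into a full-FOV frame in place.
add_emitter <- function(frame, model, x_nm, y_nm, z_nm, photons, support_px) {
  px <- model$pixel_size
  cx <- floor(x_nm / px); cy <- floor(y_nm / px)
  cols <- max(0L, cx - support_px):min(model$fov_px[1] - 1L, cx + support_px)
  rows <- max(0L, cy - support_px):min(model$fov_px[2] - 1L, cy + support_px)
  patch <- psf_expected_patch(model, x_nm, y_nm, z_nm, photons, cols, rows)
  frame[rows + 1L, cols + 1L] <- frame[rows + 1L, cols + 1L] + patch
  frame
}

#' Generate a calibration bead Z-stack with ground truth
#'
#' Simulates a full-FOV stage scan over `[z_min_um, z_max_um]` in steps of
#' `z_step_nm`: beads are placed uniformly over the field with a minimum
#' pairwise spacing, each with its own focal offset (emulating coverslip
#' tilt / bead height variation) and brightness factor (emulating the spread
#' of exposures and excitation powers used in practice). At stage position
#' `Z` a bead with focal offset `z0` is rendered at defocus `Z - z0` with
#' the model's field-dependent PSF, and frames are sampled with Poisson shot
#' noise, Gaussian read noise and baseline.
#'
#' @param model A [field_psf_model()].
#' @param n_beads Number of beads (>= 0).
#' @param z_min_um,z_max_um Stage range (um), `z_max_um > z_min_um`.
#' @param z_step_nm Stage step (nm), > 0. The frame count is
#'   `round((z_max - z_min)/step) + 1`.
#' @param seed Integer seed; same seed gives a bit-identical stack.
#' @param min_spacing_px Minimum pairwise bead spacing (pixels); default
#'   twice the 15-px crop width so co-localisation QC passes by construction.
#' @param focal_sd_nm SD of per-bead focal offsets (nm).
#' @param brightness_range Per-bead uniform brightness factor range applied
#'   to the model photon budget.
#' @param fov_id Identifier stored with the truth table.
#' @return A list of class `bead_stack` with `frames` (list of count
#'   matrices), `stage_z_nm`, `truth` (data.frame: id, x_nm, y_nm, z0_nm,
#'   photons), plus the model and acquisition metadata.
#' @export
generate_bead_stack <- function(model, n_beads = 30, z_min_um = -3,
                                z_max_um = 3, z_step_nm = 10, seed = NULL,
                                min_spacing_px = 30, focal_sd_nm = 150,
                                brightness_range = c(0.4, 1.6),
                                fov_id = 1L) {
  stopifnot(inherits(model, "field_psf_model"), n_beads >= 0)
  stopifnot_scalar(z_step_nm, "z_step_nm", positive = TRUE)
  if (z_max_um <= z_min_um) stop("z_max_um must exceed z_min_um", call. = FALSE)
  n_frames <- as.integer(round((z_max_um - z_min_um) * 1000 / z_step_nm)) + 1L
  stage_z <- z_min_um * 1000 + (seq_len(n_frames) - 1L) * z_step_nm
  with_seed(seed, {
    pos <- place_beads(n_beads, model$fov_px, model$pixel_size,
                       min_spacing_px, border_px = 10L)
    z0 <- rnorm(n_beads, 0, focal_sd_nm)
    bright <- runif(n_beads, brightness_range[1], brightness_range[2])
    truth <- data.frame(id = seq_len(n_beads),
                        fov_id = rep(fov_id, n_beads),
                        x_nm = pos[, "x_nm"], y_nm = pos[, "y_nm"],
                        z0_nm = z0, photons = bright * model$photon_budget)
    support <- 12L  # +-12 px covers > 5 sigma at the largest simulated widths
    frames <- vector("list", n_frames)
    base <- matrix(model$background, model$fov_px[2], model$fov_px[1])
    for (k in seq_len(n_frames)) {
      fr <- base
      for (b in seq_len(n_beads)) {
        fr <- add_emitter(fr, model, truth$x_nm[b], truth$y_nm[b],
                          stage_z[k] - z0[b], truth$photons[b], support)
      }
      frames[[k]] <- camera_sample(fr, model)
    }
    structure(list(frames = frames, stage_z_nm = stage_z, truth = truth,
                   model = model, z_step_nm = z_step_nm,
                   fov_px = model$fov_px, pixel_size = model$pixel_size),
              class = "bead_stack")
  })
}

#' @export
print.bead_stack <- function(x, ...) {
  cat(sprintf("Bead Z-stack: %d frames, %d beads, step %g nm, FOV %d x %d px\n",
              length(x$frames), nrow(x$truth), x$z_step_nm,
              x$fov_px[1], x$fov_px[2]))
  invisible(x)
}

#' Generate a blinking SMLM movie from a structure
#'
#' Each frame activates a Poisson-distributed number of emitters drawn (with
#' replacement) from the structure set and renders them at their true
#' positions with the field-dependent PSF; frames are sampled with the
#' camera noise model. An optional axial drift function offsets every
#' emission's z by `z_drift_fn(frame)`; the ground truth records the drifted
#' (i.e. actually rendered) z.
#'
#' @param structure Data frame of true emitter positions with columns
#'   `x_nm`, `y_nm`, `z_nm` (one row per binding site / fluorophore).
#' @param model A [field_psf_model()].
#' @param n_frames Number of movie frames.
#' @param mean_on_per_frame Expected active emitters per frame (> 0).
#' @param seed Integer seed.
#' @param z_drift_fn Optional function of the 0-based frame index returning
#'   a z offset (nm) applied to all emissions in that frame.
#' @param blinking `"poisson"` (default) or `"all_on"` (every emitter in
#'   every frame; useful for deterministic fixtures).
#' @return List of class `smlm_movie` with `frames` (count matrices) and
#'   `truth` (data.frame: id, frame, x_nm, y_nm, z_nm, photons; frame is
#'   0-based).
#' @export
generate_smlm_movie <- function(structure, model, n_frames = 1000,
                                mean_on_per_frame = 5, seed = NULL,
                                z_drift_fn = NULL,
                                blinking = c("poisson", "all_on")) {
  stopifnot(inherits(model, "field_psf_model"))
  blinking <- match.arg(blinking)
  if (NROW(structure) == 0)
    stop("structure set is empty; nothing to image", call. = FALSE)
  if (blinking == "poisson")
    stopifnot_scalar(mean_on_per_frame, "mean_on_per_frame", positive = TRUE)
  n_emit <- nrow(structure)
  with_seed(seed, {
    support <- 12L
    frames <- vector("list", n_frames)
    base <- matrix(model$background, model$fov_px[2], model$fov_px[1])
    truth_list <- vector("list", n_frames)
    for (k in seq_len(n_frames)) {
      idx <- if (blinking == "all_on") seq_len(n_emit)
             else {
               n_on <- rpois(1, mean_on_per_frame)
               if (n_on > 0) sample.int(n_emit, n_on, replace = TRUE) else integer(0)
             }
      drift <- if (is.null(z_drift_fn)) 0 else z_drift_fn(k - 1L)
      fr <- base
      if (length(idx)) {
        for (i in idx) {
          fr <- add_emitter(fr, model, structure$x_nm[i], structure$y_nm[i],
                            structure$z_nm[i] + drift, model$photon_budget,
                            support)
        }
        truth_list[[k]] <- data.frame(id = idx, frame = k - 1L,
                                      x_nm = structure$x_nm[idx],
                                      y_nm = structure$y_nm[idx],
                                      z_nm = structure$z_nm[idx] + drift,
                                      photons = model$photon_budget)
      }
      frames[[k]] <- camera_sample(fr, model)
    }
    truth <- do.call(rbind, truth_list[!vapply(truth_list, is.null, logical(1))])
    if (is.null(truth))
      truth <- data.frame(id = integer(0), frame = integer(0),
                          x_nm = numeric(0), y_nm = numeric(0),
                          z_nm = numeric(0), photons = numeric(0))
    rownames(truth) <- NULL
    structure(list(frames = frames, truth = truth, model = model,
                   fov_px = model$fov_px, pixel_size = model$pixel_size),
              class = "smlm_movie")
  })
}

#' Nuclear-pore double-ring geometry
#'
#' Parameters of the synthetic nucleoporin standard: two parallel rings of
#' protein clusters separated axially by 46 nm, eight clusters per ring on a
#' ~107 nm diameter circle. Localisations scatter around the cluster centres
#' with the stated lateral and axial localisation errors.
#'
#' @param ring_separation Axial distance between the two rings (nm).
#' @param clusters_per_ring Clusters per ring (>= 1).
#' @param ring_diameter Ring diameter (nm).
#' @param loc_per_cluster Mean localisations per cluster (Poisson).
#' @param sigma_xy,sigma_z Lateral / axial localisation error SD (nm).
#' @return List of class `npc_geometry`.
#' @export
npc_geometry <- function(ring_separation = 46, clusters_per_ring = 8,
                         ring_diameter = 107, loc_per_cluster = 2,
                         sigma_xy = 10, sigma_z = 15) {
  stopifnot_scalar(ring_separation, "ring_separation", positive = TRUE)
  if (clusters_per_ring < 1) stop("clusters_per_ring must be >= 1", call. = FALSE)
  structure(list(ring_separation = ring_separation,
                 clusters_per_ring = as.integer(clusters_per_ring),
                 ring_diameter = ring_diameter,
                 loc_per_cluster = loc_per_cluster,
                 sigma_xy = sigma_xy, sigma_z = sigma_z),
            class = "npc_geometry")
}

#' Generate synthetic nuclear-pore localisations
#'
#' Places `n_pores` double-ring structures on a (optionally tilted) plane and
#' scatters localisations around the cluster centres. Each pore has two rings
#' of `clusters_per_ring` clusters at `z0 +/- ring_separation/2`; cluster
#' counts are Poisson with mean `loc_per_cluster` (with at least one
#' localisation guaranteed per ring so that every pore carries both layers).
#' With `sigma_z = 0` and `sigma_xy = 0` the generated z values per pore are
#' exactly the two ring planes.
#'
#' @param n_pores Number of pores (>= 1).
#' @param geometry An [npc_geometry()].
#' @param seed Integer seed.
#' @param field_nm Extent `c(width, height)` of the region the pore centres
#'   are scattered over (nm).
#' @param tilt `c(dz/dx, dz/dy)` slope of the supporting plane (nm/nm).
#' @return Data frame with `x_nm`, `y_nm`, `z_nm`, `pore` (integer label),
#'   `ring` (1 or 2) and attribute `geometry`.
#' @export
generate_npc_localisations <- function(n_pores, geometry = npc_geometry(),
                                       seed = NULL,
                                       field_nm = c(20000, 20000),
                                       tilt = c(0, 0)) {
  stopifnot(inherits(geometry, "npc_geometry"))
  if (n_pores < 1) stop("n_pores must be >= 1", call. = FALSE)
  g <- geometry
  with_seed(seed, {
    out <- vector("list", n_pores)
    for (p in seq_len(n_pores)) {
      cx <- runif(1, 0, field_nm[1]); cy <- runif(1, 0, field_nm[2])
      z0 <- tilt[1] * (cx - field_nm[1] / 2) + tilt[2] * (cy - field_nm[2] / 2)
      phase <- runif(1, 0, 2 * pi)
      ang <- phase + 2 * pi * (seq_len(g$clusters_per_ring) - 1) / g$clusters_per_ring
      rows <- vector("list", 2L)
      for (ring in 1:2) {
        zr <- z0 + (if (ring == 1) -1 else 1) * g$ring_separation / 2
        n_cl <- rpois(g$clusters_per_ring, g$loc_per_cluster)
        if (sum(n_cl) == 0) n_cl[sample.int(g$clusters_per_ring, 1)] <- 1L
        cl_idx <- rep.int(seq_len(g$clusters_per_ring), n_cl)
        n <- length(cl_idx)
        rows[[ring]] <- data.frame(
          x_nm = cx + (g$ring_diameter / 2) * cos(ang[cl_idx]) +
            rnorm(n, 0, g$sigma_xy),
          y_nm = cy + (g$ring_diameter / 2) * sin(ang[cl_idx]) +
            rnorm(n, 0, g$sigma_xy),
          z_nm = zr + rnorm(n, 0, g$sigma_z),
          pore = p, ring = ring)
      }
      out[[p]] <- rbind(rows[[1]], rows[[2]])
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    attr(res, "geometry") <- g
    res
  })
}

#' Write a frame stack as a multi-frame 16-bit TIFF
#'
#' @param stack A `bead_stack`, `smlm_movie`, or list of count matrices.
#' @param path Output file.
#' @export
write_stack_tiff <- function(stack, path) {
  frames <- if (is.list(stack) && !is.null(stack$frames)) stack$frames else stack
  imgs <- lapply(frames, function(f) f / INT16_MAX)
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-frame TIFF written by [write_stack_tiff()] back into counts
#'
#' @param path TIFF file.
#' @return List of integer count matrices.
#' @export
read_stack_tiff <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  lapply(imgs, function(f) round(f * INT16_MAX))
}

#' Write a ground-truth table as CSV
#'
#' Standard header (id, frame, x_nm, y_nm, z_nm, photons); bead-stack truth
#' tables (no frame column) are written with their own columns.
#'
#' @param truth Data frame.
#' @param path Output file.
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}
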