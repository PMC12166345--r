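## Calibration preprocessing: turn full-FOV bead Z-stacks into a filtered,
## Z-aligned training set. Stages: focus-frame identification, per-bead ROI
## extraction, quality control (co-localisation, SNR, skew-Gaussian axial and
## lateral noise checks), relative-offset (deltaZ) alignment against a
## reference bead, and absolute Z = 0 assignment by an image-sharpness metric.

#' Find the most in-focus frame of a stack
#'
#' The in-focus frame is identified as the frame containing the global
#' maximum pixel intensity across the stack. Ties are broken by the lowest
#' frame index (logged).
#'
#' @param stack A `bead_stack`, `bead_roi`, or list/array of frames.
#' @return 1-based frame index.
#' @export
find_focus_frame <- function(stack) {
  frames <- stack_frames(stack)
  if (length(frames) == 0) stop("empty stack", call. = FALSE)
  maxes <- vapply(frames, max, numeric(1))
  if (diff(range(vapply(frames, range, numeric(2)))) == 0 &&
      max(maxes) == min(vapply(frames, min, numeric(1))))
    stop("stack is constant: no focus frame can be identified", call. = FALSE)
  hits <- which(maxes == max(maxes))
  if (length(hits) > 1)
    smlmz_log("focus frame tie between frames %s; taking the lowest",
              paste(hits, collapse = ", "))
  hits[1]
}

## Normalise the various stack containers to a list of matrices.
stack_frames <- function(stack) {
  if (inherits(stack, "bead_roi"))
    return(lapply(seq_len(dim(stack$pixels)[3]), function(k) stack$pixels[, , k]))
  if (is.list(stack) && !is.null(stack$frames)) return(stack$frames)
  if (is.array(stack) && length(dim(stack)) == 3)
    return(lapply(seq_len(dim(stack)[3]), function(k) stack[, , k]))
  stopifnot(is.list(stack))
  stack
}

#' Extract per-bead ROI stacks from a full-FOV Z-stack
#'
#' Crops a `roi` x `roi` window about each bead position (rounded to the
#' containing pixel) through every frame of the stack. Positions within
#' `roi %/% 2` pixels of the border cannot be cropped and are rejected with
#' a log entry.
#'
#' @param stack A `bead_stack` (or list of frames plus explicit geometry).
#' @param xy_list Data frame with `x_nm`, `y_nm` (typically 2D localisations
#'   of the focus frame, or simulator ground truth) and optionally `id`.
#' @param roi Odd crop width (pixels).
#' @return List of `bead_roi` objects; rejected positions are reported in
#'   attribute `"rejected"`.
#' @export
extract_bead_rois <- function(stack, xy_list, roi = 15) {
  if (roi %% 2 == 0) stop("`roi` must be odd", call. = FALSE)
  if (NROW(xy_list) == 0) return(list())
  frames <- stack_frames(stack)
  fov_px <- c(ncol(frames[[1]]), nrow(frames[[1]]))
  pixel_size <- stack$pixel_size %||% stop("stack lacks pixel_size metadata")
  fov_id <- if (!is.null(stack$truth$fov_id)) stack$truth$fov_id[1] else 1L
  half <- roi %/% 2
  n_z <- length(frames)
  ids <- xy_list$id %||% seq_len(nrow(xy_list))
  beads <- list(); rejected <- list()
  for (i in seq_len(nrow(xy_list))) {
    cx <- floor(xy_list$x_nm[i] / pixel_size)  # 0-based pixel indices
    cy <- floor(xy_list$y_nm[i] / pixel_size)
    if (cx < half || cy < half || cx >= fov_px[1] - half || cy >= fov_px[2] - half) {
      smlmz_log("bead %s at (%d, %d) px too close to the border; rejected",
                ids[i], cx, cy)
      rejected[[length(rejected) + 1L]] <-
        data.frame(id = ids[i], reason = "border")
      next
    }
    px <- array(0, dim = c(roi, roi, n_z))
    rows <- (cy - half):(cy + half) + 1L
    cols <- (cx - half):(cx + half) + 1L
    for (k in seq_len(n_z)) px[, , k] <- frames[[k]][rows, cols]
    beads[[length(beads) + 1L]] <- structure(
      list(id = ids[i], pixels = px, fov_xy_px = c(cx, cy),
           x_nm = xy_list$x_nm[i], y_nm = xy_list$y_nm[i],
           fov_id = fov_id, fov_px = fov_px, pixel_size = pixel_size,
           snr = NA_real_, qc = "kept", z_rel = NULL, delta_z_nm = NA_real_),
      class = "bead_roi")
  }
  attr(beads, "rejected") <- if (length(rejected)) do.call(rbind, rejected)
                             else data.frame(id = integer(0), reason = character(0))
  beads
}

#' Signal-to-noise ratio of a bead ROI stack
#'
#' SNR is the ratio of the maximum pixel intensity to the mean pixel
#' intensity over the bead's entire image stack.
#'
#' @param bead A `bead_roi` (or array/list of frames).
#' @return Scalar ratio.
#' @export
compute_snr <- function(bead) {
  px <- if (inherits(bead, "bead_roi")) bead$pixels
        else simplify2array(stack_frames(bead))
  if (length(px) == 0) stop("empty stack", call. = FALSE)
  m <- mean(px)
  if (m == 0) stop("zero-mean stack: SNR undefined", call. = FALSE)
  max(px) / m
}

#' QC thresholds for calibration beads
#'
#' The minimum SNR follows the published rule (max/mean >= 2). The
#' skew-Gaussian residual thresholds bound the normalised root-mean-square
#' residual (RMS residual divided by the data range) of a 1D skew-Gaussian
#' fit to the axial maximum-intensity profile and of a 2D skew-Gaussian fit
#' to the focus-frame image; their defaults were calibrated on the package's
#' own simulator (clean beads sit well below, heavily corrupted beads well
#' above).
#'
#' @param min_snr Minimum max/mean intensity ratio (default 2).
#' @param max_z_fit_residual Normalised residual bound for the axial fit.
#' @param max_xy_fit_residual Normalised residual bound for the lateral fit.
#' @param coloc_radius Co-localisation rejection radius (pixels); default
#'   the 15-pixel crop width.
#' @return List of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_snr = 2, max_z_fit_residual = 0.18,
                          max_xy_fit_residual = 0.08, coloc_radius = 15) {
  stopifnot_scalar(min_snr, "min_snr", positive = TRUE)
  structure(list(min_snr = min_snr,
                 max_z_fit_residual = max_z_fit_residual,
                 max_xy_fit_residual = max_xy_fit_residual,
                 coloc_radius = coloc_radius),
            class = "qc_thresholds")
}

## Skew-Gaussian: A * exp(-t^2/2) * Phi(alpha * t), t = (x - xi)/omega,
## plus offset. Returns the normalised RMS residual, or NA on failure.
fit_skew_gaussian_1d <- function(y, x = seq_along(y)) {
  rng <- diff(range(y))
  if (rng == 0) return(NA_real_)
  model_fn <- function(p) {
    t <- (x - p[3]) / max(p[4], 1e-6)
    p[1] + p[2] * exp(-t^2 / 2) * pnorm(p[5] * t)
  }
  w <- pmax(y - min(y), 0)
  mu <- sum(x * w) / sum(w)
  sd0 <- sqrt(sum((x - mu)^2 * w) / sum(w))
  start <- c(min(y), 2 * rng, mu, max(sd0, 1e-3), 0)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = function(p) y - model_fn(p),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  sqrt(mean(residuals(fit)^2)) / rng
}

fit_skew_gaussian_2d <- function(img) {
  rng <- diff(range(img))
  if (rng == 0) return(NA_real_)
  nr <- nrow(img); nc <- ncol(img)
  xs <- rep(seq_len(nc), each = nr); ys <- rep(seq_len(nr), nc)
  v <- as.vector(img)
  model_fn <- function(p) {
    tx <- (xs - p[3]) / max(p[4], 1e-6)
    ty <- (ys - p[6]) / max(p[7], 1e-6)
    p[1] + p[2] * exp(-(tx^2 + ty^2) / 2) * pnorm(p[5] * tx) * pnorm(p[8] * ty)
  }
  ## median background subtraction keeps the moment-based start robust to
  ## noise floors; a raw-min baseline inflates the width estimate and can
  ## push the optimiser into a divergent basin
  w <- pmax(v - median(v), 0)
  mx <- sum(xs * w) / sum(w); my <- sum(ys * w) / sum(w)
  sx <- sqrt(sum((xs - mx)^2 * w) / sum(w))
  sy <- sqrt(sum((ys - my)^2 * w) / sum(w))
  start <- c(median(v), 4 * rng, mx, max(sx, 1e-3), 0, my, max(sy, 1e-3), 0)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = function(p) v - model_fn(p),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  sqrt(mean(residuals(fit)^2)) / rng
}

#' Quality-control filter for bead ROI stacks
#'
#' Applies, in order, the co-localisation rule (another bead centre within
#' `coloc_radius` pixels), the minimum-SNR rule, the axial-noise rule (1D
#' skew-Gaussian fit to the per-frame maximum-intensity profile) and the
#' lateral-noise rule (2D skew-Gaussian fit to the focus-frame image). Each
#' rejected bead carries the first rule it failed; a fit that does not
#' converge rejects the bead under the corresponding noise rule rather than
#' raising an error. Per-reason counts are logged.
#'
#' @param beads List of `bead_roi` from [extract_bead_rois()].
#' @param thresholds A [qc_thresholds()].
#' @return List with `kept` and `rejected` (both lists of `bead_roi` with
#'   the `qc` verdict set) and `counts` (named integer vector).
#' @export
qc_filter <- function(beads, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  n <- length(beads)
  if (n == 0) return(list(kept = list(), rejected = list(),
                          counts = c(kept = 0L)))
  pos <- do.call(rbind, lapply(beads, function(b) b$fov_xy_px))
  verdicts <- character(n)
  for (i in seq_len(n)) {
    b <- beads[[i]]
    d <- sqrt((pos[, 1] - pos[i, 1])^2 + (pos[, 2] - pos[i, 2])^2)
    d[i] <- Inf
    if (any(d < thresholds$coloc_radius)) {
      verdicts[i] <- "rejected:colocalised"; next
    }
    b$snr <- compute_snr(b)
    beads[[i]]$snr <- b$snr
    if (b$snr < thresholds$min_snr) {
      verdicts[i] <- "rejected:low_snr"; next
    }
    prof <- apply(b$pixels, 3, max)
    rz <- fit_skew_gaussian_1d(prof)
    if (is.na(rz) || rz > thresholds$max_z_fit_residual) {
      verdicts[i] <- "rejected:noisy_z"; next
    }
    focus <- find_focus_frame(b)
    rxy <- fit_skew_gaussian_2d(b$pixels[, , focus])
    if (is.na(rxy) || rxy > thresholds$max_xy_fit_residual) {
      verdicts[i] <- "rejected:noisy_xy"; next
    }
    verdicts[i] <- "kept"
  }
  for (i in seq_len(n)) beads[[i]]$qc <- verdicts[i]
  counts <- table(verdicts)
  smlmz_log("QC: %s", paste(names(counts), as.integer(counts),
                            sep = "=", collapse = ", "))
  list(kept = beads[verdicts == "kept"],
       rejected = beads[verdicts != "kept"],
       counts = counts)
}

#' Sharpness metrics
#'
#' `sharpness_gradient` (the default for absolute-Z assignment) is the sum
#' of squared spatial-gradient magnitudes computed on a 3 x 3 box-smoothed
#' copy of the frame: raw gradient energy is dominated by the shot-noise
#' floor on dim beads, and the light denoising keeps the metric anchored to
#' the PSF structure. `sharpness_max_pixel` is the maximum pixel value,
#' reproducing the focus-frame rule.
#'
#' @param frame Image matrix.
#' @return Scalar sharpness score.
#' @export
sharpness_gradient <- function(frame) {
  sm <- box_blur3(frame)
  sum(diff(sm)^2) + sum(t(diff(t(sm)))^2)
}

## 3 x 3 box blur with edge replication.
box_blur3 <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- img[c(1, 1:nr, nr), c(1, 1:nc, nc)]
  out <- matrix(0, nr, nc)
  for (di in 0:2) for (dj in 0:2)
    out <- out + pad[di + 1:nr, dj + 1:nc]
  out / 9
}

#' @rdname sharpness_gradient
#' @export
sharpness_max_pixel <- function(frame) max(frame)

#' Absolute Z = 0 frame of the reference bead
#'
#' Selects the frame maximising an image-sharpness metric; that frame
#' becomes Z = 0 for the whole field. The per-frame scores are smoothed
#' with a short moving average before the maximum is taken, so that
#' shot-noise spikes in a single frame cannot displace the focal plane for
#' the entire field of view. Ties are broken by the lowest index (logged).
#'
#' @param reference A `bead_roi`.
#' @param sharpness Metric function of a frame matrix; default
#'   [sharpness_gradient()].
#' @param smooth_frames Width of the moving average applied to the score
#'   profile (odd; 1 disables smoothing).
#' @return 1-based frame index of Z = 0.
#' @export
set_absolute_z <- function(reference, sharpness = sharpness_gradient,
                           smooth_frames = 5) {
  frames <- stack_frames(reference)
  scores <- vapply(frames, sharpness, numeric(1))
  if (smooth_frames > 1 && length(scores) >= smooth_frames) {
    half <- smooth_frames %/% 2
    padded <- c(rep(scores[1], half), scores,
                rep(scores[length(scores)], half))  # replicate-pad ends
    sm <- stats::filter(padded, rep(1 / smooth_frames, smooth_frames),
                        sides = 2)
    scores <- as.numeric(sm[(half + 1):(half + length(scores))])
  }
  hits <- which(scores == max(scores))
  if (length(hits) > 1)
    smlmz_log("sharpness tie between frames %s; taking the lowest",
              paste(hits, collapse = ", "))
  hits[1]
}

#' Align per-bead axial offsets against a reference bead
#'
#' The reference defaults to the bead closest to the FOV centre. For every
#' other bead the integer frame shift minimising the mean squared difference
#' of (max-normalised) pixel intensities over the overlapping frames is
#' found by exhaustive search over `+/- window` frames; the bead's relative
#' offset is `deltaZ = shift * z_step_nm`. The reference's Z = 0 frame is
#' set by [set_absolute_z()] and every bead's per-frame `z_rel` follows from
#' its frame index, the stage step and its deltaZ.
#'
#' @param beads List of `bead_roi` (QC-kept), equal stack depths.
#' @param z_step_nm Stage step (nm).
#' @param reference Optional `bead_roi` or index into `beads`; by default
#'   the brightest (highest-SNR) bead within the central quarter of the
#'   FOV is used, falling back to the bead nearest the centre when none
#'   lies that close. A bright reference keeps both the shift search and
#'   the absolute-focus assignment well above the noise floor.
#' @param window Maximum absolute frame shift searched.
#' @param min_overlap Minimum overlapping frames required for a candidate
#'   shift; the default (half the stack depth, at least 10) keeps the mean
#'   squared difference well-averaged and suppresses spurious minima at
#'   extreme shifts. Beads with no admissible shift are rejected (logged).
#' @param sharpness Sharpness metric passed to [set_absolute_z()].
#' @param z0 Absolute-focus rule: `"consensus"` (default) takes the median
#'   over beads of each bead's own smoothed sharpness peak mapped back to
#'   reference coordinates, which averages out single-bead noise;
#'   `"reference"` uses the reference bead's sharpness peak alone.
#' @return List with `beads` (aligned, `z_rel` and `delta_z_nm` filled),
#'   `rejected`, `reference_index` and `z0_frame`.
#' @export
align_z_offsets <- function(beads, z_step_nm, reference = NULL, window = 100,
                            min_overlap = NULL,
                            sharpness = sharpness_gradient,
                            z0 = c("consensus", "reference")) {
  z0 <- match.arg(z0)
  if (length(beads) < 1) stop("need at least one bead", call. = FALSE)
  depths <- vapply(beads, function(b) dim(b$pixels)[3], integer(1))
  if (length(unique(depths)) != 1)
    stop("all bead stacks must have equal depth", call. = FALSE)
  n_z <- depths[1]
  min_overlap <- min_overlap %||% max(10L, n_z %/% 2L)
  ref_idx <- if (is.null(reference)) {
    fov_px <- beads[[1]]$fov_px
    ctr <- fov_px / 2
    d2 <- vapply(beads, function(b) sum((b$fov_xy_px - ctr)^2), numeric(1))
    central <- which(sqrt(d2) <= 0.25 * sqrt(sum(ctr^2)))
    if (length(central)) {
      snrs <- vapply(beads[central], compute_snr, numeric(1))
      central[which.max(snrs)]
    } else which.min(d2)
  } else if (is.numeric(reference)) as.integer(reference)
  else which(vapply(beads, function(b) identical(b, reference), logical(1)))[1]
  ref <- beads[[ref_idx]]
  ## denoise before comparing: the mean squared difference between two
  ## max-normalised raw stacks is shot-noise dominated for dim beads
  blur_norm <- function(px) {
    out <- px
    for (k in seq_len(dim(px)[3])) out[, , k] <- box_blur3(px[, , k])
    out / max(out)
  }
  ref_norm <- blur_norm(ref$pixels)
  ## smoothed sharpness profile, range-normalised; the pixel-wise MSE alone
  ## is biased when the compared beads have different field aberrations, and
  ## the profile term anchors the shift to the axial intensity structure
  sharp_prof <- function(b) {
    v <- vapply(seq_len(n_z), function(k) sharpness(b$pixels[, , k]),
                numeric(1))
    half <- 2L
    p <- c(rep(v[1], half), v, rep(v[n_z], half))
    v <- as.numeric(stats::filter(p, rep(1 / 5, 5),
                                  sides = 2))[(half + 1):(half + n_z)]
    (v - min(v)) / max(diff(range(v)), 1e-12)
  }
  ref_prof <- sharp_prof(ref)
  window <- min(window, n_z - min_overlap)
  shifts <- -window:window
  norm01 <- function(v) (v - min(v, na.rm = TRUE)) /
    max(diff(range(v, na.rm = TRUE)), 1e-12)
  aligned_idx <- integer(0); aligned_shift <- integer(0)
  rejected <- list()
  for (i in seq_along(beads)) {
    b <- beads[[i]]
    if (i == ref_idx) {
      best_shift <- 0L
    } else {
      bn <- blur_norm(b$pixels)
      bp <- sharp_prof(b)
      m3 <- rep(NA_real_, length(shifts))
      m1 <- rep(NA_real_, length(shifts))
      for (j in seq_along(shifts)) {
        s <- shifts[j]
        ## bead frame k aligns with reference frame k - s
        kb <- max(1L, 1L + s):min(n_z, n_z + s)
        kr <- kb - s
        if (length(kb) < min_overlap) next
        m3[j] <- mean((bn[, , kb] - ref_norm[, , kr])^2)
        m1[j] <- mean((bp[kb] - ref_prof[kr])^2)
      }
      best_shift <- if (all(is.na(m3))) NA_integer_
                    else shifts[which.min(norm01(m3) + norm01(m1))]
      if (is.na(best_shift)) {
        smlmz_log("bead %s: no admissible shift with overlap >= %d; rejected",
                  b$id, min_overlap)
        b$qc <- "rejected:noisy_z"
        rejected[[length(rejected) + 1L]] <- b
        next
      }
    }
    aligned_idx <- c(aligned_idx, i)
    aligned_shift <- c(aligned_shift, as.integer(best_shift))
  }
  ## absolute focus: under "consensus", every bead's own sharpness peak
  ## (parabolically interpolated to sub-frame precision) is mapped back to
  ## the reference frame axis and the median taken, which averages
  ## single-bead noise and frame quantisation out of the Z = 0 assignment
  z0_frame <- if (z0 == "consensus" && length(aligned_idx) > 1) {
    own <- vapply(aligned_idx, function(i) {
      prof <- sharp_prof(beads[[i]])
      k <- which.max(prof)
      if (k > 1 && k < n_z) {
        denom <- prof[k - 1] - 2 * prof[k] + prof[k + 1]
        if (denom < 0) k + 0.5 * (prof[k - 1] - prof[k + 1]) / denom
        else as.numeric(k)
      } else as.numeric(k)
    }, numeric(1))
    median(own - aligned_shift)
  } else {
    set_absolute_z(ref, sharpness = sharpness)
  }
  kept <- vector("list", length(aligned_idx))
  for (j in seq_along(aligned_idx)) {
    b <- beads[[aligned_idx[j]]]
    b$delta_z_nm <- aligned_shift[j] * z_step_nm
    b$z_rel <- (seq_len(n_z) - z0_frame) * z_step_nm - b$delta_z_nm
    kept[[j]] <- b
  }
  list(beads = kept, rejected = rejected,
       reference_index = ref_idx, z0_frame = z0_frame)
}
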