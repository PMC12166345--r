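## Calibration dataset assembly: one datapoint per (bead, frame) within the
## working Z range, per-bead train/val/test splitting (never per frame, so no
## bead leaks across splits), image resize to 64 x 64 and [0, 1] intensity
## rescale by the 16-bit maximum, field coordinates mapped to [-1, 1], and
## train-only augmentation to exactly triple the training count.

#' Augmentation parameters
#'
#' Each augmented copy of a training image receives additive Gaussian noise,
#' a random multiplicative brightness factor drawn uniformly from
#' `[1 - f, 1 + f]`, and Poisson resampling. The Poisson step is applied as
#' `pixel <- rpois(lambda * pixel) / lambda`, which preserves the [0, 1]
#' intensity scale and the pixel mean while injecting shot-noise-like
#' fluctuations of relative size `1/sqrt(lambda * pixel)`.
#'
#' @param gauss_mu,gauss_sigma Gaussian noise mean and SD (intensity units).
#' @param brightness_factor Half-width `f` of the brightness factor range.
#' @param poisson_lambda Poisson scale (counts at intensity 1).
#' @return List of class `augment_params`.
#' @export
augment_params <- function(gauss_mu = 0, gauss_sigma = 0.005,
                           brightness_factor = 0.075, poisson_lambda = 226) {
  stopifnot(gauss_sigma >= 0, poisson_lambda > 0)
  structure(list(gauss_mu = gauss_mu, gauss_sigma = gauss_sigma,
                 brightness_factor = brightness_factor,
                 poisson_lambda = poisson_lambda),
            class = "augment_params")
}

## Apply the augmentation chain to a [0,1] image matrix.
augment_image <- function(img, aug) {
  img <- img + rnorm(length(img), aug$gauss_mu, aug$gauss_sigma)
  img <- img * runif(1, 1 - aug$brightness_factor, 1 + aug$brightness_factor)
  img <- pmin(pmax(img, 0), 1)
  img <- matrix(rpois(length(img), aug$poisson_lambda * img) /
                  aug$poisson_lambda, nrow = nrow(img))
  pmin(pmax(img, 0), 1)
}

## Bilinear resize of a [h, w, n] array of frames to size x size.
resize_stack <- function(px, size) {
  out <- EBImage::resize(EBImage::Image(px), w = size, h = size)
  arr <- EBImage::imageData(out)
  if (length(dim(arr)) == 2) dim(arr) <- c(size, size, 1)
  arr
}

#' Build a calibration dataset from QC-kept, aligned beads
#'
#' @param beads List of `bead_roi` with `z_rel` populated (see
#'   [align_z_offsets()]); all must be QC-kept.
#' @param z_range_nm Working half-range (nm); frames with `|z_rel|` beyond
#'   it are removed (default 1000, i.e. +/- 1 um).
#' @param aug An [augment_params()].
#' @param split_fractions Named fractions for `train`/`val`/`test`,
#'   assigned per bead.
#' @param seed Integer seed for the split and the augmentation draws.
#' @param augment If `TRUE` (default), training images are augmented to
#'   exactly three times the original training count; augmented copies keep
#'   the source record's z label and field coordinates.
#' @param image_size Output image side (pixels).
#' @return Object of class `calibration_dataset` with `images`
#'   (`[image_size, image_size, N]` array in [0, 1]), `coords` (`[N, 2]` in
#'   [-1, 1]), `z` (nm), `split` (factor), `augmented` (logical),
#'   `bead_id`, `bead_key` and provenance metadata in `meta`.
#' @export
build_dataset <- function(beads, z_range_nm = 1000, aug = augment_params(),
                          split_fractions = c(train = 0.7, val = 0.15,
                                              test = 0.15),
                          seed = NULL, augment = TRUE, image_size = 64) {
  if (length(beads) == 0) stop("no beads to build a dataset from", call. = FALSE)
  if (!all(vapply(beads, function(b) identical(b$qc, "kept"), logical(1))))
    stop("all beads must be QC-kept", call. = FALSE)
  if (any(vapply(beads, function(b) is.null(b$z_rel), logical(1))))
    stop("beads must be Z-aligned first (z_rel missing)", call. = FALSE)
  stopifnot(abs(sum(split_fractions) - 1) < 1e-8)
  with_seed(seed, {
    n_beads <- length(beads)
    ## unique key per bead across FOVs
    keys <- vapply(beads, function(b) paste0(b$fov_id, ":", b$id), character(1))
    splits <- sample(rep(names(split_fractions),
                         times = diff(round(cumsum(c(0, split_fractions)) * n_beads))))
    ## rounding can drop/add one; fix length deterministically
    if (length(splits) < n_beads)
      splits <- c(splits, rep("train", n_beads - length(splits)))
    splits <- splits[seq_len(n_beads)]
    imgs <- list(); coords <- list(); zs <- list(); spl <- list()
    bid <- list(); bkey <- list(); augd <- list()
    for (i in seq_len(n_beads)) {
      b <- beads[[i]]
      keep <- which(abs(b$z_rel) <= z_range_nm)
      if (length(keep) == 0) next
      fov_nm <- b$fov_px * b$pixel_size
      u <- 2 * b$x_nm / fov_nm[1] - 1
      v <- 2 * b$y_nm / fov_nm[2] - 1
      small <- b$pixels[, , keep, drop = FALSE] / INT16_MAX
      big <- resize_stack(small, image_size)
      big <- pmin(pmax(big, 0), 1)
      n_k <- length(keep)
      imgs[[length(imgs) + 1L]] <- big
      coords[[length(coords) + 1L]] <- matrix(c(u, v), n_k, 2, byrow = TRUE)
      zs[[length(zs) + 1L]] <- b$z_rel[keep]
      spl[[length(spl) + 1L]] <- rep(splits[i], n_k)
      bid[[length(bid) + 1L]] <- rep(b$id, n_k)
      bkey[[length(bkey) + 1L]] <- rep(keys[i], n_k)
      augd[[length(augd) + 1L]] <- rep(FALSE, n_k)
    }
    if (length(imgs) == 0)
      stop("no frames within the working Z range", call. = FALSE)
    images <- array(unlist(imgs), dim = c(image_size, image_size,
                                          sum(vapply(zs, length, integer(1)))))
    coords <- do.call(rbind, coords)
    z <- unlist(zs); split <- unlist(spl); bead_id <- unlist(bid)
    bead_key <- unlist(bkey); augmented <- unlist(augd)
    if (augment) {
      tr <- which(split == "train")
      if (length(tr)) {
        n_new <- 2L * length(tr)
        aug_imgs <- array(0, dim = c(image_size, image_size, n_new))
        src <- rep(tr, each = 2L)
        for (j in seq_along(src))
          aug_imgs[, , j] <- augment_image(images[, , src[j]], aug)
        images <- array(c(images, aug_imgs),
                        dim = c(image_size, image_size,
                                dim(images)[3] + n_new))
        coords <- rbind(coords, coords[src, , drop = FALSE])
        z <- c(z, z[src])
        split <- c(split, rep("train", n_new))
        bead_id <- c(bead_id, bead_id[src])
        bead_key <- c(bead_key, bead_key[src])
        augmented <- c(augmented, rep(TRUE, n_new))
      }
    }
    structure(list(images = images, coords = coords, z = z,
                   split = factor(split, levels = c("train", "val", "test")),
                   augmented = augmented, bead_id = bead_id,
                   bead_key = bead_key,
                   meta = list(z_range_nm = z_range_nm, seed = seed,
                               image_size = image_size, aug = aug,
                               fov_px = beads[[1]]$fov_px,
                               pixel_size = beads[[1]]$pixel_size)),
              class = "calibration_dataset")
  })
}

#' @export
print.calibration_dataset <- function(x, ...) {
  cat(sprintf("Calibration dataset: %d datapoints (%d beads), %d x %d images\n",
              length(x$z), length(unique(x$bead_key)),
              x$meta$image_size, x$meta$image_size))
  print(table(split = x$split, augmented = x$augmented))
  invisible(x)
}

#' Persist / restore a calibration dataset
#'
#' The dataset arrays are stored as an RDS file with a YAML sidecar carrying
#' the provenance (seed, z range, image size, augmentation parameters).
#'
#' @param dataset A `calibration_dataset`.
#' @param path Output `.rds` path; the sidecar is `paste0(path, ".yaml")`.
#' @export
save_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "calibration_dataset"))
  saveRDS(dataset, path)
  meta <- dataset$meta
  meta$aug <- unclass(meta$aug)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname save_dataset
#' @param path Path previously passed to [save_dataset()].
#' @export
load_dataset <- function(path) {
  ds <- readRDS(path)
  if (!inherits(ds, "calibration_dataset"))
    stop("file does not contain a calibration_dataset", call. = FALSE)
  ds
}

## Subset helper used by training/evaluation.
dataset_subset <- function(dataset, which_split) {
  idx <- which(dataset$split == which_split)
  list(images = dataset$images[, , idx, drop = FALSE],
       coords = dataset$coords[idx, , drop = FALSE],
       z = dataset$z[idx], bead_key = dataset$bead_key[idx], index = idx)
}
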