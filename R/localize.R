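## Applying a trained regressor to 2D-localised SMLM data: dialect-aware
## localisation-table I/O, per-localisation ROI extraction, axial (Z)
## prediction, and axial drift correction by windowed means + smoothed
## cubic spline.

#' Construct a localisation table
#'
#' A localisation table is a data frame with one row per emitter detection:
#' `frame` (0-based), `x_nm`, `y_nm` (pixel-centre convention: a
#' localisation at the centre of 0-based pixel `i` has coordinate
#' `(i + 0.5) * pixel_size`), optional `z_nm` and `photons`, plus
#' field-geometry metadata carried as attributes.
#'
#' @param df Data frame with at least `frame`, `x_nm`, `y_nm`.
#' @param pixel_size Pixel pitch (nm).
#' @param fov_px FOV extent `c(nx, ny)` in pixels.
#' @param dialect Source dialect string.
#' @return The data frame with class `localisation_table`.
#' @export
localisation_table <- function(df, pixel_size, fov_px,
                               dialect = "generic_csv") {
  need <- setdiff(c("frame", "x_nm", "y_nm"), names(df))
  if (length(need))
    stop("missing mandatory columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(df$frame < 0)) stop("frame indices must be >= 0", call. = FALSE)
  fov_nm <- fov_px * pixel_size
  if (nrow(df) && (any(df$x_nm < 0 | df$x_nm > fov_nm[1]) ||
                   any(df$y_nm < 0 | df$y_nm > fov_nm[2])))
    stop("localisations outside the FOV extent", call. = FALSE)
  attr(df, "pixel_size") <- pixel_size
  attr(df, "fov_px") <- as.integer(fov_px)
  attr(df, "dialect") <- dialect
  class(df) <- c("localisation_table", "data.frame")
  df
}

## Column maps per dialect: external name -> internal name, plus units.
dialect_spec <- function(dialect) {
  switch(dialect,
    generic_csv = list(cols = c(frame = "frame", x_nm = "x_nm", y_nm = "y_nm"),
                       opt = c(z_nm = "z_nm", photons = "photons"),
                       xy_unit = "nm", frame_base = 0L),
    thunderstorm_csv = list(cols = c(frame = "frame", x_nm = "x [nm]",
                                     y_nm = "y [nm]"),
                            opt = c(z_nm = "z [nm]",
                                    photons = "intensity [photon]"),
                            xy_unit = "nm", frame_base = 1L),
    picasso_csv = list(cols = c(frame = "frame", x_nm = "x", y_nm = "y"),
                       opt = c(z_nm = "z", photons = "photons"),
                       xy_unit = "px", frame_base = 0L),
    stop("unknown dialect '", dialect,
         "'; available: generic_csv, thunderstorm_csv, picasso_csv",
         call. = FALSE))
}

#' Read a localisation table
#'
#' Supported dialects: `generic_csv` (columns `frame`, `x_nm`, `y_nm`, all
#' nm, 0-based frames), `thunderstorm_csv` (`frame`, `x [nm]`, `y [nm]`,
#' `intensity [photon]`; 1-based frames, nm units) and `picasso_csv`
#' (`frame`, `x`, `y` in pixels, 0-based frames; converted to nm via
#' `pixel_size`). Unit and frame-base conversions are logged.
#'
#' @param path CSV file.
#' @param dialect One of the dialect names above.
#' @param pixel_size Pixel pitch (nm), required for pixel-unit dialects and
#'   for ROI extraction downstream.
#' @param fov_px FOV extent in pixels.
#' @return A [localisation_table()].
#' @export
read_table <- function(path, dialect = "generic_csv", pixel_size = 110,
                       fov_px = c(256, 256)) {
  spec <- dialect_spec(dialect)
  raw <- utils::read.csv(path, check.names = FALSE)
  need <- setdiff(unname(spec$cols), names(raw))
  if (length(need))
    stop("missing mandatory columns for dialect '", dialect, "': ",
         paste(need, collapse = ", "), call. = FALSE)
  df <- data.frame(frame = raw[[spec$cols[["frame"]]]] - spec$frame_base)
  scale <- if (spec$xy_unit == "px") pixel_size else 1
  if (spec$xy_unit == "px")
    smlmz_log("converting x/y from px to nm (pixel_size %g nm)", pixel_size)
  if (spec$frame_base != 0L)
    smlmz_log("converting frames from %d-based to 0-based", spec$frame_base)
  df$x_nm <- raw[[spec$cols[["x_nm"]]]] * scale
  df$y_nm <- raw[[spec$cols[["y_nm"]]]] * scale
  for (int_name in names(spec$opt)) {
    ext <- spec$opt[[int_name]]
    if (ext %in% names(raw))
      df[[int_name]] <- raw[[ext]] * if (int_name == "z_nm" &&
                                         spec$xy_unit == "px") pixel_size else 1
  }
  extra <- c("z_correction_nm", "skip_reason", "pore", "ring", "id")
  for (e in intersect(extra, names(raw))) df[[e]] <- raw[[e]]
  localisation_table(df, pixel_size, fov_px, dialect)
}

#' Write a localisation table in its (or another) dialect
#'
#' @param table A [localisation_table()].
#' @param path Output CSV.
#' @param dialect Output dialect; defaults to the table's source dialect.
#' @export
write_table <- function(table, path, dialect = NULL) {
  dialect <- dialect %||% attr(table, "dialect") %||% "generic_csv"
  spec <- dialect_spec(dialect)
  scale <- if (spec$xy_unit == "px") attr(table, "pixel_size") else 1
  out <- data.frame(check.names = FALSE,
                    setNames(list(table$frame + spec$frame_base),
                             spec$cols[["frame"]]))
  out[[spec$cols[["x_nm"]]]] <- table$x_nm / scale
  out[[spec$cols[["y_nm"]]]] <- table$y_nm / scale
  for (int_name in names(spec$opt)) {
    if (int_name %in% names(table))
      out[[spec$opt[[int_name]]]] <- table[[int_name]] /
        if (int_name == "z_nm" && spec$xy_unit == "px")
          attr(table, "pixel_size") else 1
  }
  for (e in intersect(c("z_correction_nm", "skip_reason", "pore", "ring", "id"),
                      names(table)))
    out[[e]] <- table[[e]]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Extract per-localisation ROIs from a frame stack
#'
#' Crops a `roi` x `roi` window from each localisation's frame, centred on
#' the pixel containing the localisation. Localisations within `roi %/% 2`
#' pixels of the border are skipped (and counted in the log); coordinates
#' are returned normalised to [-1, 1] over the FOV.
#'
#' @param frames List of frame matrices (the raw SMLM movie).
#' @param table A [localisation_table()].
#' @param roi Odd crop width (pixels).
#' @return List with `images` (`[roi, roi, n_kept]`), `coords`
#'   (`n_kept x 2`), `kept` (row indices into `table`), and `skipped`
#'   (data.frame of row index + reason).
#' @export
extract_rois <- function(frames, table, roi = 15) {
  if (roi %% 2 == 0) stop("`roi` must be odd", call. = FALSE)
  px <- attr(table, "pixel_size"); fov_px <- attr(table, "fov_px")
  if (nrow(table) && max(table$frame) > length(frames) - 1)
    stop("table refers to frame ", max(table$frame),
         " but the stack has only ", length(frames), " frames",
         call. = FALSE)
  half <- roi %/% 2
  n <- nrow(table)
  cx <- floor(table$x_nm / px); cy <- floor(table$y_nm / px)
  ok <- cx >= half & cy >= half & cx < fov_px[1] - half & cy < fov_px[2] - half
  kept <- which(ok)
  if (any(!ok))
    smlmz_log("%d of %d localisations within %d px of the border; skipped",
              sum(!ok), n, half)
  images <- array(0, dim = c(roi, roi, length(kept)))
  for (j in seq_along(kept)) {
    i <- kept[j]
    fr <- frames[[table$frame[i] + 1L]]
    images[, , j] <- fr[(cy[i] - half):(cy[i] + half) + 1L,
                        (cx[i] - half):(cx[i] + half) + 1L]
  }
  fov_nm <- fov_px * px
  coords <- cbind(2 * table$x_nm[kept] / fov_nm[1] - 1,
                  2 * table$y_nm[kept] / fov_nm[2] - 1)
  skipped <- data.frame(index = which(!ok),
                        reason = rep("border", sum(!ok)))
  list(images = images, coords = coords, kept = kept, skipped = skipped)
}

#' Assign axial positions to a 2D localisation table
#'
#' Extracts each localisation's ROI, applies the calibration preprocessing
#' (resize to the model's input size, rescale by the 16-bit maximum) and
#' predicts Z with the trained regressor. Records whose ROI cannot be
#' extracted keep an `NA` z and carry a `skip_reason`; no record is dropped.
#'
#' @param frames List of frame matrices.
#' @param table A [localisation_table()].
#' @param model A trained `z_regressor`.
#' @param roi Crop width used at calibration time (pixels).
#' @return The table with `z_nm` (and `skip_reason`) columns filled.
#' @export
localise_3d <- function(frames, table, model, roi = 15) {
  stopifnot(inherits(model, "z_regressor"))
  fov_px <- attr(table, "fov_px")
  if (!identical(as.integer(fov_px), as.integer(model$norm$fov_px)) ||
      !isTRUE(all.equal(attr(table, "pixel_size"), model$norm$pixel_size)))
    stop("model was calibrated for FOV ",
         paste(model$norm$fov_px, collapse = "x"), " px @ ",
         model$norm$pixel_size, " nm but the table reports ",
         paste(fov_px, collapse = "x"), " px @ ",
         attr(table, "pixel_size"), " nm", call. = FALSE)
  table$z_nm <- NA_real_
  table$skip_reason <- NA_character_
  if (nrow(table) == 0) return(table)
  ex <- extract_rois(frames, table, roi = roi)
  if (length(ex$kept)) {
    imgs <- resize_stack(ex$images / INT16_MAX, model$norm$image_size)
    imgs <- pmin(pmax(imgs, 0), 1)
    table$z_nm[ex$kept] <- predict_z(model, imgs, ex$coords)
  }
  if (nrow(ex$skipped)) table$skip_reason[ex$skipped$index] <- ex$skipped$reason
  table
}

#' Correct axial drift with windowed means and a smoothed spline
#'
#' The mean Z is computed over blocks of `window` sequential frames (the
#' last partial block keeps its own mean), a smoothed cubic spline is
#' fitted to the block means against the block-centre frames, and each
#' localisation's Z is corrected by the spline offset relative to the
#' global mean Z, so the global mean is preserved. With fewer than four
#' blocks a linear fit replaces the spline.
#'
#' @param table A [localisation_table()] with `z_nm` present.
#' @param window Frames per block (default 500).
#' @param df Effective degrees of freedom of the smoothing spline; default
#'   `max(2, n_blocks / 3)`.
#' @return List with `table` (corrected `z_nm` plus `z_correction_nm`) and
#'   `trace` (a `drift_trace`: block centres/means and per-frame offsets).
#' @export
correct_z_drift <- function(table, window = 500, df = NULL) {
  ok <- !is.na(table$z_nm)
  if (!any(ok)) stop("no z values to drift-correct", call. = FALSE)
  frames <- table$frame[ok]; z <- table$z_nm[ok]
  f0 <- min(frames)
  block <- (frames - f0) %/% window
  n_blocks <- length(unique(block))
  if (n_blocks < 2)
    stop("need at least two ", window, "-frame windows of data",
         call. = FALSE)
  centres <- tapply(frames, block, median)
  means <- tapply(z, block, mean)
  global_mean <- mean(z)
  all_frames <- seq(f0, max(frames))
  if (n_blocks >= 4) {
    df <- df %||% max(2, n_blocks / 3)
    sfit <- smooth.spline(as.numeric(centres), as.numeric(means), df = df)
    fitted_at <- predict(sfit, all_frames)$y
  } else {
    lfit <- lm(m ~ f, data = data.frame(f = as.numeric(centres),
                                        m = as.numeric(means)))
    fitted_at <- predict(lfit, data.frame(f = all_frames))
  }
  offset <- fitted_at - global_mean
  corr <- offset[match(table$frame, all_frames)]
  corr[is.na(corr)] <- 0
  table$z_correction_nm <- ifelse(is.na(table$z_nm), NA_real_, -corr)
  table$z_nm <- table$z_nm - ifelse(is.na(table$z_nm), 0, corr)
  trace <- structure(list(window = window,
                          block_centres = as.numeric(centres),
                          block_means = as.numeric(means),
                          frame = all_frames, offset = offset,
                          global_mean = global_mean,
                          df = if (n_blocks >= 4) df else NA_real_),
                     class = "drift_trace")
  list(table = table, trace = trace)
}

#' @export
print.drift_trace <- function(x, ...) {
  cat(sprintf("Axial drift trace: %d blocks of %d frames, offset range [%.1f, %.1f] nm\n",
              length(x$block_centres), x$window, min(x$offset), max(x$offset)))
  invisible(x)
}

#' @export
plot.drift_trace <- function(x, ...) {
  plot(x$frame, x$offset, type = "l", xlab = "frame",
       ylab = "axial drift offset (nm)", main = "Axial drift", ...)
  points(x$block_centres, x$block_means - x$global_mean, pch = 16)
  invisible(x)
}

#' Write a drift trace as CSV
#'
#' @param trace A `drift_trace`.
#' @param path Output CSV.
#' @export
write_drift_csv <- function(trace, path) {
  utils::write.csv(data.frame(frame = trace$frame, offset_nm = trace$offset),
                   path, row.names = FALSE)
  invisible(path)
}
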