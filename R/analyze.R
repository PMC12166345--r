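## Per-structure axial analysis: kernel density estimation of the Z profile,
## topographic-prominence peak detection, double-ring success classification
## and the render-threshold rule used to contrast X/Z reconstructions.

#' Success criteria for double-ring structures
#'
#' @param bandwidth Gaussian KDE bandwidth (nm), default 15.
#' @param min_prominence Minimum topographic peak prominence (density
#'   units), default 0.0001.
#' @param separation_window Inclusive axial separation window (nm) for a
#'   "successful" double ring, default `c(40, 60)`.
#' @param normalise If `TRUE`, the KDE is divided by the localisation count
#'   (the prominence threshold then applies to the per-localisation
#'   density); default `FALSE`, i.e. density in localisations/nm.
#' @return List of class `success_criteria`.
#' @export
success_criteria <- function(bandwidth = 15, min_prominence = 0.0001,
                             separation_window = c(40, 60),
                             normalise = FALSE) {
  stopifnot(bandwidth > 0, length(separation_window) == 2,
            separation_window[1] > 0,
            separation_window[1] < separation_window[2])
  structure(list(bandwidth = bandwidth, min_prominence = min_prominence,
                 separation_window = separation_window,
                 normalise = normalise),
            class = "success_criteria")
}

#' Gaussian KDE of an axial profile
#'
#' Evaluates \eqn{d(g) = \sum_i \phi((g - z_i)/h)/h} on a regular grid
#' spanning the data range plus three bandwidths; with the default
#' (unnormalised) convention the density integrates to the localisation
#' count and has units localisations/nm.
#'
#' @param z_values Axial positions (nm), at least one.
#' @param bandwidth Kernel SD `h` (nm), > 0.
#' @param grid_step Grid spacing (nm).
#' @param normalise Divide by the number of values.
#' @return List with `grid` and `density`.
#' @export
kde_profile <- function(z_values, bandwidth = 15, grid_step = 1,
                        normalise = FALSE) {
  if (length(z_values) < 1) stop("need at least one z value", call. = FALSE)
  if (bandwidth <= 0) stop("bandwidth must be > 0", call. = FALSE)
  lo <- min(z_values) - 3 * bandwidth
  hi <- max(z_values) + 3 * bandwidth
  grid <- seq(lo, hi, by = grid_step)
  ## vectorised kernel sum over an [n_grid, n_z] difference matrix
  density <- rowSums(dnorm(outer(grid, z_values, "-") / bandwidth)) / bandwidth
  if (normalise) density <- density / length(z_values)
  list(grid = grid, density = density)
}

#' Detect peaks by topographic prominence
#'
#' Local maxima of the density are ranked by topographic prominence: the
#' height of a peak above the higher of the two minima separating it from
#' the nearest higher ground on each side (or the signal edge). Peaks with
#' prominence below `min_prominence` are discarded.
#'
#' @param grid Strictly increasing grid.
#' @param density Density values on `grid`.
#' @param min_prominence Prominence threshold (same units as `density`).
#' @return Data frame (`position`, `height`, `prominence`) sorted by
#'   decreasing prominence (ties broken by height, then lower position).
#' @export
detect_peaks <- function(grid, density, min_prominence = 0.0001) {
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing",
                                 call. = FALSE)
  n <- length(density)
  empty <- data.frame(position = numeric(0), height = numeric(0),
                      prominence = numeric(0))
  if (n < 3) return(empty)
  ## local maxima (plateau-left convention: first index of a plateau top)
  is_peak <- which(vapply(2:(n - 1), function(i) {
    density[i] > density[i - 1] && density[i] >= density[i + 1] &&
      (density[i] > density[i + 1] ||
         any(density[(i + 1):n] < density[i]))  # plateau must eventually drop
  }, logical(1))) + 1L
  if (length(is_peak) == 0) return(empty)
  prom <- vapply(is_peak, function(i) {
    h <- density[i]
    ## walk left to the nearest strictly higher point, tracking the minimum
    lmin <- h; j <- i
    while (j > 1 && density[j - 1] <= h) {
      j <- j - 1; lmin <- min(lmin, density[j])
    }
    rmin <- h; j <- i
    while (j < n && density[j + 1] <= h) {
      j <- j + 1; rmin <- min(rmin, density[j])
    }
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence
  pk <- data.frame(position = grid[is_peak][keep],
                   height = density[is_peak][keep],
                   prominence = prom[keep])
  if (nrow(pk) > 1 && anyDuplicated(signif(pk$prominence, 12)))
    smlmz_log("prominence tie among peaks; breaking by height then position")
  pk[order(-pk$prominence, -pk$height, pk$position), , drop = FALSE]
}

#' Classify a structure as a successfully resolved double ring
#'
#' Successful iff at least two peaks were detected and the two most
#' prominent are separated by an axial distance inside the (inclusive)
#' separation window.
#'
#' @param peaks Data frame from [detect_peaks()].
#' @param criteria A [success_criteria()].
#' @return `"successful"` or `"unsuccessful"`.
#' @export
classify_pore <- function(peaks, criteria = success_criteria()) {
  if (nrow(peaks) < 2) return("unsuccessful")
  sep <- abs(peaks$position[1] - peaks$position[2])
  w <- criteria$separation_window
  if (sep >= w[1] && sep <= w[2]) "successful" else "unsuccessful"
}

#' Render threshold for X/Z visual contrast
#'
#' The minimum-density threshold applied when rendering a structure: the
#' mean of (a) the mean peak height and (b) the density at the local
#' minimum between the two most prominent peaks. With fewer than two peaks
#' no thresholding is applied (threshold 0).
#'
#' @param grid,density KDE profile.
#' @param peaks Data frame from [detect_peaks()].
#' @return Scalar threshold (density units).
#' @export
render_threshold <- function(grid, density, peaks) {
  if (nrow(peaks) < 2) return(0)
  p <- sort(peaks$position[1:2])
  between <- grid >= p[1] & grid <= p[2]
  valley <- min(density[between])
  (mean(peaks$height) + valley) / 2
}

#' Analyse one picked structure
#'
#' Runs the full per-structure pipeline: KDE profile, peak detection,
#' success classification, separation of the two most prominent peaks and
#' render threshold.
#'
#' @param z_values Axial positions (nm) of the structure's localisations.
#' @param criteria A [success_criteria()].
#' @param grid_step KDE grid spacing (nm).
#' @return Object of class `pore_analysis`.
#' @export
pore_analysis <- function(z_values, criteria = success_criteria(),
                          grid_step = 1) {
  prof <- kde_profile(z_values, bandwidth = criteria$bandwidth,
                      grid_step = grid_step,
                      normalise = criteria$normalise)
  peaks <- detect_peaks(prof$grid, prof$density, criteria$min_prominence)
  cls <- classify_pore(peaks, criteria)
  sep <- if (nrow(peaks) >= 2) abs(peaks$position[1] - peaks$position[2])
         else NA_real_
  structure(list(z_values = z_values, grid = prof$grid,
                 density = prof$density, peaks = peaks,
                 classification = cls, separation_nm = sep,
                 threshold = render_threshold(prof$grid, prof$density, peaks),
                 criteria = criteria),
            class = "pore_analysis")
}

#' @export
print.pore_analysis <- function(x, ...) {
  cat(sprintf("Structure: %d localisations, %d peak(s)%s -> %s\n",
              length(x$z_values), nrow(x$peaks),
              if (!is.na(x$separation_nm))
                sprintf(", separation %.1f nm", x$separation_nm) else "",
              x$classification))
  invisible(x)
}

#' @export
plot.pore_analysis <- function(x, ...) {
  plot(x$grid, x$density, type = "l", xlab = "z (nm)",
       ylab = if (x$criteria$normalise) "density (1/nm)"
              else "density (localisations/nm)",
       main = sprintf("Axial profile (%s)", x$classification), ...)
  if (nrow(x$peaks))
    points(x$peaks$position, x$peaks$height, pch = 16)
  if (x$threshold > 0) abline(h = x$threshold, lty = 3)
  invisible(x)
}

## Split a localisation table (or data.frame) with a pore/group column into
## a named list of z-value vectors.
pore_groups <- function(table, group_col = "pore") {
  if (is.list(table) && !is.data.frame(table)) return(table)
  if (!group_col %in% names(table))
    stop("no '", group_col, "' column to group structures by", call. = FALSE)
  z <- table$z_nm %||% stop("table has no z_nm column")
  split(z[!is.na(z)], table[[group_col]][!is.na(z)])
}

#' Per-structure analysis report
#'
#' @param table Localisation table (or data frame) with `z_nm` and a group
#'   column, or a list of per-structure z vectors.
#' @param criteria A [success_criteria()].
#' @param group_col Grouping column name (default `"pore"`).
#' @return Data frame: group, n_locs, n_peaks, separation_nm,
#'   classification, threshold.
#' @export
analyse_pores <- function(table, criteria = success_criteria(),
                          group_col = "pore") {
  groups <- pore_groups(table, group_col)
  rows <- lapply(names(groups), function(g) {
    pa <- pore_analysis(groups[[g]], criteria)
    data.frame(group = g, n_locs = length(groups[[g]]),
               n_peaks = nrow(pa$peaks), separation_nm = pa$separation_nm,
               classification = pa$classification, threshold = pa$threshold)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Success counts as a function of KDE bandwidth
#'
#' Re-runs the full per-structure analysis (KDE, peak detection,
#' classification) at each bandwidth and counts successful structures.
#'
#' @param table As in [analyse_pores()].
#' @param bandwidths Vector of bandwidths (nm), all > 0.
#' @param criteria Base [success_criteria()] (its bandwidth is overridden).
#' @param group_col Grouping column name.
#' @return List with `curve` (data.frame bandwidth, n_successful) and
#'   `verdicts` (structures x bandwidths logical matrix).
#' @export
success_curve <- function(table, bandwidths = c(5, 10, 15, 20, 30, 45, 60),
                          criteria = success_criteria(),
                          group_col = "pore") {
  stopifnot(all(bandwidths > 0))
  groups <- pore_groups(table, group_col)
  verdicts <- matrix(FALSE, length(groups), length(bandwidths),
                     dimnames = list(names(groups), as.character(bandwidths)))
  for (j in seq_along(bandwidths)) {
    crit <- criteria
    crit$bandwidth <- bandwidths[j]
    for (i in seq_along(groups)) {
      pa <- pore_analysis(groups[[i]], crit)
      verdicts[i, j] <- identical(pa$classification, "successful")
    }
  }
  list(curve = data.frame(bandwidth = bandwidths,
                          n_successful = colSums(verdicts)),
       verdicts = verdicts)
}
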