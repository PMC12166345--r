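#' Field-dependent point-spread-function model
#'
#' Describes an elliptical-Gaussian PSF whose widths grow with defocus and
#' whose astigmatism varies smoothly across the field of view. The axial
#' widths are
#' \deqn{\sigma_x(z, u, v) = \sigma_0 + a_x(u, v)\, z + c\, z^2}
#' (and likewise for \eqn{\sigma_y}) with \eqn{z} in micrometres,
#' \eqn{\sigma_0} the in-focus width (nm), \eqn{a_x, a_y} the per-axis
#' astigmatism rates (nm/um) as functions of the normalised field position
#' \eqn{(u, v) \in [-1, 1]^2}, and \eqn{c} a symmetric defocus curvature
#' (nm/um^2). Opposite-signed \eqn{a_x} and \eqn{a_y} make the ellipse
#' orientation flip through focus, which is the signal that encodes the sign
#' of the defocus; their lateral variation emulates a standard (unmodified)
#' microscope whose weak intrinsic aberrations differ across the field.
#'
#' The default coefficients are weak (tens of nm/um, typical of an
#' unmodified high-NA objective) and satisfy
#' \eqn{4 c \sigma_0 > \max(a^2)} so both widths stay positive at every
#' defocus.
#'
#' @param base_width In-focus Gaussian sigma at the field centre (nm).
#' @param astig_x,astig_y Functions of `(u, v)` returning the astigmatism
#'   rate (nm/um) for the x and y axes.
#' @param defocus_curvature Symmetric quadratic blur growth (nm/um^2).
#' @param photon_budget Expected photons per emitter per frame.
#' @param background Background level (photons/pixel).
#' @param read_noise_sd Gaussian read noise (photons).
#' @param baseline Constant camera offset (counts).
#' @param pixel_size Pixel pitch (nm). A localisation at the centre of
#'   0-based pixel `i` has coordinate `(i + 0.5) * pixel_size` nm.
#' @param fov_px Field of view as `c(nx, ny)` pixels.
#' @return An object of class `field_psf_model`.
#' @export
field_psf_model <- function(base_width = 150,
                            astig_x = function(u, v) 70 + 40 * u - 25 * v,
                            astig_y = function(u, v) -70 - 35 * u + 30 * v,
                            defocus_curvature = 45,
                            photon_budget = 5000,
                            background = 20,
                            read_noise_sd = 2,
                            baseline = 100,
                            pixel_size = 110,
                            fov_px = c(256, 256)) {
  stopifnot_scalar(base_width, "base_width", positive = TRUE)
  stopifnot_scalar(photon_budget, "photon_budget", positive = TRUE)
  stopifnot_scalar(pixel_size, "pixel_size", positive = TRUE)
  stopifnot(is.function(astig_x), is.function(astig_y),
            length(fov_px) == 2L, all(fov_px >= 16))
  m <- list(base_width = base_width, astig_x = astig_x, astig_y = astig_y,
            defocus_curvature = defocus_curvature,
            photon_budget = photon_budget, background = background,
            read_noise_sd = read_noise_sd, baseline = baseline,
            pixel_size = pixel_size, fov_px = as.integer(fov_px))
  class(m) <- "field_psf_model"
  m
}

#' @export
print.field_psf_model <- function(x, ...) {
  cat("Field-dependent elliptical-Gaussian PSF model\n")
  cat(sprintf("  in-focus sigma : %g nm, defocus curvature %g nm/um^2\n",
              x$base_width, x$defocus_curvature))
  cat(sprintf("  photons %g, background %g ph/px, read noise %g, baseline %g\n",
              x$photon_budget, x$background, x$read_noise_sd, x$baseline))
  cat(sprintf("  pixel %g nm, FOV %d x %d px\n",
              x$pixel_size, x$fov_px[1], x$fov_px[2]))
  invisible(x)
}

## Normalised field position of a point (nm) within the model's FOV.
field_uv <- function(model, x_nm, y_nm) {
  w <- model$fov_px[1] * model$pixel_size
  h <- model$fov_px[2] * model$pixel_size
  cbind(u = 2 * x_nm / w - 1, v = 2 * y_nm / h - 1)
}

#' PSF widths at a given defocus and field position
#'
#' Closed-form \eqn{\sigma_x, \sigma_y} (nm) of the model; exposed so tests
#' and analyses can evaluate the simulated ground truth analytically.
#'
#' @param model A [field_psf_model()].
#' @param z_nm Defocus (nm); vectorised.
#' @param u,v Normalised field position in `[-1, 1]`.
#' @return A list with vectors `sx` and `sy` (nm).
#' @export
psf_sigma <- function(model, z_nm, u = 0, v = 0) {
  z_um <- z_nm / 1000
  sx <- model$base_width + model$astig_x(u, v) * z_um +
    model$defocus_curvature * z_um^2
  sy <- model$base_width + model$astig_y(u, v) * z_um +
    model$defocus_curvature * z_um^2
  if (any(sx <= 0) || any(sy <= 0))
    stop("PSF width non-positive at requested defocus; model coefficients ",
         "violate the positivity invariant", call. = FALSE)
  list(sx = sx, sy = sy)
}

## Expected photons per pixel for one emitter over a pixel grid.
## cols/rows are 0-based pixel indices; exact pixel-integrated Gaussian.
psf_expected_patch <- function(model, x_nm, y_nm, z_nm, photons, cols, rows) {
  uv <- field_uv(model, x_nm, y_nm)
  s <- psf_sigma(model, z_nm, uv[1, "u"], uv[1, "v"])
  px <- model$pixel_size
  fx <- pnorm((cols + 1) * px, mean = x_nm, sd = s$sx) -
    pnorm(cols * px, mean = x_nm, sd = s$sx)
  fy <- pnorm((rows + 1) * px, mean = y_nm, sd = s$sy) -
    pnorm(rows * px, mean = y_nm, sd = s$sy)
  photons * outer(fy, fx)  # [rows, cols] = [y, x]
}

#' Render a single-emitter ROI
#'
#' Renders the pixel-integrated elliptical-Gaussian image of one emitter at
#' defocus `z_nm`, centred on the pixel containing `(x_nm, y_nm)`. With
#' `seed = NULL` the noise-free expected photon image (signal + background)
#' is returned, so that `sum(image) - background * roi_px^2` equals the
#' photon budget up to Gaussian tail truncation. With a seed, Poisson shot
#' noise, Gaussian read noise and the camera baseline are applied and the
#' result is rounded and clipped to 16-bit counts.
#'
#' @param x_nm,y_nm Emitter position (nm), inside the model FOV.
#' @param z_nm Defocus (nm).
#' @param model A [field_psf_model()].
#' @param roi_px Odd ROI width in pixels.
#' @param seed Integer seed for the noisy render, or `NULL` for noise-free.
#' @param photons Photons emitted this frame; defaults to the model budget.
#' @return `roi_px` x `roi_px` matrix (rows = y, cols = x).
#' @export
render_psf <- function(x_nm, y_nm, z_nm, model, roi_px = 15, seed = NULL,
                       photons = model$photon_budget) {
  stopifnot(inherits(model, "field_psf_model"))
  if (roi_px %% 2 == 0) stop("`roi_px` must be odd", call. = FALSE)
  w <- model$fov_px[1] * model$pixel_size
  h <- model$fov_px[2] * model$pixel_size
  if (x_nm < 0 || x_nm > w)
    stop(sprintf("x position %.1f nm outside FOV [0, %.1f] nm", x_nm, w),
         call. = FALSE)
  if (y_nm < 0 || y_nm > h)
    stop(sprintf("y position %.1f nm outside FOV [0, %.1f] nm", y_nm, h),
         call. = FALSE)
  half <- roi_px %/% 2
  cx <- floor(x_nm / model$pixel_size)
  cy <- floor(y_nm / model$pixel_size)
  cols <- (cx - half):(cx + half)
  rows <- (cy - half):(cy + half)
  img <- psf_expected_patch(model, x_nm, y_nm, z_nm, photons, cols, rows) +
    model$background
  if (is.null(seed)) return(img)
  with_seed(seed, {
    n <- length(img)
    counts <- rpois(n, lambda = as.vector(img)) +
      rnorm(n, sd = model$read_noise_sd) + model$baseline
    matrix(pmin(pmax(round(counts), 0), INT16_MAX), nrow = roi_px)
  })
}
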