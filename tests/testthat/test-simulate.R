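# Synthetic PSF, bead-stack, movie and nuclear-pore generators.

test_that("noise-free PSF integrates to the photon budget and obeys the
           field model's closed-form widths", {
  m <- fix_model()
  ctr <- 64 * 110 + 55  # pixel centre near the field centre
  img <- render_psf(ctr, ctr, 0, m, roi_px = 25)
  got <- sum(img) - m$background * 25^2
  expect_lt(abs(got - m$photon_budget) / m$photon_budget, 0.01)

  # defocused and off-centre: still conserved within the wider ROI
  img2 <- render_psf(30 * 110 + 55, 90 * 110 + 55, 800, m, roi_px = 25)
  got2 <- sum(img2) - m$background * 25^2
  expect_lt(abs(got2 - m$photon_budget) / m$photon_budget, 0.01)
})

test_that("equal astigmatism coefficients give a transpose-symmetric
           in-focus image at the field centre", {
  m <- field_psf_model(astig_x = function(u, v) 50 + 0 * u,
                       astig_y = function(u, v) 50 + 0 * u,
                       fov_px = c(128, 128))
  ctr <- 64 * 110 + 55
  img <- render_psf(ctr, ctr, 0, m, roi_px = 15)
  expect_equal(img, t(img), tolerance = 1e-12)
  s <- psf_sigma(m, c(-700, 0, 700), 0.3, -0.4)
  expect_equal(s$sx, s$sy)
})

test_that("opposite defocus at a field corner flips the PSF aspect ratio", {
  m <- fix_model()
  s_plus <- psf_sigma(m, 500, 0.9, 0.9)
  s_minus <- psf_sigma(m, -500, 0.9, 0.9)
  r_plus <- s_plus$sx / s_plus$sy
  r_minus <- s_minus$sx / s_minus$sy
  expect_gt(abs(log(r_plus / r_minus)), 0.1)
  # the rendered images reflect it: x/y second moments swap order
  corner <- c(20 * 110 + 55, 108 * 110 + 55)
  moments <- function(z) {
    img <- render_psf(corner[1], corner[2], z, m, roi_px = 21)
    img <- img - m$background
    # column-major: row (y) fastest, column (x) slowest
    xs <- rep(1:21, each = 21); ys <- rep(1:21, 21)
    w <- pmax(as.vector(img), 0)
    mx <- sum(xs * w) / sum(w); my <- sum(ys * w) / sum(w)
    c(vx = sum((xs - mx)^2 * w) / sum(w),
      vy = sum((ys - my)^2 * w) / sum(w))
  }
  mp <- moments(500); mm <- moments(-500)
  expect_true((mp["vx"] - mp["vy"]) * (mm["vx"] - mm["vy"]) < 0)
})

test_that("render_psf validates its inputs", {
  m <- fix_model()
  expect_error(render_psf(-5, 100, 0, m), "outside FOV")
  expect_error(render_psf(100, 1e9, 0, m), "outside FOV")
  expect_error(render_psf(500, 500, 0, m, roi_px = 14), "odd")
})

test_that("bead stacks have the closed-form frame count", {
  m <- fix_model()
  expect_equal(length(fix_stack()$frames),
               round((1.1 - (-1.1)) * 1000 / 100) + 1)
  # the published acquisition geometry: -3 um..+3 um in 10 nm steps
  expect_equal(round((3 - (-3)) * 1000 / 10) + 1, 601)
  st0 <- generate_bead_stack(m, n_beads = 0, z_min_um = -0.1, z_max_um = 0.1,
                             z_step_nm = 50, seed = 1)
  expect_equal(length(st0$frames), 5)
  expect_equal(nrow(st0$truth), 0)
  expect_error(generate_bead_stack(m, 5, z_min_um = 1, z_max_um = -1,
                                   z_step_nm = 10), "exceed")
  expect_error(generate_bead_stack(m, 5, z_step_nm = 0), "z_step_nm")
})

test_that("generators are bit-reproducible under a fixed seed", {
  m <- fix_model()
  a <- generate_bead_stack(m, n_beads = 4, z_min_um = -0.2, z_max_um = 0.2,
                           z_step_nm = 100, seed = 99)
  b <- generate_bead_stack(m, n_beads = 4, z_min_um = -0.2, z_max_um = 0.2,
                           z_step_nm = 100, seed = 99)
  expect_identical(a$frames, b$frames)
  expect_identical(a$truth, b$truth)
  n1 <- generate_npc_localisations(5, seed = 3)
  n2 <- generate_npc_localisations(5, seed = 3)
  expect_identical(n1, n2)
})

test_that("PSFs at the same defocus differ across the field
           (the signal the regressor exploits)", {
  m <- fix_model()
  z <- 600
  img_a <- render_psf(30 * 110 + 55, 30 * 110 + 55, z, m, roi_px = 15)
  img_b <- render_psf(100 * 110 + 55, 100 * 110 + 55, z, m, roi_px = 15)
  noise_floor <- sqrt(m$background)  # shot-noise scale per pixel
  expect_gt(max(abs(img_a - img_b)), noise_floor)
})

test_that("SMLM movies draw Poisson-distributed activations with full
           ground-truth bookkeeping", {
  m <- fix_model()
  struct <- data.frame(x_nm = runif(20, 3000, 9000),
                       y_nm = runif(20, 3000, 9000),
                       z_nm = runif(20, -500, 500))
  mv <- generate_smlm_movie(struct, m, n_frames = 200,
                            mean_on_per_frame = 5, seed = 11)
  expect_equal(length(mv$frames), 200)
  n_rec <- nrow(mv$truth)
  expect_lt(abs(n_rec - 1000), 3 * sqrt(1000))
  expect_true(all(mv$truth$frame %in% 0:199))

  one <- generate_smlm_movie(struct[1, ], m, n_frames = 10,
                             mean_on_per_frame = 1, seed = 2,
                             blinking = "all_on")
  expect_equal(nrow(one$truth), 10)
  expect_equal(unique(one$truth$x_nm), struct$x_nm[1])
  expect_equal(unique(one$truth$z_nm), struct$z_nm[1])

  drift_fn <- function(frame) 0.5 * frame
  dr <- generate_smlm_movie(struct[1, ], m, n_frames = 10,
                            mean_on_per_frame = 1, seed = 2,
                            blinking = "all_on", z_drift_fn = drift_fn)
  expect_equal(dr$truth$z_nm, struct$z_nm[1] + 0.5 * (0:9))

  expect_error(generate_smlm_movie(struct[0, ], m, 10, 5, 1), "empty")
})

test_that("noiseless nuclear pores carry exactly two ring planes 46 nm
           apart with 16 cluster centres", {
  g <- npc_geometry(sigma_xy = 0, sigma_z = 0, loc_per_cluster = 10)
  npc <- generate_npc_localisations(6, g, seed = 5)
  for (p in unique(npc$pore)) {
    zs <- sort(unique(round(npc$z_nm[npc$pore == p], 9)))
    expect_length(zs, 2)
    expect_equal(diff(zs), 46)
    xyz <- unique(round(npc[npc$pore == p, c("x_nm", "y_nm", "z_nm")], 9))
    expect_equal(nrow(xyz), 16)  # 2 rings x 8 clusters (rings aligned in xy)
  }
})

test_that("TIFF round trip preserves counts exactly", {
  m <- fix_model()
  st <- generate_bead_stack(m, n_beads = 2, z_min_um = -0.1, z_max_um = 0.1,
                            z_step_nm = 100, seed = 8)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack_tiff(st, path)
  back <- read_stack_tiff(path)
  expect_equal(length(back), length(st$frames))
  expect_equal(back[[1]], st$frames[[1]])
})
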