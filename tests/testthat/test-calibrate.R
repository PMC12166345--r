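# Calibration preprocessing: focus finding, ROI extraction, QC, deltaZ
# alignment and absolute-Z assignment.

test_that("focus frame is the global maximum-intensity frame", {
  frames <- lapply(1:10, function(k) matrix(10, 5, 5))
  frames[[7]][3, 3] <- 999
  expect_equal(find_focus_frame(frames), 7)

  # synthetic bead: focus within one frame of the stack centre when the
  # bead's focal offset is zero
  m <- fix_model()
  st <- generate_bead_stack(m, n_beads = 1, z_min_um = -1, z_max_um = 1,
                            z_step_nm = 100, seed = 12, focal_sd_nm = 0)
  beads <- suppressMessages(extract_bead_rois(st, st$truth, roi = 15))
  expect_lte(abs(find_focus_frame(beads[[1]]) - 11), 1)

  expect_error(find_focus_frame(lapply(1:4, function(k) matrix(3, 5, 5))),
               "constant")
})

test_that("ROI extraction crops about the bead and rejects border beads", {
  m <- fix_model()
  st <- fix_stack()
  beads <- suppressMessages(extract_bead_rois(st, st$truth, roi = 15))
  expect_equal(length(beads) + nrow(attr(beads, "rejected")),
               nrow(st$truth))
  b <- beads[[1]]
  foc <- suppressMessages(find_focus_frame(b))
  peak <- which(b$pixels[, , foc] == max(b$pixels[, , foc]),
                arr.ind = TRUE)[1, ]
  expect_true(all(abs(peak - 8) <= 1))  # centre pixel of a 15 px crop

  # a bead 3 px from the edge cannot be cropped with roi = 15
  edge <- data.frame(id = 1, x_nm = 3 * 110 + 55, y_nm = 64 * 110 + 55)
  got <- suppressMessages(extract_bead_rois(st, edge, roi = 15))
  expect_length(got, 0)
  expect_equal(attr(got, "rejected")$reason, "border")

  expect_length(suppressMessages(extract_bead_rois(st, st$truth[0, ])), 0)
})

test_that("SNR is max over mean of the whole stack", {
  ones <- array(1, dim = c(2, 2, 2))
  expect_equal(compute_snr(ones), 1)
  v <- array(c(8, 0, 0, 0, 0, 0, 0, 0), dim = c(2, 2, 2))
  expect_equal(compute_snr(v), 8)
  expect_error(compute_snr(array(0, dim = c(2, 2, 2))), "zero-mean")
})

test_that("QC applies co-localisation, SNR and fit-noise rules with one
           verdict per bead", {
  st <- fix_stack()
  beads <- suppressMessages(extract_bead_rois(st, st$truth, roi = 15))

  # clean synthetic beads at healthy photon budgets survive
  qc <- suppressMessages(qc_filter(beads))
  expect_equal(length(qc$kept) + length(qc$rejected), length(beads))
  expect_gt(length(qc$kept), length(beads) / 2)
  verdicts <- vapply(c(qc$kept, qc$rejected), function(b) b$qc, character(1))
  expect_true(all(verdicts %in% c("kept", "rejected:colocalised",
                                  "rejected:low_snr", "rejected:noisy_z",
                                  "rejected:noisy_xy")))

  # two beads 5 px apart are both rejected as co-localised
  b1 <- beads[[1]]; b2 <- beads[[1]]
  b2$id <- 999L; b2$fov_xy_px <- b1$fov_xy_px + c(5, 0)
  qc2 <- suppressMessages(qc_filter(list(b1, b2)))
  expect_length(qc2$kept, 0)
  expect_equal(vapply(qc2$rejected, function(b) b$qc, character(1)),
               rep("rejected:colocalised", 2))

  # a bead with SNR below the minimum of 2 is rejected as low SNR
  dim_bead <- beads[[1]]
  dim_bead$pixels <- dim_bead$pixels * 0 + 100
  dim_bead$pixels[8, 8, 11] <- 190  # max/mean just under 2
  expect_lt(compute_snr(dim_bead), 2)
  qc3 <- suppressMessages(qc_filter(list(dim_bead)))
  expect_equal(qc3$rejected[[1]]$qc, "rejected:low_snr")

  # heavy noise (sigma comparable to the signal) trips a noise rule
  noisy <- beads[[1]]
  set.seed(1)
  noisy$pixels <- pmax(noisy$pixels +
    array(rnorm(length(noisy$pixels), 0, 400), dim = dim(noisy$pixels)), 0)
  qc4 <- suppressMessages(qc_filter(list(noisy)))
  expect_match(qc4$rejected[[1]]$qc, "rejected:(low_snr|noisy_z|noisy_xy)")
})

test_that("deltaZ alignment recovers constructed integer shifts exactly", {
  al <- fix_aligned()
  ref <- al$beads[[al$reference_index]]

  # identity: aligning the reference against itself gives deltaZ = 0
  expect_equal(ref$delta_z_nm, 0)

  # constructed roll: +3 frames at 100 nm steps -> deltaZ = 300 nm
  n_z <- dim(ref$pixels)[3]
  for (k in c(-4L, 1L, 3L)) {
    rolled <- ref
    rolled$id <- 1000L + k
    idx <- ((seq_len(n_z) - 1 - k) %% n_z) + 1  # rolled[j] = ref[j - k]
    rolled$pixels <- ref$pixels[, , idx]
    out <- suppressMessages(
      align_z_offsets(list(ref, rolled), z_step_nm = 100, reference = 1))
    expect_equal(out$beads[[2]]$delta_z_nm, k * 100)
  }
})

test_that("deltaZ alignment recovers the generator's focal offsets to
           within one frame", {
  st <- fix_stack()
  al <- fix_aligned()
  ref_z0 <- st$truth$z0_nm[al$beads[[al$reference_index]]$id]
  for (b in al$beads) {
    true_dz <- st$truth$z0_nm[b$id] - ref_z0
    expect_lte(abs(b$delta_z_nm - true_dz), 100 + 1e-9)
  }
})

test_that("absolute Z frame maximises sharpness and accepts metric
           overrides", {
  # constructed: a photon-conserving spot whose blur grows monotonically
  # away from frame 4 (amplitude falls as the width grows, as for a PSF)
  frames <- lapply(1:9, function(k) {
    s <- 1 + 0.8 * abs(k - 4)
    outer(dnorm(1:15, 8, s), dnorm(1:15, 8, s))
  })
  bead <- structure(list(pixels = simplify2array(frames)), class = "bead_roi")
  expect_equal(set_absolute_z(bead), 4)

  # metric override to max pixel (unsmoothed) reproduces the focus-frame
  # rule
  st_bead <- fix_aligned()$beads[[1]]
  expect_equal(set_absolute_z(st_bead, sharpness = sharpness_max_pixel,
                              smooth_frames = 1),
               suppressMessages(find_focus_frame(st_bead)))

  # on a synthetic bead the sharpest frame is near the generator focus
  # frame (astigmatism flattens the sharpness profile, so allow 2 frames)
  m <- fix_model()
  st1 <- generate_bead_stack(m, n_beads = 1, z_min_um = -1, z_max_um = 1,
                             z_step_nm = 100, seed = 21, focal_sd_nm = 0,
                             brightness_range = c(2, 2))
  b1 <- suppressMessages(extract_bead_rois(st1, st1$truth, roi = 15))[[1]]
  expect_lte(abs(set_absolute_z(b1) - 11), 2)
})
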