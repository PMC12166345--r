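# Axial KDE profiles, prominence-based peak detection, double-ring success
# classification and the render threshold.

test_that("KDE matches its closed form and the brute-force kernel sum", {
  # single value: peak density 1/(h * sqrt(2*pi)) at the value
  p <- kde_profile(0, bandwidth = 15)
  expect_equal(max(p$density), 1 / (15 * sqrt(2 * pi)), tolerance = 1e-12)
  expect_equal(p$grid[which.max(p$density)], 0)

  # brute-force double loop on 1000 random values
  set.seed(4)
  z <- rnorm(1000, 0, 80)
  p2 <- kde_profile(z, bandwidth = 15, grid_step = 5)
  brute <- vapply(p2$grid, function(g) {
    s <- 0
    for (zi in z) s <- s + dnorm((g - zi) / 15)
    s / 15
  }, numeric(1))
  expect_lt(max(abs(p2$density - brute) / brute), 1e-9)

  # mass: the profile integrates to the localisation count
  expect_equal(sum(p2$density) * 5, 1000, tolerance = 0.01 * 1000)

  # normalised convention divides by N
  p3 <- kde_profile(z, bandwidth = 15, grid_step = 5, normalise = TRUE)
  expect_equal(p3$density, p2$density / 1000)

  expect_error(kde_profile(numeric(0), 15), "at least one")
  expect_error(kde_profile(0, bandwidth = 0), "bandwidth")
})

test_that("two delta-clusters 46 nm apart give a bimodal profile with modes
           near the cluster centres", {
  z <- rep(c(0, 46), each = 100)
  p <- kde_profile(z, bandwidth = 15, grid_step = 0.5)
  pk <- suppressMessages(detect_peaks(p$grid, p$density, 1e-4))
  expect_equal(nrow(pk), 2)
  pos <- sort(pk$position)
  expect_lt(abs(pos[1] - 0), 2)
  expect_lt(abs(pos[2] - 46), 2)
})

test_that("peak detection honours monotonicity, symmetry and the
           prominence threshold", {
  g <- seq(0, 100, by = 1)
  expect_equal(nrow(detect_peaks(g, g / 100)), 0)  # monotone: no peaks

  # two equal, well-separated peaks: equal prominence
  d <- dnorm(g, 30, 8) + dnorm(g, 70, 8)
  pk <- suppressMessages(detect_peaks(g, d, 1e-4))
  expect_equal(nrow(pk), 2)
  expect_equal(pk$prominence[1], pk$prominence[2], tolerance = 1e-9)

  # a bump of prominence ~3e-5 is excluded at the 1e-4 threshold
  g2 <- seq(0, 200, by = 1)
  d2 <- dnorm(g2, 50, 10) + dnorm(g2, 150, 10) +
    4.8e-5 * dnorm(g2, 100, 5) * sqrt(2 * pi) * 5
  pk_all <- suppressMessages(detect_peaks(g2, d2, 1e-6))
  pk_thr <- suppressMessages(detect_peaks(g2, d2, 1e-4))
  expect_equal(nrow(pk_all), 3)
  expect_equal(nrow(pk_thr), 2)
  small <- pk_all$prominence[pk_all$position == 100]
  expect_lt(small, 1e-4)

  expect_error(detect_peaks(c(1, 1, 2), c(0, 1, 0)), "increasing")
})

test_that("the 40-60 nm window classifies double rings inclusively", {
  mk <- function(p1, p2) data.frame(position = c(p1, p2), height = c(1, 1),
                                    prominence = c(1, 0.9))
  expect_equal(classify_pore(mk(0, 46)), "successful")
  expect_equal(classify_pore(mk(0, 40)), "successful")   # inclusive ends
  expect_equal(classify_pore(mk(0, 60)), "successful")
  expect_equal(classify_pore(mk(0, 30)), "unsuccessful")
  expect_equal(classify_pore(mk(0, 61)), "unsuccessful")
  expect_equal(classify_pore(mk(0, 46)[1, ]), "unsuccessful")  # single peak
})

test_that("render threshold is the mean of mean peak height and the
           inter-peak minimum", {
  g <- 0:100
  d <- c(seq(0, 0.5, length.out = 21),        # rise to first peak region
         seq(0.5, 0.2, length.out = 20),      # descend into the valley
         rep(0.2, 20),                        # valley floor
         seq(0.2, 0.4, length.out = 20),      # rise towards second peak
         seq(0.4, 0.1, length.out = 20))      # tail
  d[21] <- 0.8; d[81] <- 0.6                  # the two peaks
  pk <- data.frame(position = c(20, 80), height = c(0.8, 0.6),
                   prominence = c(0.8, 0.6))
  expect_equal(render_threshold(g, d, pk), (0.7 + 0.2) / 2)
  expect_equal(render_threshold(g, d, pk[1, ]), 0)  # < 2 peaks

  # bound property on random profiles
  set.seed(9)
  for (i in 1:20) {
    z <- rnorm(40, 0, 40)
    pa <- suppressMessages(pore_analysis(z))
    expect_gte(pa$threshold, 0)
    if (nrow(pa$peaks) >= 2) {
      expect_lte(pa$threshold, max(pa$density))
      expect_gte(pa$threshold, min(pa$density))
    }
  }
})

test_that("classification is invariant under a global z shift", {
  set.seed(6)
  npc <- generate_npc_localisations(10, npc_geometry(sigma_z = 8), seed = 6)
  for (p in unique(npc$pore)) {
    z <- npc$z_nm[npc$pore == p]
    a <- suppressMessages(pore_analysis(z))
    b <- suppressMessages(pore_analysis(z + 12345.6))
    expect_equal(a$classification, b$classification)
    expect_equal(a$separation_nm, b$separation_nm, tolerance = 1e-9)
  }
})

test_that("success counts respond to bandwidth as oversmoothing predicts", {
  # low axial noise: at the 15 nm working bandwidth most pores resolve;
  # at 60 nm the rings blur together and successes drop
  npc <- generate_npc_localisations(40, npc_geometry(sigma_z = 5), seed = 31)
  sc <- suppressMessages(success_curve(npc, bandwidths = c(15, 60)))
  n15 <- sc$curve$n_successful[sc$curve$bandwidth == 15]
  n60 <- sc$curve$n_successful[sc$curve$bandwidth == 60]
  expect_gt(n15, 20)  # majority of 40
  expect_lt(n60, n15)

  # zero structures
  sc0 <- success_curve(list(), bandwidths = c(15, 60))
  expect_equal(sc0$curve$n_successful, c(0, 0))
})

test_that("per-structure report covers every group with consistent
           verdicts", {
  npc <- generate_npc_localisations(15, seed = 13)
  rep <- suppressMessages(analyse_pores(npc))
  expect_equal(nrow(rep), 15)
  expect_true(all(rep$classification %in% c("successful", "unsuccessful")))
  expect_true(all(rep$n_locs > 0))
  # separation defined iff >= 2 peaks
  expect_true(all(is.na(rep$separation_nm) == (rep$n_peaks < 2)))
})
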