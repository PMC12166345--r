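# The two-branch axial regressor: build, train, predict, evaluate,
# persist.

test_that("built models run a finite forward pass and report parameters", {
  m <- suppressMessages(zreg_build(backbone = "tiny_cnn", seed = 1))
  imgs <- array(0, dim = c(64, 64, 4))
  coords <- matrix(0, 4, 2)
  z <- predict_z(m, imgs, coords)
  expect_length(z, 4)
  expect_true(all(is.finite(z)))
  expect_gt(m$n_params, 1e4)

  expect_error(suppressMessages(zreg_build(backbone = "resnet50")),
               "tiny_cnn, mobilenet_v3_small")
})

test_that("the mobilenet backbone builds with a parameter count on the
           order of millions and runs forward", {
  m <- suppressMessages(zreg_build(backbone = "mobilenet_v3_small",
                                   seed = 1))
  expect_gt(m$n_params, 1e6)
  expect_lt(m$n_params, 1e7)
  imgs <- array(runif(64 * 64 * 2), dim = c(64, 64, 2))
  z <- predict_z(m, imgs, matrix(0.1, 2, 2))
  expect_true(all(is.finite(z)))
})

test_that("model building is deterministic under a fixed seed", {
  imgs <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  coords <- matrix(runif(6, -1, 1), 3, 2)
  a <- suppressMessages(zreg_build(seed = 5))
  b <- suppressMessages(zreg_build(seed = 5))
  expect_identical(predict_z(a, imgs, coords), predict_z(b, imgs, coords))
  c <- suppressMessages(zreg_build(seed = 6))
  expect_false(identical(predict_z(a, imgs, coords),
                         predict_z(c, imgs, coords)))
})

test_that("the regressor memorises a single bead to high precision", {
  al <- fix_aligned()
  b <- al$beads[[1]]
  ds0 <- suppressMessages(build_dataset(list(b), seed = 1, augment = FALSE,
                                        split_fractions = c(train = 1,
                                                            val = 0,
                                                            test = 0)))
  n <- length(ds0$z)
  ds <- make_dataset(ds0$images[, , c(seq_len(n), seq_len(n))],
                     rbind(ds0$coords, ds0$coords),
                     c(ds0$z, ds0$z),
                     c(rep("train", n), rep("val", n)))
  m <- suppressMessages(zreg_build(seed = 2, dropout_rate = 0))
  cfg <- train_config(max_epochs = 600, lr = 3e-3, batch_size = n,
                      lr_patience = 60, early_stop_patience = 600,
                      seed = 2)
  m <- suppressMessages(zreg_train(m, ds, cfg))
  pred <- predict_z(m, ds0$images, ds0$coords)
  rmse <- sqrt(mean((pred - ds0$z)^2))
  expect_lt(rmse, 10)

  # predictions on the memorised inputs sit within 10 nm of the labels
  expect_lt(max(abs(pred - ds0$z)), 30)
})

test_that("early stopping fires on a constant-label dataset", {
  ds <- fix_dataset()
  idx <- which(ds$split == "train")[1:64]
  dsc <- make_dataset(ds$images[, , c(idx, idx)],
                      rbind(ds$coords[idx, ], ds$coords[idx, ]),
                      rep(0, 2 * length(idx)),
                      c(rep("train", length(idx)), rep("val", length(idx))))
  m <- suppressMessages(zreg_build(seed = 3))
  cfg <- train_config(max_epochs = 200, early_stop_patience = 3, seed = 3)
  m <- suppressMessages(zreg_train(m, dsc, cfg))
  expect_lt(m$train_summary$epochs_run, 200)
})

test_that("prediction is deterministic and validates its inputs", {
  m <- suppressMessages(zreg_build(seed = 4))
  imgs <- array(runif(64 * 64 * 2), dim = c(64, 64, 2))
  dup <- imgs[, , c(1, 1)]
  z <- predict_z(m, dup, matrix(0.2, 2, 2))
  expect_identical(z[1], z[2])
  expect_identical(predict_z(m, imgs, matrix(0, 2, 2)),
                   predict_z(m, imgs, matrix(0, 2, 2)))

  expect_error(predict_z(m, imgs * 2, matrix(0, 2, 2)), "\\[0, 1\\]")
  expect_error(predict_z(m, imgs, matrix(5, 2, 2)), "\\[-1, 1\\]")
  expect_error(predict_z(m, array(0, dim = c(32, 32, 2)),
                         matrix(0, 2, 2)), "64 x 64")
  expect_error(predict_z(m, imgs, matrix(0, 3, 2)), "matching")
})

test_that("evaluation metrics agree with closed forms", {
  ds <- fix_dataset()
  m <- suppressMessages(zreg_build(seed = 8))

  # perfect predictor: relabel the test split with the model's own output
  sub_idx <- which(ds$split == "test")
  pred <- predict_z(m, ds$images[, , sub_idx], ds$coords[sub_idx, ])
  ds_perfect <- ds
  ds_perfect$z[sub_idx] <- pred
  ev <- zreg_evaluate(m, ds_perfect, "test")
  expect_equal(ev$rmse_nm, 0, tolerance = 1e-9)
  expect_equal(ev$slope, 1, tolerance = 1e-9)
  expect_equal(ev$intercept, 0, tolerance = 1e-6)

  # constant-zero predictor on uniform z in [-1000, 1000]:
  # RMSE -> 1000/sqrt(3) ~ 577 nm
  mz <- m
  mz$net$head[[length(mz$net$head)]]$params$W[] <- 0
  mz$net$head[[length(mz$net$head)]]$params$b[] <- 0
  set.seed(10)
  n <- 4000
  dsu <- make_dataset(array(runif(64 * 64 * 64), dim = c(64, 64, 64))[, ,
                        rep(1:64, length.out = n)],
                      matrix(0, n, 2), runif(n, -1000, 1000),
                      rep("test", n))
  ev0 <- zreg_evaluate(mz, dsu, "test")
  expect_equal(ev0$rmse_nm, 1000 / sqrt(3), tolerance = 0.05 * 577)
})

test_that("checkpoints round-trip bit-for-bit and refuse mismatches", {
  m <- suppressMessages(zreg_build(seed = 11))
  imgs <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  coords <- matrix(runif(6, -1, 1), 3, 2)
  before <- predict_z(m, imgs, coords)
  path <- withr::local_tempfile(fileext = ".rds")
  zreg_save(m, path)
  back <- zreg_load(path)
  expect_identical(predict_z(back, imgs, coords), before)

  expect_error(zreg_load(file.path(tempdir(), "nope.rds")), "no checkpoint")
  expect_error(zreg_load(path, expect_backbone = "mobilenet_v3_small"),
               "tiny_cnn")

  # a sidecar disagreeing with the weights is an error
  side <- yaml::read_yaml(paste0(path, ".yaml"))
  side$backbone <- "mobilenet_v3_small"
  yaml::write_yaml(side, paste0(path, ".yaml"))
  expect_error(zreg_load(path), "does not match")
})

test_that("training aborts on non-finite loss with a diagnostic", {
  ds <- fix_dataset()
  idx <- which(ds$split == "train")[1:32]
  bad <- make_dataset(ds$images[, , c(idx, idx)],
                      rbind(ds$coords[idx, ], ds$coords[idx, ]),
                      c(rep(1e160, length(idx)), rep(1e160, length(idx))),
                      c(rep("train", length(idx)),
                        rep("val", length(idx))))
  m <- suppressMessages(zreg_build(seed = 1))
  expect_error(suppressMessages(
    zreg_train(m, bad, train_config(max_epochs = 3, seed = 1))),
    "non-finite")
})
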