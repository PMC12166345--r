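## The axial regressor: build / train / predict / evaluate / persist, plus
## the S3 methods of the fitted-model object.

#' Training configuration for the axial regressor
#'
#' AdamW with mean-squared-error loss, learning-rate reduction when the
#' training loss plateaus, and early stopping when the validation loss
#' ceases to decrease (the best-validation weights are restored).
#'
#' @param lr Initial learning rate.
#' @param weight_decay AdamW decoupled weight decay.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch budget.
#' @param lr_factor,lr_patience Plateau reduction: multiply `lr` by
#'   `lr_factor` after `lr_patience` epochs without training-loss
#'   improvement.
#' @param early_stop_patience Stop after this many epochs without
#'   validation-loss improvement.
#' @param min_lr Floor for the reduced learning rate.
#' @param seed Integer seed for shuffling and dropout.
#' @param verbose Print per-epoch losses.
#' @return List of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, weight_decay = 1e-4, batch_size = 128,
                         max_epochs = 60, lr_factor = 0.5, lr_patience = 5,
                         early_stop_patience = 10, min_lr = 1e-5,
                         seed = 1L, verbose = FALSE) {
  stopifnot(lr > 0, lr_patience >= 1, early_stop_patience >= 1)
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = batch_size, max_epochs = max_epochs,
                 lr_factor = lr_factor, lr_patience = lr_patience,
                 early_stop_patience = early_stop_patience, min_lr = min_lr,
                 seed = seed, verbose = verbose),
            class = "train_config")
}

#' Build an (untrained) axial regressor
#'
#' Assembles the two-branch network: a convolutional backbone embeds the
#' 64 x 64 localisation image, two dense layers embed the normalised field
#' coordinates, and a dropout + dense head maps the concatenated embedding
#' to a single axial position. Targets are scaled to units of `z_range_nm`
#' (so the network regresses values in roughly [-1, 1]) and rescaled to nm
#' at prediction time; the scaling is stored with the model.
#'
#' @param backbone `"tiny_cnn"` or `"mobilenet_v3_small"`.
#' @param image_size Input image side (pixels).
#' @param z_range_nm Working half-range (nm) used as the target scale.
#' @param coord_widths Widths of the two coordinate-branch dense layers.
#' @param head_widths Widths of the head dense layers (before the final
#'   scalar output).
#' @param conv_channels,embed_dim tiny_cnn backbone widths: channels of the
#'   two convolutions and the image-embedding dimension.
#' @param dropout_rate Dropout rate at the concatenated embedding.
#' @param input_gain Fixed multiplicative rescale applied to the input
#'   images inside the network. Images normalised by the 16-bit maximum
#'   occupy only a small slice of `[0, 1]`; the constant gain restores a
#'   dynamic range the ReLU stack trains well on. Stored with the model.
#' @param fov_px,pixel_size Field geometry the model is calibrated for;
#'   stored so that applying the model to mismatched data errors out.
#' @param seed Integer seed for weight initialisation.
#' @return Object of class `z_regressor`.
#' @export
zreg_build <- function(backbone = c("tiny_cnn", "mobilenet_v3_small"),
                       image_size = 64, z_range_nm = 1000,
                       coord_widths = c(64, 64), head_widths = c(64),
                       conv_channels = c(16L, 32L), embed_dim = 128L,
                       dropout_rate = 0.2, input_gain = 100,
                       fov_px = c(256, 256),
                       pixel_size = 110, seed = 1L) {
  backbone <- if (is.character(backbone) && length(backbone) > 1)
    backbone[1] else backbone
  with_seed(seed, {
    br <- build_branches(backbone, image_size, coord_widths, head_widths,
                         dropout_rate, conv_channels, embed_dim)
    net <- list(image_branch = br$image_branch,
                coord_branch = br$coord_branch, head = br$head,
                input_gain = input_gain,
                channels = if (backbone == "mobilenet_v3_small") 3L else 1L)
    n_par <- count_params(net_params(net))
    smlmz_log("built %s backbone: %s trainable parameters", backbone,
              format(n_par, big.mark = ","))
    structure(list(net = net, backbone = backbone,
                   norm = list(intensity_divisor = INT16_MAX,
                               image_size = image_size,
                               z_range_nm = z_range_nm,
                               fov_px = fov_px, pixel_size = pixel_size),
                   n_params = n_par, seed = seed,
                   trained = FALSE, history = NULL),
              class = "z_regressor")
  })
}

## Images in any of: [s, s, N] array, [s*s, N] matrix. Returns [s*s, N].
flatten_images <- function(images, image_size) {
  if (is.matrix(images) && nrow(images) == image_size^2) return(images)
  d <- dim(images)
  if (length(d) == 2 && all(d == c(image_size, image_size))) {
    dim(images) <- c(image_size^2, 1)
    return(images)
  }
  if (length(d) == 3 && d[1] == image_size && d[2] == image_size) {
    dim(images) <- c(image_size^2, d[3])
    return(images)
  }
  stop(sprintf("images must be %d x %d (x N)", image_size, image_size),
       call. = FALSE)
}

check_inputs <- function(model, imgs, coords) {
  if (min(imgs) < 0 || max(imgs) > 1)
    stop("image intensities must lie in [0, 1] (divide by the 16-bit max)",
         call. = FALSE)
  if (ncol(coords) != 2 || nrow(coords) != ncol(imgs))
    stop("coords must be an N x 2 matrix matching the image count",
         call. = FALSE)
  if (any(abs(coords) > 1 + 1e-9))
    stop("coords must be normalised to [-1, 1]", call. = FALSE)
  invisible(TRUE)
}

#' Train the axial regressor on a calibration dataset
#'
#' Minimises the mean squared error of the scaled axial position on the
#' training split while monitoring the validation split. The learning rate
#' is halved when the training loss plateaus; training stops early when the
#' validation loss stops improving, and the best-validation weights are
#' restored. A non-finite loss aborts with a diagnostic.
#'
#' @param model A `z_regressor` from [zreg_build()].
#' @param dataset A `calibration_dataset` with non-empty train and val
#'   splits.
#' @param config A [train_config()].
#' @return The trained `z_regressor`; `$history` holds per-epoch losses and
#'   learning rates.
#' @export
zreg_train <- function(model, dataset, config = train_config()) {
  stopifnot(inherits(model, "z_regressor"),
            inherits(dataset, "calibration_dataset"),
            inherits(config, "train_config"))
  tr <- dataset_subset(dataset, "train")
  va <- dataset_subset(dataset, "val")
  if (length(tr$z) == 0 || length(va$z) == 0)
    stop("dataset must have non-empty train and val splits", call. = FALSE)
  s <- model$norm$image_size
  zr <- model$norm$z_range_nm
  Xtr <- flatten_images(tr$images, s); Ctr <- t(tr$coords)
  ytr <- tr$z / zr
  Xva <- flatten_images(va$images, s); Cva <- t(va$coords)
  yva <- va$z / zr
  net <- model$net
  with_seed(config$seed, {
    params <- net_params(net)
    m_state <- NULL; v_state <- NULL; t_step <- 0L
    lr <- config$lr
    n <- length(ytr)
    best_train <- Inf; train_wait <- 0L
    best_val <- Inf; val_wait <- 0L; best_params <- params
    hist <- list()
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      nb <- ceiling(n / config$batch_size)
      ep_loss <- 0
      for (b in seq_len(nb)) {
        idx <- ord[(((b - 1) * config$batch_size) + 1):min(b * config$batch_size, n)]
        net <- net_set_params(net, params)
        fw <- net_forward(net, Xtr[, idx, drop = FALSE],
                          Ctr[, idx, drop = FALSE], training = TRUE)
        err <- fw$Y - matrix(ytr[idx], nrow = 1)
        loss <- mean(err^2)
        if (!is.finite(loss))
          stop(sprintf("non-finite training loss at epoch %d batch %d; ",
                       epoch, b),
               "reduce the learning rate or check the inputs", call. = FALSE)
        ep_loss <- ep_loss + loss * length(idx)
        dY <- 2 * err / length(idx)
        grads <- net_backward(net, fw$cache, dY)
        t_step <- t_step + 1L
        upd <- adamw_step(params, grads, m_state, v_state, lr,
                          config$weight_decay, 0.9, 0.999, 1e-8, t_step)
        params <- upd$params; m_state <- upd$m; v_state <- upd$v
      }
      ep_loss <- ep_loss / n
      net <- net_set_params(net, params)
      val_pred <- net_predict(net, Xva, Cva, batch = 512)
      val_loss <- mean((val_pred - yva)^2)
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss,
                                  val_loss = val_loss, lr = lr)
      if (config$verbose)
        smlmz_log("epoch %3d  train %.5f  val %.5f  lr %.2g",
                  epoch, ep_loss, val_loss, lr)
      ## plateau LR schedule on the training loss
      if (ep_loss < best_train - 1e-7) {
        best_train <- ep_loss; train_wait <- 0L
      } else {
        train_wait <- train_wait + 1L
        if (train_wait >= config$lr_patience) {
          lr <- max(lr * config$lr_factor, config$min_lr)
          train_wait <- 0L
        }
      }
      ## early stopping on the validation loss
      if (val_loss < best_val - 1e-7) {
        best_val <- val_loss; val_wait <- 0L; best_params <- params
      } else {
        val_wait <- val_wait + 1L
        if (val_wait >= config$early_stop_patience) {
          smlmz_log("early stopping at epoch %d (best val %.5f)",
                    epoch, best_val)
          break
        }
      }
    }
    model$net <- net_set_params(net, best_params)
    model$history <- do.call(rbind, hist)
    model$trained <- TRUE
    model$train_config <- config
    model$train_summary <- list(epochs_run = nrow(model$history),
                                final_train_loss = ep_loss,
                                best_val_loss = best_val,
                                n_train = n, n_val = length(yva))
    model
  })
}

## Batched deterministic forward pass on flattened inputs (scaled units).
net_predict <- function(net, X, C, batch = 512) {
  n <- ncol(X)
  out <- numeric(n)
  for (start in seq(1, n, by = batch)) {
    idx <- start:min(start + batch - 1, n)
    out[idx] <- as.vector(net_forward(net, X[, idx, drop = FALSE],
                                      C[, idx, drop = FALSE],
                                      training = FALSE)$Y)
  }
  out
}

#' Predict axial positions
#'
#' @param model A `z_regressor`.
#' @param images `[64, 64, N]` array (or `[4096, N]` matrix) of [0, 1]
#'   localisation images.
#' @param coords `N x 2` matrix of normalised field coordinates in [-1, 1].
#' @return Numeric vector of axial positions (nm).
#' @export
predict_z <- function(model, images, coords) {
  stopifnot(inherits(model, "z_regressor"))
  s <- model$norm$image_size
  X <- flatten_images(images, s)
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 2)
  check_inputs(model, X, coords)
  net_predict(model$net, X, t(coords)) * model$norm$z_range_nm
}

#' @export
predict.z_regressor <- function(object, images, coords, ...) {
  predict_z(object, images, coords)
}

#' Evaluate the regressor on a dataset split
#'
#' Reports the global root-mean-squared error (nm), the per-bead RMSE, and
#' the slope/intercept of the predicted-versus-true regression line (a
#' well-calibrated model tracks the stage movement with slope ~1).
#'
#' @param model A trained `z_regressor`.
#' @param dataset A `calibration_dataset`.
#' @param split Which split to evaluate (default `"test"`).
#' @return List of class `zreg_evaluation`: `rmse_nm`, `per_bead`
#'   (data.frame with bead key and RMSE), `slope`, `intercept`, `n`,
#'   and the per-record `predicted` / `true` vectors.
#' @export
zreg_evaluate <- function(model, dataset, split = "test") {
  sub <- dataset_subset(dataset, split)
  if (length(sub$z) == 0) stop("split '", split, "' is empty", call. = FALSE)
  pred <- predict_z(model, sub$images, sub$coords)
  rmse <- sqrt(mean((pred - sub$z)^2))
  per_bead <- vapply(split(seq_along(sub$z), sub$bead_key), function(ii)
    sqrt(mean((pred[ii] - sub$z[ii])^2)), numeric(1))
  fit <- lm(pred ~ sub$z)
  structure(list(rmse_nm = rmse,
                 per_bead = data.frame(bead_key = names(per_bead),
                                       rmse_nm = as.numeric(per_bead),
                                       row.names = NULL),
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 n = length(sub$z), predicted = pred, true = sub$z),
            class = "zreg_evaluation")
}

#' @export
print.zreg_evaluation <- function(x, ...) {
  cat(sprintf("RMSE %.2f nm over %d datapoints (%d beads)\n",
              x$rmse_nm, x$n, nrow(x$per_bead)))
  cat(sprintf("predicted-vs-true slope %.3f, intercept %.1f nm\n",
              x$slope, x$intercept))
  invisible(x)
}

#' @export
print.z_regressor <- function(x, ...) {
  cat(sprintf("Axial regressor (%s backbone, %s parameters)%s\n",
              x$backbone, format(x$n_params, big.mark = ","),
              if (x$trained) "" else " [untrained]"))
  cat(sprintf("  working range +/- %g nm, %d x %d inputs, FOV %d x %d px @ %g nm\n",
              x$norm$z_range_nm, x$norm$image_size, x$norm$image_size,
              x$norm$fov_px[1], x$norm$fov_px[2], x$norm$pixel_size))
  if (x$trained)
    cat(sprintf("  trained %d epochs, best val loss %.5f\n",
                x$train_summary$epochs_run, x$train_summary$best_val_loss))
  invisible(x)
}

#' @export
summary.z_regressor <- function(object, ...) {
  print(object)
  if (object$trained) {
    h <- object$history
    cat("\nTraining history (last 5 epochs):\n")
    print(utils::tail(h, 5), row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.z_regressor <- function(x, ...) {
  if (!x$trained) stop("model is untrained; nothing to plot", call. = FALSE)
  h <- x$history
  plot(h$epoch, h$train_loss, type = "l", log = "y", xlab = "epoch",
       ylab = "MSE (scaled z)", main = "Training history", ...)
  lines(h$epoch, h$val_loss, lty = 2)
  legend("topright", legend = c("train", "val"), lty = 1:2, bty = "n")
  invisible(x)
}

#' Save / load a trained regressor
#'
#' The weights and architecture are stored as RDS with a YAML sidecar
#' recording the backbone, normalisation constants, seed and a dataset
#' fingerprint, so a checkpoint cannot be silently applied with the wrong
#' normalisation. Loading verifies the sidecar against the weights and,
#' optionally, an expected backbone.
#'
#' @param model A `z_regressor`.
#' @param path Output `.rds` path (sidecar at `paste0(path, ".yaml")`).
#' @export
zreg_save <- function(model, path) {
  stopifnot(inherits(model, "z_regressor"))
  saveRDS(model, path)
  side <- list(backbone = model$backbone, n_params = model$n_params,
               norm = model$norm, seed = model$seed,
               trained = model$trained)
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname zreg_save
#' @param expect_backbone If given, loading a checkpoint with a different
#'   backbone is an error.
#' @export
zreg_load <- function(path, expect_backbone = NULL) {
  if (!file.exists(path)) stop("no checkpoint at ", path, call. = FALSE)
  model <- readRDS(path)
  if (!inherits(model, "z_regressor"))
    stop("file does not contain a z_regressor", call. = FALSE)
  sidecar <- paste0(path, ".yaml")
  if (file.exists(sidecar)) {
    side <- yaml::read_yaml(sidecar)
    if (!identical(side$backbone, model$backbone))
      stop("checkpoint sidecar backbone '", side$backbone,
           "' does not match weights '", model$backbone, "'", call. = FALSE)
  }
  if (!is.null(expect_backbone) && !identical(expect_backbone, model$backbone))
    stop("checkpoint has backbone '", model$backbone,
         "' but '", expect_backbone, "' was requested", call. = FALSE)
  model
}
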