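## Two-branch network assembly and the training loop.
##
## The regressor has an image branch (a convolutional backbone on the 64 x 64
## localisation image), a coordinate branch (two dense layers on the
## normalised field position), and a head (dropout + dense layers on the
## concatenated embeddings) emitting one scalar: the axial position in units
## of the working half-range. Two backbones are available: `tiny_cnn`, a
## small strided CNN adequate for pixel-integrated Gaussian-like PSFs and
## cheap enough to train on a single CPU core, and `mobilenet_v3_small`, a
## structural implementation of the MobileNetV3-small feature extractor
## (inverted residual blocks with depthwise convolutions, squeeze-excitation
## and hard-swish; normalisation layers folded into per-channel affine
## transforms, randomly initialised).

backbone_tiny_cnn <- function(image_size, conv_channels = c(16L, 32L),
                              embed_dim = 128L) {
  s <- c(image_size, image_size, 1L)
  ## the 64 x 64 input is an upsampled 15 x 15 crop, so a 4 x 4 average
  ## pool loses no information and keeps the im2col gathers small
  p0 <- nn_avgpool(s, 4L)
  l1 <- nn_conv(p0$out_shape, out_channels = conv_channels[1], kernel = 3L,
                stride = 1L, need_input_grad = FALSE)
  l2 <- nn_act("relu", l1$out_shape)
  l3 <- nn_conv(l1$out_shape, out_channels = conv_channels[2], kernel = 3L,
                stride = 2L)
  l4 <- nn_act("relu", l3$out_shape)
  flat <- prod(l3$out_shape)
  l5 <- nn_dense(flat, embed_dim)
  l6 <- nn_act("relu", embed_dim)
  list(p0, l1, l2, l3, l4, l5, l6)
}

## One MobileNetV3 inverted-residual block (expand -> depthwise -> optional
## squeeze-excite -> project), normalisations folded to per-channel affines.
mnv3_block <- function(in_shape, kernel, expand, out_channels, se, act,
                       stride) {
  C <- in_shape[3]
  layers <- list()
  shape <- in_shape
  if (expand != C) {
    l <- nn_conv(shape, expand, kernel = 1L)
    layers <- c(layers, list(l, nn_affine(l$out_shape),
                             nn_act(act, l$out_shape)))
    shape <- l$out_shape
  }
  l <- nn_conv(shape, expand, kernel = kernel, stride = stride,
               pad = kernel %/% 2L, depthwise = TRUE)
  layers <- c(layers, list(l, nn_affine(l$out_shape),
                           nn_act(act, l$out_shape)))
  shape <- l$out_shape
  if (se) layers <- c(layers, list(nn_se(shape)))
  l <- nn_conv(shape, out_channels, kernel = 1L)
  layers <- c(layers, list(l, nn_affine(l$out_shape)))
  nn_block(layers, residual = (stride == 1L && C == out_channels))
}

backbone_mobilenet_v3_small <- function(image_size) {
  ## input: single channel replicated to 3 by the caller
  s <- c(image_size, image_size, 3L)
  stem <- nn_conv(s, 16L, kernel = 3L, stride = 2L, pad = 1L,
                  need_input_grad = FALSE)
  layers <- list(stem, nn_affine(stem$out_shape),
                 nn_act("hswish", stem$out_shape))
  shape <- stem$out_shape
  spec <- list(
    list(3L,  16L, 16L, TRUE,  "relu",   2L),
    list(3L,  72L, 24L, FALSE, "relu",   2L),
    list(3L,  88L, 24L, FALSE, "relu",   1L),
    list(5L,  96L, 40L, TRUE,  "hswish", 2L),
    list(5L, 240L, 40L, TRUE,  "hswish", 1L),
    list(5L, 240L, 40L, TRUE,  "hswish", 1L),
    list(5L, 120L, 48L, TRUE,  "hswish", 1L),
    list(5L, 144L, 48L, TRUE,  "hswish", 1L),
    list(5L, 288L, 96L, TRUE,  "hswish", 2L),
    list(5L, 576L, 96L, TRUE,  "hswish", 1L),
    list(5L, 576L, 96L, TRUE,  "hswish", 1L))
  for (bs in spec) {
    blk <- mnv3_block(shape, bs[[1]], bs[[2]], bs[[3]], bs[[4]], bs[[5]],
                      bs[[6]])
    layers <- c(layers, list(blk))
    shape <- blk$out_shape
  }
  last <- nn_conv(shape, 576L, kernel = 1L)
  layers <- c(layers, list(last, nn_affine(last$out_shape),
                           nn_act("hswish", last$out_shape),
                           nn_gap(last$out_shape),
                           nn_dense(576L, 1024L), nn_act("hswish", 1024L)))
  layers
}

build_branches <- function(backbone, image_size, coord_widths, head_widths,
                           dropout_rate, conv_channels = c(16L, 32L),
                           embed_dim = 128L) {
  image_branch <- switch(backbone,
                         tiny_cnn = backbone_tiny_cnn(image_size,
                                                      conv_channels,
                                                      embed_dim),
                         mobilenet_v3_small =
                           backbone_mobilenet_v3_small(image_size),
                         stop("unknown backbone '", backbone,
                              "'; available: tiny_cnn, mobilenet_v3_small",
                              call. = FALSE))
  img_dim <- image_branch[[length(image_branch)]]$out_shape
  coord_branch <- list(nn_dense(2L, coord_widths[1]),
                       nn_act("relu", coord_widths[1]),
                       nn_dense(coord_widths[1], coord_widths[2]),
                       nn_act("relu", coord_widths[2]))
  concat_dim <- img_dim + coord_widths[2]
  head <- list(nn_dropout(dropout_rate, concat_dim))
  d <- concat_dim
  for (w in head_widths) {
    head <- c(head, list(nn_dense(d, w), nn_act("relu", w)))
    d <- w
  }
  head <- c(head, list(nn_dense(d, 1L)))
  list(image_branch = image_branch, coord_branch = coord_branch, head = head,
       concat_dim = concat_dim, img_dim = img_dim)
}

## Full forward pass. imgs: [npix, B] matrix; coords: [2, B].
net_forward <- function(net, imgs, coords, training = FALSE) {
  ## fixed input gain: bead images normalised by the 16-bit maximum occupy
  ## only ~1% of the [0, 1] range, which starves ReLU stacks; a constant
  ## architecture-level rescale restores a usable dynamic range
  if (!is.null(net$input_gain) && net$input_gain != 1)
    imgs <- imgs * net$input_gain
  ## replicate the single channel into channel-fastest 3-channel layout
  if (net$channels == 3L) imgs <- imgs[rep(seq_len(nrow(imgs)), each = 3L), ,
                                       drop = FALSE]
  ri <- seq_forward(net$image_branch, imgs, training)
  rc <- seq_forward(net$coord_branch, coords, training)
  rh <- seq_forward(net$head, rbind(ri$Y, rc$Y), training)
  list(Y = rh$Y, cache = list(img = ri$caches, coord = rc$caches,
                              head = rh$caches,
                              img_dim = nrow(ri$Y)))
}

net_backward <- function(net, cache, dY) {
  rh <- seq_backward(net$head, cache$head, dY, need_input_grad = TRUE)
  di <- rh$dX[seq_len(cache$img_dim), , drop = FALSE]
  dc <- rh$dX[-seq_len(cache$img_dim), , drop = FALSE]
  gi <- seq_backward(net$image_branch, cache$img, di, need_input_grad = FALSE)
  gc <- seq_backward(net$coord_branch, cache$coord, dc,
                     need_input_grad = FALSE)
  list(image_branch = gi$grads, coord_branch = gc$grads, head = rh$grads)
}

net_params <- function(net) list(image_branch = seq_params(net$image_branch),
                                 coord_branch = seq_params(net$coord_branch),
                                 head = seq_params(net$head))

net_set_params <- function(net, p) {
  net$image_branch <- seq_set_params(net$image_branch, p$image_branch)
  net$coord_branch <- seq_set_params(net$coord_branch, p$coord_branch)
  net$head <- seq_set_params(net$head, p$head)
  net
}
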