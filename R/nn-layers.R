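## Minimal neural-network engine used by the axial regressor.
##
## Activations are stored as matrices [features, batch]. A feature vector for
## an image tensor uses channel-fastest layout: element (c, h, w) sits at
## index c + C*(h + H*w). This makes the im2col convolution output
## ([Cout, OH*OW*B] with channel fastest per column) reinterpretable as a
## feature matrix by a plain dim() change, with no transposes anywhere in the
## hot path. The single-channel input image is a special case (C = 1) where
## the layout coincides with the raw pixel vector. Convolutions are
## evaluated as matrix products via an im2col index map precomputed per
## layer; the backward scatter uses a sparse matrix (one nonzero per
## gathered element). All randomness (initialisation, dropout, batch
## shuffling) flows through R's RNG so a seed makes runs bit-reproducible.

## ---- initialisers ---------------------------------------------------------

he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

## ---- layer constructors ---------------------------------------------------
## Each layer is a plain list: type, trainable params in $params, fixed
## geometry in the remaining fields. Constructors take the input shape
## (c(H, W, C) for spatial layers, an integer for flat layers) and record the
## output shape so networks can be assembled by folding over a config list.
## `env` holds memoised batch-size-dependent gather indices; being an
## environment it is shared across copies of the layer list.

nn_conv <- function(in_shape, out_channels, kernel, stride = 1, pad = 0,
                    depthwise = FALSE, need_input_grad = TRUE) {
  H <- in_shape[1]; W <- in_shape[2]; C <- in_shape[3]
  k <- kernel
  PH <- H + 2 * pad; PW <- W + 2 * pad
  OH <- (PH - k) %/% stride + 1L
  OW <- (PW - k) %/% stride + 1L
  if (OH < 1 || OW < 1) stop("conv output collapsed to zero size")
  if (depthwise && out_channels != C)
    stop("depthwise conv requires out_channels == in_channels")
  k2 <- k * k
  ## im2col index map into the padded channel-fastest vector:
  ## padded element (c, ph, pw) at index c + C*(ph + PH*pw).
  ## Row order of the map: kernel-row fastest, then kernel-col, then channel.
  oh <- rep(seq_len(OH) - 1L, times = OW)
  ow <- rep(seq_len(OW) - 1L, each = OH)
  top <- oh * stride; left <- ow * stride          # 0-based corners
  kh <- rep(seq_len(k) - 1L, times = k)
  kw <- rep(seq_len(k) - 1L, each = k)
  sp <- C * (outer(kh, top, "+") + PH * outer(kw, left, "+"))  # [k2, OH*OW]
  IDX <- matrix(0L, k2 * C, OH * OW)
  for (c in seq_len(C))
    IDX[((c - 1) * k2 + 1):(c * k2), ] <- sp + (c - 1L)
  IDX <- IDX + 1L
  ## padding embed map: rows of the padded vector holding original pixels
  pad_rows <- NULL
  if (pad > 0) {
    c <- rep(seq_len(C) - 1L, times = H * W)
    h <- rep(rep(seq_len(H) - 1L, each = C), times = W)
    w <- rep(seq_len(W) - 1L, each = C * H)
    pad_rows <- c + C * ((h + pad) + PH * (w + pad)) + 1L
  }
  scatter <- NULL
  if (need_input_grad) {
    scatter <- Matrix::sparseMatrix(i = as.vector(IDX),
                                    j = seq_len(length(IDX)), x = 1,
                                    dims = c(PH * PW * C, length(IDX)))
  }
  params <- if (depthwise) {
    list(W = he_init(C, k2, fan_in = k2), b = numeric(C))
  } else {
    list(W = he_init(out_channels, k2 * C, fan_in = k2 * C),
         b = numeric(out_channels))
  }
  list(type = if (depthwise) "dw_conv" else "conv", params = params,
       in_shape = in_shape, out_shape = c(OH, OW, out_channels),
       k = k, stride = stride, pad = pad, C = C, Cout = out_channels,
       OHOW = OH * OW, PHPWC = PH * PW * C, IDX = IDX,
       pad_rows = pad_rows, scatter = scatter,
       need_input_grad = need_input_grad, env = new.env(parent = emptyenv()))
}

nn_dense <- function(in_dim, out_dim) {
  list(type = "dense",
       params = list(W = he_init(out_dim, in_dim, fan_in = in_dim),
                     b = numeric(out_dim)),
       in_shape = in_dim, out_shape = out_dim)
}

nn_act <- function(kind, shape) list(type = kind, params = NULL,
                                     in_shape = shape, out_shape = shape)

nn_dropout <- function(rate, shape) list(type = "dropout", rate = rate,
                                         params = NULL, in_shape = shape,
                                         out_shape = shape)

## channel-expansion index: feature row (c, o) for o in 1..OHOW
chan_rows <- function(C, OHOW) rep.int(seq_len(C), OHOW)

## Non-overlapping average pooling (stride = size) as one sparse product.
nn_avgpool <- function(in_shape, size) {
  H <- in_shape[1]; W <- in_shape[2]; C <- in_shape[3]
  if (H %% size || W %% size) stop("pool size must divide the input")
  OH <- H %/% size; OW <- W %/% size
  ## output row (c, oh, ow); input rows (c, oh*s+i, ow*s+j), channel-fastest
  orow <- rep(seq_len(C * OH * OW), each = size * size)
  oc <- (orow - 1L) %% C
  osp <- (orow - 1L) %/% C
  ooh <- osp %% OH; oow <- osp %/% OH
  i <- rep_len(rep(seq_len(size) - 1L, times = size), length(orow))
  j <- rep_len(rep(seq_len(size) - 1L, each = size), length(orow))
  irow <- oc + C * ((ooh * size + i) + H * (oow * size + j)) + 1L
  P <- Matrix::sparseMatrix(i = orow, j = irow, x = 1 / (size * size),
                            dims = c(C * OH * OW, C * H * W))
  list(type = "avgpool", params = NULL, in_shape = in_shape,
       out_shape = c(OH, OW, C), P = P)
}

nn_gap <- function(in_shape) {
  C <- in_shape[3]; OHOW <- in_shape[1] * in_shape[2]
  ## mean-pooling matrix [C, C*OHOW] over the channel-fastest layout
  P <- Matrix::sparseMatrix(i = chan_rows(C, OHOW),
                            j = seq_len(C * OHOW), x = 1 / OHOW,
                            dims = c(C, C * OHOW))
  list(type = "gap", params = NULL, in_shape = in_shape, out_shape = C,
       OHOW = OHOW, C = C, P = P)
}

## Per-channel affine (folded normalisation): y = x * g[c] + b[c].
nn_affine <- function(in_shape) {
  C <- in_shape[3]
  list(type = "affine", params = list(g = rep(1, C), b = numeric(C)),
       in_shape = in_shape, out_shape = in_shape,
       OHOW = in_shape[1] * in_shape[2], C = C)
}

## Squeeze-and-excitation: global pool -> dense(C->Cr) relu -> dense(Cr->C)
## hard-sigmoid -> per-channel gate.
nn_se <- function(in_shape, reduce = 4) {
  C <- in_shape[3]
  Cr <- max(1L, as.integer(round(C / reduce)))
  OHOW <- in_shape[1] * in_shape[2]
  P <- Matrix::sparseMatrix(i = chan_rows(C, OHOW),
                            j = seq_len(C * OHOW), x = 1 / OHOW,
                            dims = c(C, C * OHOW))
  list(type = "se",
       params = list(W1 = he_init(Cr, C, fan_in = C), b1 = numeric(Cr),
                     W2 = he_init(C, Cr, fan_in = Cr), b2 = numeric(C)),
       in_shape = in_shape, out_shape = in_shape,
       OHOW = OHOW, C = C, Cr = Cr, P = P)
}

## Residual block: a sequence of sub-layers with optional identity skip.
nn_block <- function(layers, residual) {
  list(type = "block", layers = layers, residual = residual,
       in_shape = layers[[1]]$in_shape,
       out_shape = layers[[length(layers)]]$out_shape)
}

## ---- activations ----------------------------------------------------------

act_forward <- function(kind, x) {
  switch(kind,
         relu = pmax(x, 0),
         hswish = x * pmin(pmax(x + 3, 0), 6) / 6,
         hsigmoid = pmin(pmax(x + 3, 0), 6) / 6,
         stop("unknown activation ", kind))
}

act_backward <- function(kind, x, dy) {
  switch(kind,
         relu = dy * (x > 0),
         hswish = {
           g <- ifelse(x <= -3, 0, ifelse(x >= 3, 1, (2 * x + 3) / 6))
           dy * g
         },
         hsigmoid = dy * ((x > -3) & (x < 3)) / 6,
         stop("unknown activation ", kind))
}

## ---- conv helpers ---------------------------------------------------------

## Gather the im2col matrix [k2C, OHOW*B]; the batch-expanded index is
## memoised per batch size in the layer's environment.
conv_im2col <- function(layer, X) {
  B <- ncol(X)
  Xp <- if (layer$pad > 0) {
    tmp <- matrix(0, layer$PHPWC, B)
    tmp[layer$pad_rows, ] <- X
    tmp
  } else X
  key <- as.character(B)
  big <- layer$env$big[[key]]
  if (is.null(big)) {
    nidx <- length(layer$IDX)
    big <- rep(as.vector(layer$IDX), times = B) +
      rep((seq_len(B) - 1L) * layer$PHPWC, each = nidx)
    if (is.null(layer$env$big)) layer$env$big <- list()
    layer$env$big[[key]] <- big
  }
  cols <- Xp[big]
  dim(cols) <- c(nrow(layer$IDX), layer$OHOW * B)
  cols
}

## ---- forward / backward ---------------------------------------------------

layer_forward <- function(layer, X, training = FALSE) {
  B <- ncol(X)
  switch(layer$type,
    conv = {
      cols <- conv_im2col(layer, X)
      out <- layer$params$W %*% cols + layer$params$b
      dim(out) <- c(layer$Cout * layer$OHOW, B)
      list(Y = out, cache = list(cols = cols, B = B))
    },
    dw_conv = {
      cols <- conv_im2col(layer, X)
      k2 <- layer$k^2
      Wexp <- as.vector(t(layer$params$W))        # (k2 fast, channel slow)
      prod <- cols * Wexp
      dim(prod) <- c(k2, layer$C * layer$OHOW * B)
      out <- colSums(prod)
      dim(out) <- c(layer$C, layer$OHOW * B)
      out <- out + layer$params$b
      dim(out) <- c(layer$C * layer$OHOW, B)
      list(Y = out, cache = list(cols = cols, B = B))
    },
    dense = list(Y = layer$params$W %*% X + layer$params$b,
                 cache = list(X = X)),
    relu = , hswish = , hsigmoid =
      list(Y = act_forward(layer$type, X), cache = list(X = X)),
    dropout = {
      if (training && layer$rate > 0) {
        mask <- (matrix(runif(length(X)), nrow(X)) >= layer$rate) /
          (1 - layer$rate)
        list(Y = X * mask, cache = list(mask = mask))
      } else list(Y = X, cache = list(mask = NULL))
    },
    avgpool = , gap = list(Y = as.matrix(layer$P %*% X),
                           cache = list(B = B)),
    affine = {
      rows <- chan_rows(layer$C, layer$OHOW)
      list(Y = X * layer$params$g[rows] + layer$params$b[rows],
           cache = list(X = X))
    },
    se = {
      s <- as.matrix(layer$P %*% X)                             # [C, B]
      a1 <- layer$params$W1 %*% s + layer$params$b1
      h1 <- pmax(a1, 0)
      a2 <- layer$params$W2 %*% h1 + layer$params$b2
      g <- pmin(pmax(a2 + 3, 0), 6) / 6                         # [C, B]
      gex <- g[chan_rows(layer$C, layer$OHOW), , drop = FALSE]
      list(Y = X * gex, cache = list(X = X, s = s, a1 = a1, h1 = h1,
                                     a2 = a2, g = g, gex = gex, B = B))
    },
    block = {
      caches <- vector("list", length(layer$layers))
      Y <- X
      for (i in seq_along(layer$layers)) {
        r <- layer_forward(layer$layers[[i]], Y, training)
        Y <- r$Y; caches[[i]] <- r$cache
      }
      if (layer$residual) Y <- Y + X
      list(Y = Y, cache = list(caches = caches))
    },
    stop("unknown layer type ", layer$type))
}

## Returns list(dX = ..., grads = ...); grads mirrors layer$params (or, for
## blocks, a list per sub-layer). dX is NULL when need_input_grad is FALSE.
layer_backward <- function(layer, cache, dY, need_input_grad = TRUE) {
  if (is.null(dY)) {
    ## a layer above us truncated the gradient (need_input_grad = FALSE);
    ## only parameter-free layers may sit below such a layer
    if (!is.null(layer$params))
      stop("gradient truncated above a parameterised layer", call. = FALSE)
    return(list(dX = NULL, grads = NULL))
  }
  switch(layer$type,
    conv = {
      B <- cache$B
      dOut <- dY
      dim(dOut) <- c(layer$Cout, layer$OHOW * B)
      grads <- list(W = tcrossprod(dOut, cache$cols), b = rowSums(dOut))
      dX <- NULL
      if (need_input_grad && layer$need_input_grad) {
        dCols <- crossprod(layer$params$W, dOut)
        dim(dCols) <- c(length(layer$IDX), B)
        dXp <- as.matrix(layer$scatter %*% dCols)
        dX <- if (layer$pad > 0) dXp[layer$pad_rows, , drop = FALSE] else dXp
      }
      list(dX = dX, grads = grads)
    },
    dw_conv = {
      B <- cache$B
      k2 <- layer$k^2
      dOut <- dY
      dim(dOut) <- c(layer$C, layer$OHOW * B)
      dOutExp <- dOut[rep(seq_len(layer$C), each = k2), , drop = FALSE]
      prod2 <- cache$cols * dOutExp
      dW <- t(matrix(rowSums(prod2), nrow = k2))        # [C, k2]
      grads <- list(W = dW, b = rowSums(dOut))
      dX <- NULL
      if (need_input_grad && layer$need_input_grad) {
        Wexp <- as.vector(t(layer$params$W))
        dCols <- Wexp * dOutExp
        dim(dCols) <- c(length(layer$IDX), B)
        dXp <- as.matrix(layer$scatter %*% dCols)
        dX <- if (layer$pad > 0) dXp[layer$pad_rows, , drop = FALSE] else dXp
      }
      list(dX = dX, grads = grads)
    },
    dense = list(dX = if (need_input_grad) crossprod(layer$params$W, dY),
                 grads = list(W = tcrossprod(dY, cache$X), b = rowSums(dY))),
    relu = , hswish = , hsigmoid =
      list(dX = act_backward(layer$type, cache$X, dY), grads = NULL),
    dropout = list(dX = if (is.null(cache$mask)) dY else dY * cache$mask,
                   grads = NULL),
    avgpool = , gap = list(dX = as.matrix(Matrix::crossprod(layer$P, dY)),
                           grads = NULL),
    affine = {
      rows <- chan_rows(layer$C, layer$OHOW)
      prod <- cache$X * dY
      dim(prod) <- c(layer$C, layer$OHOW * ncol(dY))
      dg <- rowSums(prod)
      dYr <- dY; dim(dYr) <- c(layer$C, layer$OHOW * ncol(dY))
      db <- rowSums(dYr)
      list(dX = if (need_input_grad) dY * layer$params$g[rows],
           grads = list(g = dg, b = db))
    },
    se = {
      B <- cache$B; OHOW <- layer$OHOW; C <- layer$C
      ## gate gradient: dg[c,b] = sum_o X * dY  (channel-fastest layout)
      prod <- cache$X * dY
      dg <- as.matrix(layer$P %*% prod) * OHOW
      ## through hard-sigmoid
      da2 <- dg * ((cache$a2 > -3) & (cache$a2 < 3)) / 6
      gW2 <- tcrossprod(da2, cache$h1); gb2 <- rowSums(da2)
      dh1 <- crossprod(layer$params$W2, da2) * (cache$a1 > 0)
      gW1 <- tcrossprod(dh1, cache$s); gb1 <- rowSums(dh1)
      ds <- crossprod(layer$params$W1, dh1)       # [C, B]
      dX <- dY * cache$gex +
        ds[chan_rows(C, OHOW), , drop = FALSE] / OHOW
      list(dX = dX, grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
    },
    block = {
      n <- length(layer$layers)
      grads <- vector("list", n)
      d <- dY
      for (i in rev(seq_len(n))) {
        need <- need_input_grad || i > 1 || layer$residual
        r <- layer_backward(layer$layers[[i]], cache$caches[[i]], d, need)
        grads[i] <- list(r$grads)   # keep NULL slots (list assignment)
        d <- r$dX
      }
      if (layer$residual) d <- d + dY
      list(dX = d, grads = grads)
    },
    stop("unknown layer type ", layer$type))
}

## Run a sequence of layers.
seq_forward <- function(layers, X, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], X, training)
    X <- r$Y; caches[[i]] <- r$cache
  }
  list(Y = X, caches = caches)
}

seq_backward <- function(layers, caches, dY, need_input_grad = TRUE) {
  n <- length(layers)
  grads <- vector("list", n)
  for (i in rev(seq_len(n))) {
    need <- need_input_grad || i > 1
    r <- layer_backward(layers[[i]], caches[[i]], dY, need)
    grads[i] <- list(r$grads)       # keep NULL slots (list assignment)
    dY <- r$dX
  }
  list(dX = dY, grads = grads)
}

## ---- parameter bookkeeping ------------------------------------------------

## Nested list of all trainable parameters of a layer sequence; used by the
## optimiser and by (de)serialisation.
seq_params <- function(layers) lapply(layers, layer_params1)

layer_params1 <- function(layer) {
  if (layer$type == "block") lapply(layer$layers, layer_params1)
  else layer$params
}

seq_set_params <- function(layers, params) {
  for (i in seq_along(layers)) {
    if (layers[[i]]$type == "block")
      layers[[i]]$layers <- seq_set_params(layers[[i]]$layers, params[[i]])
    else if (!is.null(params[[i]])) layers[[i]]$params <- params[[i]]
  }
  layers
}

## Count of trainable scalars.
count_params <- function(params) {
  if (is.null(params)) return(0)
  if (is.list(params)) return(sum(vapply(params, count_params, numeric(1))))
  length(params)
}

## Recursive AdamW step over parallel (params, grads, m, v) structures.
adamw_step <- function(params, grads, m, v, lr, wd, beta1, beta2, eps, t) {
  if (is.null(params)) return(list(params = NULL, m = NULL, v = NULL))
  if (is.list(params)) {
    out_p <- params; out_m <- m; out_v <- v
    for (i in seq_along(params)) {
      r <- adamw_step(params[[i]], grads[[i]],
                      if (is.null(m)) NULL else m[[i]],
                      if (is.null(v)) NULL else v[[i]],
                      lr, wd, beta1, beta2, eps, t)
      ## list-slot assignment keeps NULL entries in place
      out_p[i] <- list(r$params); out_m[i] <- list(r$m); out_v[i] <- list(r$v)
    }
    return(list(params = out_p, m = out_m, v = out_v))
  }
  if (is.null(m)) { m <- params * 0; v <- params * 0 }
  m <- beta1 * m + (1 - beta1) * grads
  v <- beta2 * v + (1 - beta2) * grads^2
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  params <- params - lr * (mhat / (sqrt(vhat) + eps) + wd * params)
  list(params = params, m = m, v = v)
}
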