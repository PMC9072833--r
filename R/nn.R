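# Minimal convolutional-network engine with hand-derived backpropagation.
# Written in vectorised base R: convolutions are im2col + BLAS matrix
# multiplies, the col2im scatter-add of the backward pass is a cached sparse
# matrix product. Tensors are (H, W, C, B) arrays (column-major, batch last);
# after global average pooling features become (C, B) matrices.
#
# Every layer implements forward(layer, x, training) -> list(out, cache,
# layer) and backward(layer, dout, cache) -> list(dx, grads). Correctness of
# all backward passes is pinned down by finite-difference gradient checks in
# the test suite.

.nn_cache <- new.env(parent = emptyenv())

# im2col gather indices + col2im sparse scatter matrix for one geometry
conv_geometry <- function(H, W, C, k, stride, pad) {
  key <- paste(H, W, C, k, stride, pad, sep = "_")
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  OH <- (Hp - k) %/% stride + 1L
  OW <- (Wp - k) %/% stride + 1L
  # flat 1-based index of (r, c, ch) in the padded sample: r + (c-1)Hp + ch0*HpWp
  off <- as.vector(outer(outer(seq_len(k), (seq_len(k) - 1L) * Hp, `+`),
                         (seq_len(C) - 1L) * (Hp * Wp), `+`))
  corner <- as.vector(outer((seq_len(OH) - 1L) * stride,
                            (seq_len(OW) - 1L) * stride * Hp, `+`))
  idx <- matrix(rep(corner, each = length(off)) + off, nrow = length(off))
  scatter <- Matrix::sparseMatrix(i = as.vector(idx),
                                  j = seq_along(idx), x = 1,
                                  dims = c(Hp * Wp * C, length(idx)))
  geo <- list(Hp = Hp, Wp = Wp, OH = OH, OW = OW, idx = idx,
              scatter = scatter)
  .nn_cache[[key]] <- geo
  geo
}

layer_conv <- function(in_ch, out_ch, k = 3, stride = 1,
                       pad = (k - 1) %/% 2) {
  fan_in <- k * k * in_ch
  list(type = "conv",
       W = matrix(rtrunc_normal(fan_in * out_ch, sqrt(2 / fan_in)),
                  fan_in, out_ch),
       b = numeric(out_ch),
       k = as.integer(k), stride = as.integer(stride), pad = as.integer(pad),
       in_ch = as.integer(in_ch), out_ch = as.integer(out_ch))
}

conv_forward <- function(layer, x, training) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  p <- layer$pad
  geo <- conv_geometry(H, W, C, layer$k, layer$stride, p)
  if (p > 0) {
    xp <- array(0, c(geo$Hp, geo$Wp, C, B))
    xp[p + seq_len(H), p + seq_len(W), , ] <- x
  } else {
    xp <- x
  }
  idxB <- as.vector(outer(as.vector(geo$idx),
                          (seq_len(B) - 1L) * (geo$Hp * geo$Wp * C), `+`))
  Xcol <- matrix(xp[idxB], nrow = nrow(geo$idx))
  M <- crossprod(Xcol, layer$W)
  M <- M + matrix(layer$b, nrow(M), ncol(M), byrow = TRUE)
  dim(M) <- c(geo$OH, geo$OW, B, layer$out_ch)
  out <- aperm(M, c(1, 2, 4, 3))
  list(out = out, layer = layer,
       cache = list(Xcol = Xcol, dims = d, geo = geo))
}

conv_backward <- function(layer, dout, cache) {
  geo <- cache$geo
  d <- cache$dims
  B <- d[4]; p <- layer$pad
  dM <- aperm(dout, c(1, 2, 4, 3))
  dim(dM) <- c(geo$OH * geo$OW * B, layer$out_ch)
  dW <- cache$Xcol %*% dM
  db <- colSums(dM)
  dXcol <- tcrossprod(layer$W, dM) # kkC x (OH*OW*B)
  dim(dXcol) <- c(nrow(geo$idx) * geo$OH * geo$OW, B)
  dxp <- as.matrix(geo$scatter %*% dXcol) # (Hp*Wp*C) x B
  dim(dxp) <- c(geo$Hp, geo$Wp, d[3], B)
  dx <- if (p > 0) {
    dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE]
  } else {
    dxp
  }
  list(dx = dx, grads = list(W = dW, b = db))
}

layer_bn <- function(n_ch, eps = 1e-5, momentum = 0.1) {
  list(type = "bn", gamma = rep(1, n_ch), beta = numeric(n_ch),
       run_mean = numeric(n_ch), run_var = rep(1, n_ch),
       eps = eps, momentum = momentum, n_ch = as.integer(n_ch))
}

bn_forward <- function(layer, x, training) {
  d <- dim(x)
  C <- d[3]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)
  m <- nrow(xm)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    layer$run_mean <- (1 - layer$momentum) * layer$run_mean + layer$momentum * mu
    layer$run_var <- (1 - layer$momentum) * layer$run_var + layer$momentum * v
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
  }
  inv_sd <- 1 / sqrt(v + layer$eps)
  xhat <- (xm - matrix(mu, m, C, byrow = TRUE)) *
    matrix(inv_sd, m, C, byrow = TRUE)
  om <- xhat * matrix(layer$gamma, m, C, byrow = TRUE) +
    matrix(layer$beta, m, C, byrow = TRUE)
  dim(om) <- c(d[1], d[2], d[4], C)
  list(out = aperm(om, c(1, 2, 4, 3)), layer = layer,
       cache = list(xhat = xhat, inv_sd = inv_sd, dims = d))
}

bn_backward <- function(layer, dout, cache) {
  d <- cache$dims
  C <- d[3]
  dm <- matrix(aperm(dout, c(1, 2, 4, 3)), ncol = C)
  m <- nrow(dm)
  xhat <- cache$xhat
  dgamma <- colSums(dm * xhat)
  dbeta <- colSums(dm)
  dxhat <- dm * matrix(layer$gamma, m, C, byrow = TRUE)
  dxm <- matrix(cache$inv_sd, m, C, byrow = TRUE) *
    (dxhat -
       matrix(colMeans(dxhat), m, C, byrow = TRUE) -
       xhat * matrix(colMeans(dxhat * xhat), m, C, byrow = TRUE))
  dim(dxm) <- c(d[1], d[2], d[4], C)
  list(dx = aperm(dxm, c(1, 2, 4, 3)),
       grads = list(gamma = dgamma, beta = dbeta))
}

layer_relu <- function() list(type = "relu")

relu_forward <- function(layer, x, training) {
  list(out = pmax(x, 0), layer = layer, cache = list(mask = x > 0))
}

relu_backward <- function(layer, dout, cache) {
  list(dx = dout * cache$mask, grads = list())
}

layer_maxpool <- function() list(type = "maxpool") # 2x2, stride 2

maxpool_forward <- function(layer, x, training) {
  d <- dim(x)
  if (d[1] %% 2L || d[2] %% 2L) stop("maxpool needs even spatial dims")
  ro <- seq(1, d[1], 2); re <- ro + 1
  co <- seq(1, d[2], 2); ce <- co + 1
  q <- list(x[ro, co, , , drop = FALSE], x[re, co, , , drop = FALSE],
            x[ro, ce, , , drop = FALSE], x[re, ce, , , drop = FALSE])
  out <- pmax(q[[1]], q[[2]], q[[3]], q[[4]])
  taken <- array(FALSE, dim(out))
  masks <- vector("list", 4)
  for (i in 1:4) {
    masks[[i]] <- (q[[i]] == out) & !taken
    taken <- taken | masks[[i]]
  }
  list(out = out, layer = layer, cache = list(masks = masks, dims = d))
}

maxpool_backward <- function(layer, dout, cache) {
  d <- cache$dims
  dx <- array(0, d)
  ro <- seq(1, d[1], 2); re <- ro + 1
  co <- seq(1, d[2], 2); ce <- co + 1
  dx[ro, co, , ] <- dout * cache$masks[[1]]
  dx[re, co, , ] <- dout * cache$masks[[2]]
  dx[ro, ce, , ] <- dout * cache$masks[[3]]
  dx[re, ce, , ] <- dout * cache$masks[[4]]
  list(dx = dx, grads = list())
}

# 3x3 average pool, stride 1, zero padding (self-adjoint linear operator)
layer_avgpool3 <- function() list(type = "avgpool3")

box3 <- function(x) {
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L, d[2] + 2L, d[3], d[4]))
  xp[1 + seq_len(d[1]), 1 + seq_len(d[2]), , ] <- x
  out <- array(0, d)
  for (dr in 0:2) {
    for (dc in 0:2) {
      out <- out + xp[dr + seq_len(d[1]), dc + seq_len(d[2]), , ,
                      drop = FALSE]
    }
  }
  out / 9
}

avgpool3_forward <- function(layer, x, training) {
  list(out = box3(x), layer = layer, cache = list())
}

avgpool3_backward <- function(layer, dout, cache) {
  list(dx = box3(dout), grads = list())
}

layer_gap <- function() list(type = "gap")

gap_forward <- function(layer, x, training) {
  d <- dim(x)
  out <- matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
  list(out = out, layer = layer, cache = list(dims = d))
}

gap_backward <- function(layer, dout, cache) {
  d <- cache$dims
  dx <- array(rep(as.vector(dout), each = d[1] * d[2]) / (d[1] * d[2]), d)
  list(dx = dx, grads = list())
}

layer_dropout <- function(p) list(type = "dropout", p = p)

dropout_forward <- function(layer, x, training) {
  if (!training || layer$p <= 0) {
    return(list(out = x, layer = layer, cache = list(mask = NULL)))
  }
  mask <- matrix((stats::runif(length(x)) >= layer$p) / (1 - layer$p),
                 nrow(x), ncol(x))
  list(out = x * mask, layer = layer, cache = list(mask = mask))
}

dropout_backward <- function(layer, dout, cache) {
  dx <- if (is.null(cache$mask)) dout else dout * cache$mask
  list(dx = dx, grads = list())
}

# Cosine classifier: scores are cosine similarities between the L2-normalised
# feature vector and L2-normalised class weight vectors (scores in [-1, 1];
# the loss applies the logit scale). Keeps margin-based losses well-scaled.
layer_cosine <- function(in_feat, n_class) {
  list(type = "cosine",
       W = matrix(rtrunc_normal(n_class * in_feat, sqrt(2 / in_feat)),
                  n_class, in_feat),
       in_feat = as.integer(in_feat), n_class = as.integer(n_class))
}

cosine_forward <- function(layer, f, training) {
  C <- nrow(f)
  fnorm <- sqrt(colSums(f^2)) + 1e-12
  fn <- f / rep(fnorm, each = C)
  wnorm <- sqrt(rowSums(layer$W^2)) + 1e-12
  Wn <- layer$W / wnorm
  z <- t(Wn %*% fn) # B x S
  list(out = z, layer = layer,
       cache = list(fn = fn, fnorm = fnorm, Wn = Wn, wnorm = wnorm))
}

cosine_backward <- function(layer, dz, cache) {
  C <- nrow(cache$fn)
  dZ <- t(dz) # S x B
  dWn <- dZ %*% t(cache$fn)
  dfn <- crossprod(cache$Wn, dZ) # C x B
  s1 <- colSums(cache$fn * dfn)
  df <- (dfn - cache$fn * rep(s1, each = C)) / rep(cache$fnorm, each = C)
  r1 <- rowSums(cache$Wn * dWn)
  dW <- (dWn - cache$Wn * r1) / cache$wnorm
  list(dx = df, grads = list(W = dW))
}

layer_linear <- function(in_feat, n_class) {
  list(type = "linear",
       W = matrix(rtrunc_normal(n_class * in_feat, sqrt(2 / in_feat)),
                  n_class, in_feat),
       b = numeric(n_class),
       in_feat = as.integer(in_feat), n_class = as.integer(n_class))
}

linear_forward <- function(layer, f, training) {
  z <- t(layer$W %*% f + layer$b)
  list(out = z, layer = layer, cache = list(f = f))
}

linear_backward <- function(layer, dz, cache) {
  dZ <- t(dz)
  list(dx = crossprod(layer$W, dZ),
       grads = list(W = dZ %*% t(cache$f), b = rowSums(dZ)))
}

# Inception-style composite layer: parallel branches (each a list of layers)
# on the same input, outputs concatenated along the channel axis.
layer_inception <- function(branches) {
  list(type = "inception", branches = branches)
}

inception_forward <- function(layer, x, training) {
  outs <- vector("list", length(layer$branches))
  caches <- vector("list", length(layer$branches))
  for (i in seq_along(layer$branches)) {
    r <- net_forward(layer$branches[[i]], x, training)
    outs[[i]] <- r$out
    caches[[i]] <- r$caches
    layer$branches[[i]] <- r$layers
  }
  chans <- vapply(outs, function(o) dim(o)[3], 0)
  d <- dim(outs[[1]])
  out <- array(0, c(d[1], d[2], sum(chans), d[4]))
  at <- 0L
  for (i in seq_along(outs)) {
    out[, , at + seq_len(chans[i]), ] <- outs[[i]]
    at <- at + chans[i]
  }
  list(out = out, layer = layer,
       cache = list(caches = caches, chans = chans))
}

inception_backward <- function(layer, dout, cache) {
  dx <- NULL
  grads <- vector("list", length(layer$branches))
  at <- 0L
  for (i in seq_along(layer$branches)) {
    dsub <- dout[, , at + seq_len(cache$chans[i]), , drop = FALSE]
    at <- at + cache$chans[i]
    r <- net_backward(layer$branches[[i]], cache$caches[[i]], dsub)
    grads[[i]] <- r$grads
    dx <- if (is.null(dx)) r$dx else dx + r$dx
  }
  list(dx = dx, grads = list(branches = grads))
}

.forward_fns <- list(conv = conv_forward, bn = bn_forward,
                     relu = relu_forward, maxpool = maxpool_forward,
                     avgpool3 = avgpool3_forward, gap = gap_forward,
                     dropout = dropout_forward, cosine = cosine_forward,
                     linear = linear_forward, inception = inception_forward)
.backward_fns <- list(conv = conv_backward, bn = bn_backward,
                      relu = relu_backward, maxpool = maxpool_backward,
                      avgpool3 = avgpool3_backward, gap = gap_backward,
                      dropout = dropout_backward, cosine = cosine_backward,
                      linear = linear_backward, inception = inception_backward)

net_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- .forward_fns[[layers[[i]]$type]](layers[[i]], x, training)
    x <- r$out
    caches[[i]] <- r$cache
    layers[[i]] <- r$layer
  }
  list(out = x, caches = caches, layers = layers)
}

net_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- .backward_fns[[layers[[i]]$type]](layers[[i]], dout, caches[[i]])
    grads[[i]] <- r$grads
    dout <- r$dx
  }
  list(dx = dout, grads = grads)
}

# parameter fields subject to weight decay
.decayed <- c("W")

# SGD with momentum; velocities mirror the (possibly nested) layer structure.
sgd_init <- function(layers) {
  lapply(layers, function(l) {
    if (l$type == "inception") {
      list(branches = lapply(l$branches, sgd_init))
    } else {
      vel <- list()
      for (p in intersect(c("W", "b", "gamma", "beta"), names(l))) {
        vel[[p]] <- l[[p]] * 0
      }
      vel
    }
  })
}

sgd_step <- function(layers, grads, vel, lr, momentum, weight_decay) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "inception") {
      for (j in seq_along(l$branches)) {
        r <- sgd_step(l$branches[[j]], grads[[i]]$branches[[j]],
                      vel[[i]]$branches[[j]], lr, momentum, weight_decay)
        l$branches[[j]] <- r$layers
        vel[[i]]$branches[[j]] <- r$vel
      }
      layers[[i]] <- l
    } else {
      for (p in names(vel[[i]])) {
        g <- grads[[i]][[p]]
        if (is.null(g)) next
        if (p %in% .decayed) g <- g + weight_decay * l[[p]]
        vel[[i]][[p]] <- momentum * vel[[i]][[p]] - lr * g
        l[[p]] <- l[[p]] + vel[[i]][[p]]
      }
      layers[[i]] <- l
    }
  }
  list(layers = layers, vel = vel)
}
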