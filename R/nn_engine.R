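# Minimal neural-network engine used by the model builders: valid-mode
# strided 2D convolution via im2col, batch normalization, ReLU, dropout,
# dense layers, MSE / binary cross-entropy losses and the Adam optimizer.
# Everything is plain vectorized R; batches flow as matrices.
#
# Data layout: a single-channel H x W image batch is a matrix N x (H*W)
# with flat index h + H*w (0-based, rows fastest), i.e. the natural
# column-major flattening of an (N, H, W) array. Multi-channel tensors use
# flat index h + H*w + H*W*c. Convolution outputs are produced in
# "patch-major" form, an (N*outH*outW) x nKernels matrix, which is what
# batch norm and ReLU operate on; a regroup step reshapes back to
# channel layout for the next layer.

# im2col gather index: (outH*outW) x (kh*kw*inC) of 1-based flat input
# indices; output position o runs with outH fastest.
convPatchIndex <- function(inH, inW, inC, kh, kw, stride) {
  outH <- (inH - kh) %/% stride + 1L
  outW <- (inW - kw) %/% stride + 1L
  oh <- rep(seq_len(outH) - 1L, times = outW)
  ow <- rep(seq_len(outW) - 1L, each = outH)
  ki <- rep(seq_len(kh) - 1L, times = kw * inC)
  kj <- rep(rep(seq_len(kw) - 1L, each = kh), times = inC)
  kc <- rep(seq_len(inC) - 1L, each = kh * kw)
  h <- outer(oh * stride, ki, "+")      # (ohow) x (khkwC)
  w <- outer(ow * stride, kj, "+")
  idx <- h + inH * w + (inH * inW) * matrix(kc, nrow(h), ncol(h),
                                            byrow = TRUE)
  list(idx = idx + 1L, outH = outH, outW = outW)
}

newConvLayer <- function(inH, inW, inC, nK, kh, kw, stride) {
  pi <- convPatchIndex(inH, inW, inC, kh, kw, stride)
  fanIn <- kh * kw * inC
  list(type = "conv",
       W = matrix(stats::rnorm(fanIn * nK, sd = sqrt(2 / fanIn)), fanIn, nK),
       b = numeric(nK),
       idx = pi$idx, stride = stride, inH = inH, inW = inW, inC = inC,
       outH = pi$outH, outW = pi$outW, nK = nK)
}

newBnLayer <- function(nUnits) {
  list(type = "bn", gamma = rep(1, nUnits), beta = numeric(nUnits),
       runMean = numeric(nUnits), runVar = rep(1, nUnits),
       momentum = 0.9, eps = 1e-5)
}

newDenseLayer <- function(nIn, nOut) {
  list(type = "dense",
       W = matrix(stats::rnorm(nIn * nOut, sd = sqrt(2 / nIn)), nIn, nOut),
       b = numeric(nOut))
}

# Layer forward passes. Each returns list(out, cache); eval mode uses
# running statistics and disables dropout.
layerForward <- function(layer, x, train) {
  switch(layer$type,
    conv = {
      n <- nrow(x)
      ohow <- layer$outH * layer$outW
      m <- x[, as.vector(layer$idx), drop = FALSE]
      dim(m) <- c(n * ohow, ncol(layer$idx))
      out <- m %*% layer$W
      out <- out + rep(layer$b, each = nrow(out))
      list(out = out, cache = list(m = m, n = n))
    },
    regroup = {
      # (N*ohow) x nK  ->  N x (ohow*nK)
      n <- nrow(x) %/% layer$ohow
      dim(x) <- c(n, layer$ohow * layer$nK)
      list(out = x, cache = NULL)
    },
    bn = {
      if (train) {
        mu <- colMeans(x)
        xc <- sweep(x, 2, mu)
        v <- colMeans(xc^2)
        istd <- 1 / sqrt(v + layer$eps)
        xhat <- sweep(xc, 2, istd, "*")
        out <- sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
        list(out = out,
             cache = list(xhat = xhat, istd = istd, mu = mu, v = v))
      } else {
        xhat <- sweep(sweep(x, 2, layer$runMean), 2,
                      1 / sqrt(layer$runVar + layer$eps), "*")
        out <- sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
        list(out = out, cache = NULL)
      }
    },
    relu = {
      mask <- x > 0
      list(out = x * mask, cache = mask)
    },
    dropout = {
      if (train && layer$keep < 1) {
        mask <- matrix(stats::runif(length(x)) < layer$keep, nrow(x)) /
          layer$keep
        list(out = x * mask, cache = mask)
      } else {
        list(out = x, cache = NULL)
      }
    },
    dense = {
      out <- x %*% layer$W
      out <- out + rep(layer$b, each = nrow(out))
      list(out = out, cache = x)
    },
    stop("unknown layer type ", layer$type))
}

# Layer backward passes: return list(dx, grads) where grads mirrors the
# layer's trainable tensors (NULL for parameterless layers).
layerBackward <- function(layer, dout, cache) {
  switch(layer$type,
    conv = {
      dW <- crossprod(cache$m, dout)
      db <- colSums(dout)
      dm <- tcrossprod(dout, layer$W)
      n <- cache$n
      ohow <- layer$outH * layer$outW
      dim(dm) <- c(n, ohow, ncol(layer$idx))
      dx <- matrix(0, n, layer$inH * layer$inW * layer$inC)
      for (c2 in seq_len(ncol(layer$idx))) {
        cols <- layer$idx[, c2]
        dx[, cols] <- dx[, cols] + dm[, , c2]
      }
      list(dx = dx, grads = list(W = dW, b = db))
    },
    regroup = {
      n <- nrow(dout)
      dim(dout) <- c(n * layer$ohow, layer$nK)
      list(dx = dout, grads = NULL)
    },
    bn = {
      dgamma <- colSums(dout * cache$xhat)
      dbeta <- colSums(dout)
      m <- nrow(dout)
      dxhat <- sweep(dout, 2, layer$gamma, "*")
      t1 <- sweep(dxhat, 2, colSums(dxhat) / m)
      t2 <- sweep(cache$xhat, 2, colSums(dxhat * cache$xhat) / m, "*")
      dx <- sweep(t1 - t2, 2, cache$istd, "*")
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    relu = list(dx = dout * cache, grads = NULL),
    dropout = {
      if (is.null(cache)) list(dx = dout, grads = NULL)
      else list(dx = dout * cache, grads = NULL)
    },
    dense = list(dx = tcrossprod(dout, layer$W),
                 grads = list(W = crossprod(cache, dout),
                              b = colSums(dout))),
    stop("unknown layer type ", layer$type))
}

segmentForward <- function(layers, x, train) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    fw <- layerForward(layers[[i]], x, train)
    x <- fw$out
    caches[[i]] <- fw$cache
  }
  list(out = x, caches = caches)
}

segmentBackward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    bw <- layerBackward(layers[[i]], dout, caches[[i]])
    dout <- bw$dx
    grads[i] <- list(bw$grads)
  }
  list(dx = dout, grads = grads)
}

# Update running batch-norm statistics after a training forward pass.
segmentUpdateBnStats <- function(layers, caches) {
  for (i in seq_along(layers)) {
    if (layers[[i]]$type == "bn" && !is.null(caches[[i]])) {
      mom <- layers[[i]]$momentum
      layers[[i]]$runMean <- mom * layers[[i]]$runMean +
        (1 - mom) * caches[[i]]$mu
      layers[[i]]$runVar <- mom * layers[[i]]$runVar +
        (1 - mom) * caches[[i]]$v
    }
  }
  layers
}

# ---------------------------------------------------------------------------
# Adam
# ---------------------------------------------------------------------------

adamInit <- function(layers) {
  lapply(layers, function(l) {
    nm <- intersect(c("W", "b", "gamma", "beta"), names(l))
    if (length(nm) == 0) return(NULL)
    s <- lapply(l[nm], function(p) list(m = p * 0, v = p * 0))
    s
  })
}

adamStep <- function(layers, grads, state, t, lr, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[nm]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[nm]]^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[i]][[nm]] <- layers[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(layers = layers, state = state)
}

countParams <- function(layers) {
  sum(vapply(layers, function(l) {
    nm <- intersect(c("W", "b", "gamma", "beta"), names(l))
    sum(vapply(l[nm], length, integer(1)))
  }, numeric(1)))
}
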