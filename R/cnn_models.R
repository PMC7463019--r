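# Architecture specifications and training for the convolutional models:
# a sequential regressor (two 7x7 stride-2 conv blocks, dense 256/64), a
# sequential classifier (16/32 7x7 and 64 3x3 conv blocks, dense 256/64),
# a two-arm hybrid for paired cell-line/drug images (dense 305/175), and a
# plain dense reference network. All run on the package's own engine.

#' Output size of a valid-mode strided convolution
#'
#' \code{floor((in - kernel) / stride) + 1}.
#'
#' @param inSize input size along one dimension
#' @param kernel kernel size along that dimension
#' @param stride stride (>= 1)
#' @return integer output size
#' @examples
#' convOutputSize(26, 7, 2)  # 10
#' @export
convOutputSize <- function(inSize, kernel, stride = 1) {
  if (kernel > inSize)
    stopf("kernel size %d exceeds input size %d", kernel, inSize)
  if (stride < 1) stopf("stride must be >= 1")
  as.integer((inSize - kernel) %/% stride + 1)
}

#' Specification of one convolutional layer
#'
#' @param nKernels number of kernels (>= 1)
#' @param kernel kernel height and width
#' @param stride stride (>= 1)
#' @param batchNorm follow with batch normalization?
#' @param activation activation function (only \code{"relu"})
#' @return a \code{convLayerSpec} list
#' @export
convLayerSpec <- function(nKernels, kernel = c(7, 7), stride = 2,
                          batchNorm = TRUE, activation = "relu") {
  if (nKernels < 1) stopf("nKernels must be >= 1")
  kernel <- rep(as.integer(kernel), length.out = 2)
  if (any(kernel < 1)) stopf("kernel dimensions must be >= 1")
  if (stride < 1) stopf("stride must be >= 1")
  activation <- match.arg(activation, "relu")
  structure(list(nKernels = as.integer(nKernels), kernel = kernel,
                 stride = as.integer(stride), padding = "valid",
                 batchNorm = batchNorm, activation = activation),
            class = "convLayerSpec")
}

# Validate a conv stack against an input shape; returns the flattened
# output length. Errors name the offending layer.
stackOutputLength <- function(inputShape, stack, armName = "input") {
  h <- inputShape[1]; w <- inputShape[2]
  for (i in seq_along(stack)) {
    cs <- stack[[i]]
    if (cs$kernel[1] > h || cs$kernel[2] > w)
      stopf("%s conv layer %d: kernel %dx%d does not fit input %dx%d",
            armName, i, cs$kernel[1], cs$kernel[2], h, w)
    h <- convOutputSize(h, cs$kernel[1], cs$stride)
    w <- convOutputSize(w, cs$kernel[2], cs$stride)
  }
  nC <- if (length(stack) > 0) stack[[length(stack)]]$nKernels else 1L
  h * w * nC
}

#' Full architecture specification
#'
#' @param inputShapes list of (rows, cols) input shapes, one per arm; a
#'   length-1 shape means a flat (dense-only) input
#' @param convStacks list (one per arm) of lists of [convLayerSpec()]
#' @param denseSizes widths of the dense layers after concatenation
#' @param dropoutKeep retaining probability of the dropout layer before the
#'   output (in (0, 1])
#' @param head \code{"regression"} (linear output) or
#'   \code{"binary_classification"} (sigmoid output)
#' @return an \code{architectureSpec} list
#' @export
architectureSpec <- function(inputShapes, convStacks, denseSizes,
                             dropoutKeep = 0.7,
                             head = c("regression", "binary_classification")) {
  head <- match.arg(head)
  if (dropoutKeep <= 0 || dropoutKeep > 1)
    stopf("dropoutKeep must lie in (0, 1]")
  if (length(denseSizes) < 1) stopf("denseSizes must be nonempty")
  if (length(inputShapes) != length(convStacks))
    stopf("one conv stack per input arm required")
  armNames <- if (length(inputShapes) > 1)
    paste0("arm ", seq_along(inputShapes)) else "input"
  flat <- mapply(function(shape, stack, nm) {
    if (length(shape) == 1) {
      if (length(stack) > 0) stopf("%s: flat input cannot have conv layers", nm)
      shape
    } else stackOutputLength(shape, stack, nm)
  }, inputShapes, convStacks, armNames)
  structure(list(inputShapes = inputShapes, convStacks = convStacks,
                 denseSizes = as.integer(denseSizes),
                 dropoutKeep = dropoutKeep, head = head,
                 flatLengths = as.integer(flat)),
            class = "architectureSpec")
}

#' Sequential CNN regressor specification
#'
#' Two convolutional blocks (default 64 kernels of 7x7, valid border,
#' stride 2, each followed by batch normalization and ReLU), dense layers
#' of 256 and 64 units (each with batch normalization and ReLU), a dropout
#' layer with retaining probability 0.7 before the linear output. Kernel
#' size and stride are configurable so the same stack can be applied to
#' smaller images.
#'
#' @param inputShape (rows, cols) of the input image
#' @param nKernels kernels per conv layer
#' @param kernel kernel size
#' @param stride conv stride
#' @param nConv number of identical conv blocks
#' @param denseSizes dense-layer widths
#' @param dropoutKeep dropout retaining probability
#' @return an \code{architectureSpec}
#' @export
buildRegressorSpec <- function(inputShape, nKernels = 64, kernel = c(7, 7),
                               stride = 2, nConv = 2,
                               denseSizes = c(256, 64), dropoutKeep = 0.7) {
  stack <- replicate(nConv,
                     convLayerSpec(nKernels, kernel, stride),
                     simplify = FALSE)
  architectureSpec(list(inputShape), list(stack), denseSizes, dropoutKeep,
                   "regression")
}

#' Sequential CNN classifier specification
#'
#' Three convolutional blocks of 16 7x7, 32 7x7 and 64 3x3 kernels (batch
#' normalization + ReLU each), dense layers of 256 and 64 units, dropout
#' keep 0.7, sigmoid output.
#'
#' @param inputShape (rows, cols) of the input image
#' @param stride conv stride (default 1)
#' @return an \code{architectureSpec}
#' @export
buildClassifierSpec <- function(inputShape, stride = 1) {
  stack <- list(convLayerSpec(16, c(7, 7), stride),
                convLayerSpec(32, c(7, 7), stride),
                convLayerSpec(64, c(3, 3), stride))
  architectureSpec(list(inputShape), list(stack), c(256, 64), 0.7,
                   "binary_classification")
}

#' Two-arm hybrid CNN specification
#'
#' Separate convolutional arms for cell-line and drug images: each arm has
#' 60 5x5 stride-1, 72 6x6 stride-2 and 72 5x5 kernels, with the last conv
#' layer at stride 2 on the cell arm and stride 1 on the drug arm. The arms
#' are concatenated and followed by dense layers of 305 and 175 units,
#' dropout keep 0.7 and a linear output.
#'
#' @param inputShapeCell,inputShapeDrug (rows, cols) of the two image sets
#' @return an \code{architectureSpec} (arm 1 = cell, arm 2 = drug)
#' @export
buildHybridSpec <- function(inputShapeCell, inputShapeDrug) {
  cellArm <- list(convLayerSpec(60, c(5, 5), 1),
                  convLayerSpec(72, c(6, 6), 2),
                  convLayerSpec(72, c(5, 5), 2))
  drugArm <- list(convLayerSpec(60, c(5, 5), 1),
                  convLayerSpec(72, c(6, 6), 2),
                  convLayerSpec(72, c(5, 5), 1))
  architectureSpec(list(inputShapeCell, inputShapeDrug),
                   list(cellArm, drugArm), c(305, 175), 0.7, "regression")
}

#' Dense reference network specification
#'
#' A plain fully connected network on the raw feature vector, used as the
#' ANN comparator.
#'
#' @param inputLength number of input features
#' @param hidden hidden-layer widths
#' @param dropoutKeep dropout retaining probability
#' @param head output head
#' @return an \code{architectureSpec}
#' @export
buildDenseSpec <- function(inputLength, hidden = c(256, 64),
                           dropoutKeep = 0.7, head = "regression") {
  architectureSpec(list(inputLength), list(list()), hidden, dropoutKeep,
                   head)
}

#' Training configuration
#'
#' @param lr Adam learning rate (default 1e-4)
#' @param epochs maximum epochs
#' @param batchSize minibatch size (default 128)
#' @param seed integer seed (weight init, shuffling, dropout)
#' @param earlyStopPatience epochs without validation improvement before
#'   stopping (best weights are restored)
#' @param verbose print per-epoch losses?
#' @return a \code{trainConfig} list
#' @export
trainConfig <- function(lr = 1e-4, epochs = 50, batchSize = 128, seed = 1L,
                        earlyStopPatience = 20, verbose = FALSE) {
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize), seed = as.integer(seed),
                 earlyStopPatience = as.integer(earlyStopPatience),
                 verbose = verbose),
            class = "trainConfig")
}

# Instantiate engine layers from a spec (weights randomly initialised from
# the current RNG state).
buildNetwork <- function(spec) {
  arms <- vector("list", length(spec$inputShapes))
  for (ai in seq_along(spec$inputShapes)) {
    shape <- spec$inputShapes[[ai]]
    stack <- spec$convStacks[[ai]]
    layers <- list()
    if (length(shape) > 1) {
      h <- shape[1]; w <- shape[2]; ch <- 1L
      for (cs in stack) {
        conv <- newConvLayer(h, w, ch, cs$nKernels, cs$kernel[1],
                             cs$kernel[2], cs$stride)
        layers <- c(layers, list(conv))
        if (cs$batchNorm) layers <- c(layers, list(newBnLayer(cs$nKernels)))
        layers <- c(layers, list(list(type = "relu")),
                    list(list(type = "regroup",
                              ohow = conv$outH * conv$outW, nK = cs$nKernels)))
        h <- conv$outH; w <- conv$outW; ch <- cs$nKernels
      }
    }
    arms[[ai]] <- layers
  }
  joint <- list()
  nIn <- sum(spec$flatLengths)
  for (sz in spec$denseSizes) {
    joint <- c(joint, list(newDenseLayer(nIn, sz), newBnLayer(sz),
                           list(type = "relu")))
    nIn <- sz
  }
  joint <- c(joint, list(list(type = "dropout", keep = spec$dropoutKeep),
                         newDenseLayer(nIn, 1L)))
  list(arms = arms, joint = joint)
}

# Coerce images (ImageSet, 3D array or matrix) to the engine's flat
# N x (H*W) layout and check the shape against the spec's input shape.
armMatrix <- function(images, shape, armName) {
  if (is(images, "ImageSet")) images <- images@pixels
  if (length(shape) == 1) {
    x <- as.matrix(images)
    if (ncol(x) != shape)
      stopf("%s: expected %d features, got %d", armName, shape, ncol(x))
    return(x)
  }
  if (length(dim(images)) == 3) {
    d <- dim(images)
    if (d[2] != shape[1] || d[3] != shape[2])
      stopf("%s: images are %d x %d but the architecture expects %d x %d",
            armName, d[2], d[3], shape[1], shape[2])
    x <- images
    dim(x) <- c(d[1], d[2] * d[3])
    return(x)
  }
  stopf("%s: cannot interpret image input of class %s", armName,
        class(images)[1])
}

modelForward <- function(net, xs, train) {
  armOuts <- vector("list", length(net$arms))
  armCaches <- vector("list", length(net$arms))
  for (ai in seq_along(net$arms)) {
    sf <- segmentForward(net$arms[[ai]], xs[[ai]], train)
    armOuts[[ai]] <- sf$out
    armCaches[[ai]] <- sf$caches
  }
  joined <- do.call(cbind, armOuts)
  jf <- segmentForward(net$joint, joined, train)
  list(out = jf$out, armCaches = armCaches, jointCache = jf$caches,
       armWidths = vapply(armOuts, ncol, integer(1)))
}

#' Train a model from an architecture specification
#'
#' Minibatch Adam with early stopping on validation loss (best-validation
#' weights restored). Regression heads use mean squared error; binary
#' classification uses a sigmoid output with cross-entropy loss. Training
#' is deterministic given the configuration seed.
#'
#' @param spec an \code{architectureSpec}
#' @param images an [ImageSet-class] / array / matrix, or a list of them
#'   (one per arm for the hybrid network)
#' @param targets numeric responses (0/1 labels for classification)
#' @param split list with integer index vectors \code{train} and
#'   \code{validation} (see [trainValTestSplit()])
#' @param cfg a [trainConfig()]
#' @return list with \code{net} (trained weights), \code{spec}, and
#'   \code{history} (data.frame epoch / trainLoss / valLoss)
#' @export
trainModel <- function(spec, images, targets, split, cfg = trainConfig()) {
  stopifnot(inherits(spec, "architectureSpec"))
  if (!is.list(images) || is(images, "ImageSet")) images <- list(images)
  if (length(images) != length(spec$inputShapes))
    stopf("architecture expects %d input set(s), got %d",
          length(spec$inputShapes), length(images))
  armNames <- paste0("arm ", seq_along(images))
  xs <- mapply(armMatrix, images, spec$inputShapes, armNames,
               SIMPLIFY = FALSE)
  n <- nrow(xs[[1]])
  if (length(targets) != n)
    stopf("targets length %d does not match %d samples", length(targets), n)
  trainIdx <- split$train
  valIdx <- split$validation
  if (length(intersect(trainIdx, valIdx)) > 0)
    stopf("train and validation indices overlap")
  classify <- spec$head == "binary_classification"

  lossGrad <- function(z, y) {
    if (classify) {
      p <- stats::plogis(z)
      list(loss = -mean(y * log(pmax(p, 1e-12)) +
                          (1 - y) * log(pmax(1 - p, 1e-12))),
           dz = (p - y) / length(y))
    } else {
      list(loss = mean((z - y)^2), dz = 2 * (z - y) / length(y))
    }
  }
  evalLoss <- function(net, idx) {
    if (length(idx) == 0) return(NA_real_)
    tot <- 0
    for (chunk in split(idx, ceiling(seq_along(idx) / 1024))) {
      xsub <- lapply(xs, function(x) x[chunk, , drop = FALSE])
      z <- modelForward(net, xsub, train = FALSE)$out[, 1]
      tot <- tot + lossGrad(z, targets[chunk])$loss * length(chunk)
    }
    tot / length(idx)
  }

  withSeed(cfg$seed, {
    net <- buildNetwork(spec)
    adamArms <- lapply(net$arms, adamInit)
    adamJoint <- adamInit(net$joint)
    t <- 0L
    best <- list(loss = Inf, net = NULL)
    sinceBest <- 0L
    history <- data.frame(epoch = integer(), trainLoss = numeric(),
                          valLoss = numeric())
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample(trainIdx)
      batches <- split(perm, ceiling(seq_along(perm) / cfg$batchSize))
      epochLoss <- 0
      for (batch in batches) {
        xb <- lapply(xs, function(x) x[batch, , drop = FALSE])
        fw <- modelForward(net, xb, train = TRUE)
        lg <- lossGrad(fw$out[, 1], targets[batch])
        epochLoss <- epochLoss + lg$loss * length(batch)
        # backward
        dout <- matrix(lg$dz, ncol = 1)
        jb <- segmentBackward(net$joint, fw$jointCache, dout)
        net$joint <- segmentUpdateBnStats(net$joint, fw$jointCache)
        t <- t + 1L
        up <- adamStep(net$joint, jb$grads, adamJoint, t, cfg$lr)
        net$joint <- up$layers
        adamJoint <- up$state
        off <- 0L
        for (ai in seq_along(net$arms)) {
          wid <- fw$armWidths[ai]
          dArm <- jb$dx[, off + seq_len(wid), drop = FALSE]
          off <- off + wid
          if (length(net$arms[[ai]]) == 0) next
          ab <- segmentBackward(net$arms[[ai]], fw$armCaches[[ai]], dArm)
          net$arms[[ai]] <- segmentUpdateBnStats(net$arms[[ai]],
                                                 fw$armCaches[[ai]])
          upA <- adamStep(net$arms[[ai]], ab$grads, adamArms[[ai]], t,
                          cfg$lr)
          net$arms[[ai]] <- upA$layers
          adamArms[[ai]] <- upA$state
        }
      }
      trainLoss <- epochLoss / length(trainIdx)
      valLoss <- evalLoss(net, valIdx)
      history <- rbind(history, data.frame(epoch = epoch,
                                           trainLoss = trainLoss,
                                           valLoss = valLoss))
      if (!is.finite(trainLoss))
        stopf("non-finite training loss at epoch %d", epoch)
      if (cfg$verbose)
        message(sprintf("epoch %d train %.5f val %.5f", epoch, trainLoss,
                        valLoss))
      monitor <- if (is.na(valLoss)) trainLoss else valLoss
      if (monitor < best$loss - 1e-12) {
        best <- list(loss = monitor, net = net)
        sinceBest <- 0L
      } else {
        sinceBest <- sinceBest + 1L
        if (sinceBest >= cfg$earlyStopPatience) break
      }
    }
    if (!is.null(best$net)) net <- best$net
    structure(list(net = net, spec = spec, history = history,
                   config = cfg),
              class = "refinedModel")
  })
}

#' Predict from a trained model
#'
#' Evaluation-mode forward pass (batch-norm running statistics, no
#' dropout), so predictions do not depend on the batch size. Classifier
#' heads return probabilities in [0, 1].
#'
#' @param model a model returned by [trainModel()]
#' @param images input images (same form as in training)
#' @param batchSize evaluation batch size
#' @return numeric prediction vector
#' @export
predictModel <- function(model, images, batchSize = 1024) {
  stopifnot(inherits(model, "refinedModel"))
  spec <- model$spec
  if (!is.list(images) || is(images, "ImageSet")) images <- list(images)
  xs <- mapply(armMatrix, images, spec$inputShapes,
               paste0("arm ", seq_along(images)), SIMPLIFY = FALSE)
  n <- nrow(xs[[1]])
  out <- numeric(n)
  for (chunk in split(seq_len(n), ceiling(seq_len(n) / batchSize))) {
    xsub <- lapply(xs, function(x) x[chunk, , drop = FALSE])
    z <- modelForward(model$net, xsub, train = FALSE)$out[, 1]
    out[chunk] <- z
  }
  if (spec$head == "binary_classification") stats::plogis(out) else out
}

#' Trainable parameter counts per layer
#'
#' Introspection helper: for each layer with trainable tensors, its type
#' and parameter count.
#'
#' @param model a trained model, or the result of building a spec
#' @return data.frame with segment, layer index, type and nParams
#' @export
modelParameterCounts <- function(model) {
  net <- if (inherits(model, "refinedModel")) model$net else model
  rows <- list()
  segs <- c(lapply(seq_along(net$arms), function(i)
    list(name = paste0("arm", i), layers = net$arms[[i]])),
    list(list(name = "joint", layers = net$joint)))
  for (seg in segs) {
    for (i in seq_along(seg$layers)) {
      l <- seg$layers[[i]]
      nm <- intersect(c("W", "b", "gamma", "beta"), names(l))
      if (length(nm) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        segment = seg$name, layer = i, type = l$type,
        nParams = sum(vapply(l[nm], length, integer(1))))
    }
  }
  do.call(rbind, rows)
}
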