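## The two-class AlexNet-architecture quality network.
##
## The architecture follows the classic eight-learnable-layer design:
## five convolutions (the 2nd, 4th and 5th with two filter groups, which
## is what their printed kernel depths of 48/192/192 imply), cross-channel
## response normalisation after conv1/conv2, overlapping 3x3/stride-2 max
## pooling, and three fully connected layers with dropout, ending in a
## two-way softmax head.  Forward and backward passes run through the
## compiled kernels in src/convops.cpp; the fully connected algebra stays
## in R where it is a plain BLAS matrix product.

IMAGENET_MEAN <- c(0.485, 0.456, 0.406)
IMAGENET_STD <- c(0.229, 0.224, 0.225)

#' AlexNet architecture description
#'
#' Layer-by-layer specification of the network: names, kernel counts,
#' kernel sizes, strides, padding and group structure, ending in a
#' two-class softmax head.
#'
#' @param nClasses number of output classes (default 2).
#' @return ordered list of layer descriptors.
#' @export
alexNetSpec <- function(nClasses = 2L) {
  list(
    list(name = "conv1", type = "conv", kernels = 96L,
         size = c(11L, 11L, 3L), stride = 4L, pad = 0L, groups = 1L),
    list(name = "relu1", type = "relu"),
    list(name = "norm1", type = "lrn", n = 5L, alpha = 1e-4, beta = 0.75,
         k = 2),
    list(name = "pool1", type = "maxpool", size = 3L, stride = 2L),
    list(name = "conv2", type = "conv", kernels = 256L,
         size = c(5L, 5L, 48L), stride = 1L, pad = 2L, groups = 2L),
    list(name = "relu2", type = "relu"),
    list(name = "norm2", type = "lrn", n = 5L, alpha = 1e-4, beta = 0.75,
         k = 2),
    list(name = "pool2", type = "maxpool", size = 3L, stride = 2L),
    list(name = "conv3", type = "conv", kernels = 384L,
         size = c(3L, 3L, 256L), stride = 1L, pad = 1L, groups = 1L),
    list(name = "relu3", type = "relu"),
    list(name = "conv4", type = "conv", kernels = 384L,
         size = c(3L, 3L, 192L), stride = 1L, pad = 1L, groups = 2L),
    list(name = "relu4", type = "relu"),
    list(name = "conv5", type = "conv", kernels = 256L,
         size = c(3L, 3L, 192L), stride = 1L, pad = 1L, groups = 2L),
    list(name = "relu5", type = "relu"),
    list(name = "pool5", type = "maxpool", size = 3L, stride = 2L),
    list(name = "fc6", type = "fc", units = 4096L, inputs = 9216L),
    list(name = "relu6", type = "relu"),
    list(name = "drop6", type = "dropout", p = 0.5),
    list(name = "fc7", type = "fc", units = 4096L, inputs = 4096L),
    list(name = "relu7", type = "relu"),
    list(name = "drop7", type = "dropout", p = 0.5),
    list(name = "fc8", type = "fc", units = as.integer(nClasses),
         inputs = 4096L),
    list(name = "softmax", type = "softmax"))
}

#' Spatial output size of a valid/padded convolution or pooling
#'
#' @param inSize input height/width.
#' @param k kernel size.
#' @param stride stride.
#' @param pad zero padding on each side.
#' @return output height/width.
#' @export
convOutSize <- function(inSize, k, stride, pad = 0) {
  (inSize + 2 * pad - k) %/% stride + 1
}

heInitMat <- function(nOut, nIn) {
  matrix(stats::rnorm(nOut * nIn, sd = sqrt(2 / nIn)), nOut, nIn)
}

initParams <- function(spec, seed, headOnly = FALSE, existing = NULL) {
  set.seed(as.integer(seed))
  params <- if (is.null(existing)) list() else existing
  for (layer in spec) {
    if (layer$type == "conv") {
      nIn <- prod(layer$size[1:2]) * layer$size[3]
      if (!headOnly) {
        params[[layer$name]] <- list(W = heInitMat(layer$kernels, nIn),
                                     b = numeric(layer$kernels))
      }
    } else if (layer$type == "fc") {
      if (!headOnly || layer$name == "fc8") {
        params[[layer$name]] <- list(W = heInitMat(layer$units, layer$inputs),
                                     b = numeric(layer$units))
      }
    }
  }
  params
}

#' Build the two-class quality network
#'
#' With `pretrained = TRUE` the convolutional and fc6/fc7 parameters are
#' loaded from a locally stored parameter file (an RDS holding the named
#' weight list, see [saveModel()]) pointed to by
#' `options(ecgsqa.alexnet_weights = "<path>")`, and only the replaced
#' two-way head is initialised from `seed`.  With `pretrained = FALSE`
#' the whole network is seeded with He-scaled Gaussian weights.
#'
#' @param pretrained load backbone weights from the configured local store.
#' @param seed integer seed for the (head) initialisation.
#' @return a [QualityModel-class].
#' @export
buildModel <- function(pretrained = FALSE, seed = 1L) {
  spec <- alexNetSpec(2L)
  if (pretrained) {
    path <- getOption("ecgsqa.alexnet_weights", "")
    if (!nzchar(path) || !file.exists(path))
      stop("pretrained backbone weights not found; download an AlexNet ",
           "parameter export once, save it with saveModel(), and point ",
           "options(ecgsqa.alexnet_weights=) at the file")
    stored <- readRDS(path)
    params <- initParams(spec, seed, headOnly = TRUE, existing = stored$params)
  } else {
    params <- initParams(spec, seed, headOnly = FALSE)
  }
  new("QualityModel", spec = spec, params = params,
      classOrder = c("HIGH", "LOW"), lossTrace = numeric(0))
}

#' Numerically stable softmax
#'
#' @param z numeric vector of logits.
#' @return probabilities summing to 1.
#' @export
softmaxProbs <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

## 227 x 227 x 3 rgb in [0,1] -> channel-standardised network input
imageToInput <- function(img) {
  a <- if (is(img, "ScalogramImage")) img@rgb else img
  if (!identical(dim(a), c(227L, 227L, 3L)))
    stop("network input must be a 227 x 227 x 3 image")
  for (c in 1:3) a[, , c] <- (a[, , c] - IMAGENET_MEAN[c]) / IMAGENET_STD[c]
  a
}

## full forward pass; returns logits plus (optionally) every intermediate
## needed by the backward pass.  masks: list(drop6=, drop7=) or NULL for
## inference scaling (inverted dropout: identity at inference).
alexForward <- function(params, x, keepCache = FALSE, masks = NULL,
                        upTo = "fc8") {
  cache <- list(x0 = x)
  c1 <- conv_forward(x, params$conv1$W, params$conv1$b, 11L, 4L, 0L, 1L)
  r1 <- pmax(c1, 0)
  n1 <- lrn_forward(r1, 5L, 1e-4, 0.75, 2)
  p1 <- maxpool_forward(n1$y, 3L, 2L)
  c2 <- conv_forward(p1$y, params$conv2$W, params$conv2$b, 5L, 1L, 2L, 2L)
  r2 <- pmax(c2, 0)
  n2 <- lrn_forward(r2, 5L, 1e-4, 0.75, 2)
  p2 <- maxpool_forward(n2$y, 3L, 2L)
  c3 <- conv_forward(p2$y, params$conv3$W, params$conv3$b, 3L, 1L, 1L, 1L)
  r3 <- pmax(c3, 0)
  c4 <- conv_forward(r3, params$conv4$W, params$conv4$b, 3L, 1L, 1L, 2L)
  r4 <- pmax(c4, 0)
  c5 <- conv_forward(r4, params$conv5$W, params$conv5$b, 3L, 1L, 1L, 2L)
  r5 <- pmax(c5, 0)
  p5 <- maxpool_forward(r5, 3L, 2L)
  f5 <- as.numeric(p5$y)
  if (upTo == "pool5") {
    if (keepCache) stop("cache is only kept for full passes")
    return(list(features = f5))
  }
  h6 <- as.numeric(params$fc6$W %*% f5) + params$fc6$b
  r6 <- pmax(h6, 0)
  d6 <- if (is.null(masks)) r6 else r6 * masks$drop6
  h7 <- as.numeric(params$fc7$W %*% d6) + params$fc7$b
  r7 <- pmax(h7, 0)
  if (upTo == "fc7") {
    if (keepCache) stop("cache is only kept for full passes")
    return(list(features = r7))
  }
  d7 <- if (is.null(masks)) r7 else r7 * masks$drop7
  z <- as.numeric(params$fc8$W %*% d7) + params$fc8$b
  if (keepCache) {
    cache <- list(x0 = x, c1 = c1, r1 = r1, n1 = n1, p1 = p1, c2 = c2,
                  r2 = r2, n2 = n2, p2 = p2, c3 = c3, r3 = r3, c4 = c4,
                  r4 = r4, c5 = c5, r5 = r5, p5 = p5, f5 = f5, h6 = h6,
                  d6 = d6, h7 = h7, d7 = d7, masks = masks)
    list(logits = z, cache = cache)
  } else {
    list(logits = z)
  }
}

## gradients of the cross-entropy loss w.r.t. every parameter, given the
## softmax-minus-onehot logit gradient dz
alexBackward <- function(params, cache, dz) {
  g <- list()
  g$fc8 <- list(W = outer(dz, cache$d7), b = dz)
  dd7 <- as.numeric(t(params$fc8$W) %*% dz)
  if (!is.null(cache$masks)) dd7 <- dd7 * cache$masks$drop7
  dh7 <- dd7 * (cache$h7 > 0)
  g$fc7 <- list(W = outer(dh7, cache$d6), b = dh7)
  dd6 <- as.numeric(t(params$fc7$W) %*% dh7)
  if (!is.null(cache$masks)) dd6 <- dd6 * cache$masks$drop6
  dh6 <- dd6 * (cache$h6 > 0)
  g$fc6 <- list(W = outer(dh6, cache$f5), b = dh6)
  df5 <- as.numeric(t(params$fc6$W) %*% dh6)
  dp5 <- array(df5, dim = dim(cache$p5$y))
  dr5 <- maxpool_backward(cache$p5$argmax, dp5, nrow(cache$r5[, , 1]),
                          ncol(cache$r5[, , 1]))
  dc5 <- dr5 * (cache$c5 > 0)
  b5 <- conv_backward(cache$r4, params$conv5$W, dc5, 3L, 1L, 1L, 2L)
  g$conv5 <- list(W = b5$dW, b = as.numeric(b5$db))
  dc4 <- b5$dx * (cache$c4 > 0)
  b4 <- conv_backward(cache$r3, params$conv4$W, dc4, 3L, 1L, 1L, 2L)
  g$conv4 <- list(W = b4$dW, b = as.numeric(b4$db))
  dc3 <- b4$dx * (cache$c3 > 0)
  b3 <- conv_backward(cache$p2$y, params$conv3$W, dc3, 3L, 1L, 1L, 1L)
  g$conv3 <- list(W = b3$dW, b = as.numeric(b3$db))
  dn2 <- maxpool_backward(cache$p2$argmax, b3$dx, nrow(cache$r2[, , 1]),
                          ncol(cache$r2[, , 1]))
  dr2 <- lrn_backward(cache$r2, cache$n2$denom, dn2, 5L, 1e-4, 0.75, 2)
  dc2 <- dr2 * (cache$c2 > 0)
  b2 <- conv_backward(cache$p1$y, params$conv2$W, dc2, 5L, 1L, 2L, 2L)
  g$conv2 <- list(W = b2$dW, b = as.numeric(b2$db))
  dn1 <- maxpool_backward(cache$p1$argmax, b2$dx, nrow(cache$r1[, , 1]),
                          ncol(cache$r1[, , 1]))
  dr1 <- lrn_backward(cache$r1, cache$n1$denom, dn1, 5L, 1e-4, 0.75, 2)
  dc1 <- dr1 * (cache$c1 > 0)
  b1 <- conv_backward(cache$x0, params$conv1$W, dc1, 11L, 4L, 0L, 1L)
  g$conv1 <- list(W = b1$dW, b = as.numeric(b1$db))
  g
}

#' Fine-tuning configuration
#'
#' @param learningRate SGD learning rate (default 0.0001).
#' @param momentum SGD momentum in [0, 1) (default 0.9).
#' @param epochs training epochs.
#' @param batchSize minibatch size.
#' @param seed RNG seed for shuffling, dropout and head initialisation.
#' @param freeze `"none"` for full fine-tuning; `"conv"` to freeze the
#'   convolutional base and train the fully connected head (fc6, fc7, fc8)
#'   on cached pool5 activations — the frozen-base fast mode; or
#'   `"features"` to train only the two-way fc8 head on cached fc7
#'   activations.
#' @param dropout dropout probability for drop6/drop7 during full
#'   fine-tuning.
#' @return a `TrainConfig` list.
#' @export
trainConfig <- function(learningRate = 1e-4, momentum = 0.9, epochs = 10L,
                        batchSize = 32L, seed = 1L,
                        freeze = c("none", "conv", "features"),
                        dropout = 0.5) {
  freeze <- match.arg(freeze)
  stopifnot(learningRate >= 0, momentum >= 0, momentum < 1, epochs >= 1,
            batchSize >= 1, dropout >= 0, dropout < 1)
  structure(list(learningRate = learningRate, momentum = momentum,
                 epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 seed = as.integer(seed), freeze = freeze, dropout = dropout),
            class = "TrainConfig")
}

#' Fast frozen-base fine-tuning preset
#'
#' Freezes everything below the classification layer and trains the
#' two-way fc8 head on fc7 activations extracted once, with a learning
#' rate suited to head convergence in a few dozen epochs.  The heavier
#' `freeze = "conv"` policy (training fc6/fc7/fc8 on pool5 activations)
#' and full fine-tuning remain available through [trainConfig()].
#'
#' @param epochs,learningRate,batchSize,seed overrides of the preset.
#' @return a `TrainConfig` list with `freeze = "features"`.
#' @export
fastTrainConfig <- function(epochs = 60L, learningRate = 0.001,
                            batchSize = 32L, seed = 1L) {
  trainConfig(learningRate = learningRate, momentum = 0.9, epochs = epochs,
              batchSize = batchSize, seed = seed, freeze = "features")
}

## feature matrix for a list of images: pool5 (n x 9216) or fc7 (n x 4096)
extractFeatures <- function(params, images, at = c("fc7", "pool5")) {
  at <- match.arg(at)
  nf <- if (at == "fc7") 4096L else 9216L
  t(vapply(images, function(im) {
    alexForward(params, imageToInput(im), upTo = at)$features
  }, numeric(nf)))
}

#' Fine-tune the quality network
#'
#' Stochastic gradient descent with momentum on the two-class
#' cross-entropy loss.  With `cfg$freeze == "features"` only the fc8 head
#' is updated, on fc7 activations extracted once; with `"none"` the whole
#' network is trained by backpropagation.  The per-epoch mean training
#' loss is stored in the returned model's `lossTrace`.
#'
#' @param model a [QualityModel-class].
#' @param images list of [ScalogramImage-class] (or 227x227x3 arrays).
#' @param labels `HIGH`/`LOW` label per image; both classes must be
#'   present.
#' @param cfg a [trainConfig()].
#' @param features optional cache of frozen-layer activations (one row per
#'   image): fc7 activations for `freeze = "features"`, pool5 activations
#'   for `freeze = "conv"` (see [extractFrozenFeatures()]).  Passing the
#'   cache skips the forward passes through the frozen base, which is what
#'   makes repeated holdout runs affordable; it never changes the result.
#' @return the updated [QualityModel-class].
#' @export
finetune <- function(model, images, labels, cfg = trainConfig(),
                     features = NULL) {
  stopifnot(is(model, "QualityModel"), inherits(cfg, "TrainConfig"))
  labels <- as.character(labels)
  if (length(images) != length(labels)) stop("one label per image required")
  if (length(unique(labels)) < 2)
    stop("both classes must be present in the training set")
  if (!all(labels %in% model@classOrder)) stop("labels must be HIGH/LOW")
  y <- match(labels, model@classOrder)       # 1 = HIGH, 2 = LOW
  n <- length(images)
  params <- model@params
  set.seed(cfg$seed)

  if (cfg$freeze %in% c("conv", "features")) {
    ## frozen base: cache activations once, train the head by batched SGD
    at <- if (cfg$freeze == "conv") "pool5" else "fc7"
    feats <- if (is.null(features)) extractFeatures(params, images, at)
             else features
    if (nrow(feats) != n) stop("feature cache does not match the image set")
    trained <- if (cfg$freeze == "conv") c("fc6", "fc7", "fc8") else "fc8"
    W <- lapply(trained, function(nm) params[[nm]]$W)
    b <- lapply(trained, function(nm) params[[nm]]$b)
    vW <- lapply(W, function(w) w * 0)
    vb <- lapply(b, function(x) x * 0)
    nl <- length(trained)
    useDrop <- cfg$freeze == "conv" && cfg$dropout > 0
    rowSoftmax <- function(Z) {
      E <- exp(Z - apply(Z, 1, max))
      E / rowSums(E)
    }
    lossTrace <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1, n, by = cfg$batchSize)) {
        idx <- ord[start:min(start + cfg$batchSize - 1, n)]
        B <- length(idx)
        A <- feats[idx, , drop = FALSE]
        acts <- vector("list", nl)   # post-dropout input of each layer
        pre <- vector("list", nl)    # pre-activation of each layer
        masks <- vector("list", nl)
        for (l in seq_len(nl)) {
          acts[[l]] <- A
          Z <- A %*% t(W[[l]]) + matrix(b[[l]], B, length(b[[l]]),
                                        byrow = TRUE)
          pre[[l]] <- Z
          if (l < nl) {
            A <- pmax(Z, 0)
            if (useDrop) {
              masks[[l]] <- matrix(
                (stats::runif(length(A)) >= cfg$dropout) / (1 - cfg$dropout),
                B, ncol(A))
              A <- A * masks[[l]]
            }
          }
        }
        P <- rowSoftmax(pre[[nl]])
        losses <- c(losses,
                    -mean(log(P[cbind(seq_len(B), y[idx])] + 1e-12)))
        dZ <- P
        dZ[cbind(seq_len(B), y[idx])] <- dZ[cbind(seq_len(B), y[idx])] - 1
        dZ <- dZ / B
        for (l in rev(seq_len(nl))) {
          gW <- t(dZ) %*% acts[[l]]
          gb <- colSums(dZ)
          if (l > 1) {
            dA <- dZ %*% W[[l]]
            if (useDrop) dA <- dA * masks[[l - 1]]
            dZ <- dA * (pre[[l - 1]] > 0)
          }
          vW[[l]] <- cfg$momentum * vW[[l]] - cfg$learningRate * gW
          vb[[l]] <- cfg$momentum * vb[[l]] - cfg$learningRate * gb
          W[[l]] <- W[[l]] + vW[[l]]
          b[[l]] <- b[[l]] + vb[[l]]
        }
      }
      lossTrace[ep] <- mean(losses)
    }
    for (l in seq_len(nl)) params[[trained[l]]] <- list(W = W[[l]], b = b[[l]])
  } else {
    vel <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
    lossTrace <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1, n, by = cfg$batchSize)) {
        idx <- ord[start:min(start + cfg$batchSize - 1, n)]
        grads <- NULL
        batchLoss <- 0
        for (i in idx) {
          masks <- list(
            drop6 = (stats::runif(4096) >= cfg$dropout) / (1 - cfg$dropout),
            drop7 = (stats::runif(4096) >= cfg$dropout) / (1 - cfg$dropout))
          fwd <- alexForward(params, imageToInput(images[[i]]),
                             keepCache = TRUE, masks = masks)
          p <- softmaxProbs(fwd$logits)
          batchLoss <- batchLoss - log(p[y[i]] + 1e-12)
          dz <- p; dz[y[i]] <- dz[y[i]] - 1
          g <- alexBackward(params, fwd$cache, dz)
          grads <- if (is.null(grads)) g else
            mapply(function(a, bb) list(W = a$W + bb$W, b = a$b + bb$b),
                   grads, g, SIMPLIFY = FALSE)
        }
        losses <- c(losses, batchLoss / length(idx))
        for (nm in names(grads)) {
          vel[[nm]]$W <- cfg$momentum * vel[[nm]]$W -
            cfg$learningRate * grads[[nm]]$W / length(idx)
          vel[[nm]]$b <- cfg$momentum * vel[[nm]]$b -
            cfg$learningRate * grads[[nm]]$b / length(idx)
          params[[nm]]$W <- params[[nm]]$W + vel[[nm]]$W
          params[[nm]]$b <- params[[nm]]$b + vel[[nm]]$b
        }
      }
      lossTrace[ep] <- mean(losses)
    }
  }
  new("QualityModel", spec = model@spec, params = params,
      classOrder = model@classOrder, lossTrace = lossTrace)
}

## run the fully connected stack from a cached activation matrix
headForward <- function(params, feats, from = c("fc7", "pool5")) {
  from <- match.arg(from)
  A <- feats
  if (from == "pool5") {
    for (nm in c("fc6", "fc7")) {
      Z <- A %*% t(params[[nm]]$W)
      A <- pmax(sweep(Z, 2, params[[nm]]$b, "+"), 0)
    }
  }
  sweep(A %*% t(params$fc8$W), 2, params$fc8$b, "+")
}

#' Extract frozen-layer activations for an image set
#'
#' Returns the activation matrix (one row per image) at the boundary the
#' given freeze policy trains above: fc7 activations for
#' `freeze = "features"`, pool5 activations for `freeze = "conv"`.  The
#' matrix can be passed to [finetune()] and [predictQuality()] as a cache
#' so that repeated holdout runs forward each image through the frozen
#' base only once.
#'
#' @param model a [QualityModel-class].
#' @param images list of [ScalogramImage-class] / 227x227x3 arrays.
#' @param freeze the freeze policy the cache is meant for.
#' @return numeric matrix, images by activations.
#' @export
extractFrozenFeatures <- function(model, images,
                                  freeze = c("features", "conv")) {
  freeze <- match.arg(freeze)
  extractFeatures(model@params, images,
                  at = if (freeze == "conv") "pool5" else "fc7")
}

#' Classify scalogram images
#'
#' @param model a [QualityModel-class].
#' @param images a single image or a list of [ScalogramImage-class] /
#'   227x227x3 arrays.
#' @param features optional cached activation matrix from
#'   [extractFrozenFeatures()] (with matching `freeze`); when supplied,
#'   only the layers above the cache boundary are evaluated.
#' @param freeze boundary of the supplied cache.
#' @return data.frame with `p_high`, `p_low` (softmax probabilities summing
#'   to 1) and the hard `label` (`HIGH` when `p_high > 0.5`; an exact tie
#'   goes to `LOW`).
#' @export
predictQuality <- function(model, images, features = NULL,
                           freeze = c("features", "conv")) {
  stopifnot(is(model, "QualityModel"))
  freeze <- match.arg(freeze)
  if (is.null(features)) {
    if (!is.list(images)) images <- list(images)
    features <- extractFeatures(model@params, images, at = "fc7")
    freeze <- "features"
  }
  Z <- headForward(model@params, features,
                   from = if (freeze == "conv") "pool5" else "fc7")
  probs <- t(apply(Z, 1, softmaxProbs))
  data.frame(p_high = probs[, 1], p_low = probs[, 2],
             label = ifelse(probs[, 1] > 0.5, "HIGH", "LOW"),
             stringsAsFactors = FALSE)
}

#' Save / load a quality model
#'
#' Models are serialised as a plain named parameter list together with the
#' architecture description.
#'
#' @param model a [QualityModel-class].
#' @param path RDS path.
#' @return `path` invisibly ([saveModel()]); the restored
#'   [QualityModel-class] ([loadModel()]).
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "QualityModel"))
  saveRDS(list(spec = model@spec, params = model@params,
               classOrder = model@classOrder), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  s <- readRDS(path)
  new("QualityModel", spec = s$spec, params = s$params,
      classOrder = s$classOrder, lossTrace = numeric(0))
}
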