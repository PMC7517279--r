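test_that("the instantiated architecture matches the layer enumeration", {
  spec <- alexNetSpec()
  names_ <- vapply(spec, `[[`, "", "name")
  expect_identical(names_,
    c("conv1", "relu1", "norm1", "pool1", "conv2", "relu2", "norm2",
      "pool2", "conv3", "relu3", "conv4", "relu4", "conv5", "relu5",
      "pool5", "fc6", "relu6", "drop6", "fc7", "relu7", "drop7", "fc8",
      "softmax"))
  conv <- function(nm) spec[[which(names_ == nm)]]
  expect_equal(conv("conv1")[c("kernels", "stride")],
               list(kernels = 96L, stride = 4L))
  expect_equal(conv("conv1")$size, c(11L, 11L, 3L))
  expect_equal(conv("conv2")$kernels, 256L)
  expect_equal(conv("conv2")$size, c(5L, 5L, 48L))   # two-group structure
  expect_equal(conv("conv2")$groups, 2L)
  expect_equal(conv("conv3")$size, c(3L, 3L, 256L))
  expect_equal(conv("conv3")$kernels, 384L)
  expect_equal(conv("conv4")$kernels, 384L)
  expect_equal(conv("conv4")$size, c(3L, 3L, 192L))
  expect_equal(conv("conv5")$kernels, 256L)
  expect_equal(conv("conv5")$size, c(3L, 3L, 192L))
  expect_equal(conv("fc8")$units, 2L)                # two-class head

  model <- buildModel(seed = 1)
  ## conv1 parameter count: 11*11*3*96 weights + 96 biases
  expect_equal(length(model@params$conv1$W), 34848L)
  expect_equal(length(model@params$conv1$b), 96L)
  ## fc8 parameter count: 4096*2 + 2
  expect_equal(length(model@params$fc8$W), 8192L)
  expect_equal(length(model@params$fc8$b), 2L)
  ## conv1 output spatial size by convolution arithmetic
  expect_equal(convOutSize(227, 11, 4, 0), 55)
  expect_equal(convOutSize(55, 3, 2), 27)            # pool1
  expect_equal(convOutSize(27, 3, 2), 13)            # pool2
})

test_that("seeded builds are identical; different seeds differ", {
  m1 <- buildModel(seed = 7)
  m2 <- buildModel(seed = 7)
  expect_identical(m1@params$fc8$W, m2@params$fc8$W)
  expect_identical(m1@params$conv3$W, m2@params$conv3$W)
  m3 <- buildModel(seed = 8)
  expect_false(identical(m1@params$fc8$W, m3@params$fc8$W))
  expect_error(buildModel(pretrained = TRUE), "weights not found")
})

test_that("softmax matches brute-force exponentiation and ties go to LOW", {
  set.seed(2)
  for (i in 1:20) {
    z <- rnorm(2, sd = 5)
    p <- softmaxProbs(z)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(p, exp(z) / sum(exp(z)), tolerance = 1e-9)
  }
  ## equal logits -> exact tie -> LOW by the tie rule
  m <- buildModel(seed = 1)
  m@params$fc8$W[] <- 0
  m@params$fc8$b[] <- c(1.3, 1.3)
  pred <- predictQuality(m, uniformImage(0.5))
  expect_equal(pred$p_high, 0.5)
  expect_equal(pred$label, "LOW")
})

test_that("network forward shapes follow the convolution arithmetic", {
  m <- buildModel(seed = 3)
  x <- ecgsqa:::imageToInput(uniformImage(0.4))
  c1 <- ecgsqa:::conv_forward(x, m@params$conv1$W, m@params$conv1$b, 11L, 4L, 0L, 1L)
  expect_equal(dim(c1), c(55L, 55L, 96L))          # (227-11)/4 + 1 = 55
  p1 <- ecgsqa:::maxpool_forward(ecgsqa:::lrn_forward(pmax(c1, 0), 5L, 1e-4, 0.75,
                                             2)$y, 3L, 2L)
  expect_equal(dim(p1$y), c(27L, 27L, 96L))
  f <- ecgsqa:::alexForward(m@params, x, upTo = "fc7")
  expect_length(f$features, 4096L)
  full <- ecgsqa:::alexForward(m@params, x)
  expect_length(full$logits, 2L)
})

test_that("layer gradients agree with central finite differences", {
  set.seed(9)
  relerr <- function(a, b) {
    max(abs(as.numeric(a) - as.numeric(b))) / max(max(abs(b)), 1e-8)
  }
  numgrad <- function(f, p, eps = 1e-6) {
    vapply(seq_along(p), function(i) {
      p1 <- p; p2 <- p
      p1[i] <- p1[i] + eps; p2[i] <- p2[i] - eps
      (f(p1) - f(p2)) / (2 * eps)
    }, numeric(1))
  }
  ## grouped strided padded convolution
  x <- array(rnorm(7 * 7 * 4), c(7, 7, 4))
  W <- matrix(rnorm(6 * 18), 6, 18)
  b <- rnorm(6)
  y <- ecgsqa:::conv_forward(x, W, b, 3L, 2L, 1L, 2L)
  dy <- array(rnorm(length(y)), dim(y))
  g <- ecgsqa:::conv_backward(x, W, dy, 3L, 2L, 1L, 2L)
  loss <- function(xx, WW, bb) sum(ecgsqa:::conv_forward(xx, WW, bb, 3L, 2L, 1L, 2L) * dy)
  expect_lt(relerr(g$dx, numgrad(function(p) loss(array(p, dim(x)), W, b),
                                 as.numeric(x))), 1e-6)
  expect_lt(relerr(g$dW, numgrad(function(p) loss(x, matrix(p, 6, 18), b),
                                 as.numeric(W))), 1e-6)
  expect_lt(relerr(g$db, numgrad(function(p) loss(x, W, p), b)), 1e-6)
  ## cross-channel response normalisation
  x2 <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  fw <- ecgsqa:::lrn_forward(x2, 5L, 1e-2, 0.75, 2)
  dy2 <- array(rnorm(length(fw$y)), dim(fw$y))
  dx2 <- ecgsqa:::lrn_backward(x2, fw$denom, dy2, 5L, 1e-2, 0.75, 2)
  l2 <- function(p) sum(ecgsqa:::lrn_forward(array(p, dim(x2)), 5L, 1e-2,
                                             0.75, 2)$y * dy2)
  expect_lt(relerr(dx2, numgrad(l2, as.numeric(x2))), 1e-6)
  ## overlapping max pooling
  x3 <- array(rnorm(7 * 7 * 3), c(7, 7, 3))
  fw3 <- ecgsqa:::maxpool_forward(x3, 3L, 2L)
  dy3 <- array(rnorm(length(fw3$y)), dim(fw3$y))
  dx3 <- ecgsqa:::maxpool_backward(fw3$argmax, dy3, 7L, 7L)
  l3 <- function(p) sum(ecgsqa:::maxpool_forward(array(p, dim(x3)), 3L, 2L)$y * dy3)
  expect_lt(relerr(dx3, numgrad(l3, as.numeric(x3))), 1e-6)
})

test_that("the full-network gradient matches finite differences at spot checks", {
  set.seed(17)
  m <- buildModel(seed = 17)
  x <- ecgsqa:::imageToInput(array(runif(227 * 227 * 3), c(227, 227, 3)))
  fwd <- ecgsqa:::alexForward(m@params, x, keepCache = TRUE)
  p <- softmaxProbs(fwd$logits)
  dz <- p; dz[1] <- dz[1] - 1                       # loss = -log p_HIGH
  g <- ecgsqa:::alexBackward(m@params, fwd$cache, dz)
  lossAt <- function(params) {
    z <- ecgsqa:::alexForward(params, x)$logits
    -log(softmaxProbs(z)[1])
  }
  eps <- 1e-5
  for (layer in c("conv1", "conv3", "conv5", "fc6", "fc8")) {
    i <- sample(length(m@params[[layer]]$W), 1)
    p1 <- m@params; p1[[layer]]$W[i] <- p1[[layer]]$W[i] + eps
    p2 <- m@params; p2[[layer]]$W[i] <- p2[[layer]]$W[i] - eps
    num <- (lossAt(p1) - lossAt(p2)) / (2 * eps)
    expect_equal(g[[layer]]$W[i], num, tolerance = 1e-3)
  }
})

test_that("zero learning rate leaves weights untouched with a flat loss", {
  imgs <- c(lapply(1:3, function(i) uniformImage(0.1 + 0.02 * i)),
            lapply(1:3, function(i) uniformImage(0.8 + 0.02 * i)))
  labels <- rep(c("LOW", "HIGH"), each = 3)
  m <- buildModel(seed = 4)
  cfg <- trainConfig(learningRate = 0, epochs = 3, batchSize = 2, seed = 4,
                     freeze = "features")
  trained <- finetune(m, imgs, labels, cfg)
  expect_identical(trained@params$fc8$W, m@params$fc8$W)
  expect_equal(diff(range(trained@lossTrace)), 0, tolerance = 1e-12)
  expect_error(finetune(m, imgs, rep("HIGH", 6), cfg), "both classes")
  expect_error(finetune(m, lapply(1:6, function(i) array(0, c(10, 10, 3))),
                        labels, cfg), "227")
})

test_that("trivially separable images are learned to 100% training accuracy", {
  set.seed(6)
  n <- 100                                 # 50 per class
  imgs <- c(lapply(seq_len(n / 2), function(i)
              uniformImage(runif(1, 0.05, 0.25))),
            lapply(seq_len(n / 2), function(i)
              uniformImage(runif(1, 0.75, 0.95))))
  labels <- rep(c("LOW", "HIGH"), each = n / 2)
  m <- buildModel(seed = 6)
  trained <- finetune(m, imgs, labels, fastTrainConfig(epochs = 10, seed = 6))
  ## training loss strictly decreases over the first 3 epochs
  expect_lt(trained@lossTrace[2], trained@lossTrace[1])
  expect_lt(trained@lossTrace[3], trained@lossTrace[2])
  pred <- predictQuality(trained, imgs)
  expect_equal(mean(pred$label == labels), 1.0)
  expect_true(all(abs(pred$p_high + pred$p_low - 1) < 1e-6))
  ## batching contract: prediction independent of order
  pred2 <- predictQuality(trained, rev(imgs))
  expect_equal(rev(pred2$p_high), pred$p_high, tolerance = 1e-12)
})

test_that("checkpoints round-trip through save and load", {
  dir <- withr::local_tempdir()
  m <- buildModel(seed = 2)
  p <- file.path(dir, "model.rds")
  saveModel(m, p)
  m2 <- loadModel(p)
  expect_identical(m2@params$fc8$W, m@params$fc8$W)
  expect_identical(m2@classOrder, m@classOrder)
  img <- uniformImage(0.3)
  expect_equal(predictQuality(m2, img)$p_high, predictQuality(m, img)$p_high)
})
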