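# small architecture used throughout: keeps training in milliseconds
smallConfig <- function(lens, E, ...) {
  modelConfig(lens, E, denseSizes = c(32L, 16L), batchSize = 32L,
              patience = 0L, ...)
}

# two-modality toy task: labels depend linearly on modality "a" only
toyData <- function(n = 200, L = 20, E = 3L, seed = 1) {
  set.seed(seed)
  Xa <- matrix(runif(n * L), n, L)
  Xb <- matrix(runif(n * L), n, L)
  W <- matrix(rnorm(L * E), L, E)
  y <- max.col(Xa %*% W) - 1L
  list(Xs = list(a = Xa, b = Xb), y = y, E = E)
}

test_that("submodel dimensions follow the valid-convolution arithmetic", {
  spec <- submodelSpec(1144L)
  d <- submodelDims(spec)
  expect_equal(d$convLength, 1144L - 5L + 1L)   # L - k + 1
  expect_equal(d$flatSize, 1140L)
  expect_equal(d$outputWidth, 256L)             # last default dense size
  expect_error(submodelSpec(4L, convKernel = 5L), "exceeds")
  expect_error(submodelSpec(10L, dropout = 1), "dropout")
  expect_error(submodelSpec(10L, denseSizes = integer()), "non-empty")
  d2 <- submodelDims(submodelSpec(100L, convFilters = 3L, convKernel = 7L))
  expect_equal(d2$flatSize, (100L - 7L + 1L) * 3L)
  d3 <- submodelDims(submodelSpec(50L, useConv = FALSE))
  expect_equal(d3$flatSize, 50L)
})

test_that("built model has softmax outputs and the closed-form parameter count", {
  lens <- c(a = 40L, b = 40L, c = 40L, d = 40L)
  E <- 65L
  cfg <- modelConfig(lens, E, denseSizes = c(24L, 16L))
  m <- buildModel(cfg)
  # closed form: per branch conv (k*f + f) + dense (in*out + out + 2*out
  # for batch-norm scale/shift), head ((4*16)*E + E)
  Lc <- 40L - 5L + 1L
  perBranch <- (5 + 1) + (Lc * 24 + 24 + 48) + (24 * 16 + 16 + 32)
  expect_equal(countParameters(m), 4L * perBranch + (4L * 16L) * E + E)

  set.seed(31)
  Xs <- lapply(lens, function(L) matrix(runif(3 * L), 3, L))
  P <- predictProba(m, Xs)
  expect_equal(dim(P), c(3L, 65L))
  expect_equal(rowSums(P), rep(1, 3), tolerance = 1e-5)

  # empty batch
  P0 <- predictProba(m, lapply(lens, function(L) matrix(0, 0, L)))
  expect_equal(dim(P0), c(0L, 65L))

  # shape mismatch names the expected length
  expect_error(predictProba(m, lapply(lens, function(L) matrix(0, 2, L + 1))),
               "expects input length")

  # single modality reduces to submodel + head
  m1 <- buildModel(modelConfig(c(a = 40L), 5L, denseSizes = 8L))
  expect_equal(dim(predictProba(m1, list(a = matrix(runif(80), 2)))), c(2L, 5L))
})

test_that("inference is deterministic and duplicated inputs give identical rows", {
  lens <- c(a = 30L, b = 30L)
  m <- buildModel(smallConfig(lens, 4L))
  set.seed(32)
  x <- runif(30)
  Xs <- list(a = rbind(x, x), b = rbind(x, x))
  P1 <- predictProba(m, Xs)
  P2 <- predictProba(m, Xs)
  expect_equal(P1, P2, tolerance = 1e-12)
  expect_equal(P1[1, ], P1[2, ], tolerance = 1e-12)
})

test_that("epochs = 0 returns the initialized model unchanged", {
  d <- toyData(50)
  cfg <- smallConfig(c(a = 20L, b = 20L), d$E, epochs = 0L)
  m0 <- buildModel(cfg)
  m1 <- trainModel(m0, d$Xs, d$y)
  expect_identical(m1$params, m0$params)
})

test_that("training fits separable data and the loss trend decreases", {
  d <- toyData(300, E = 2L, seed = 5)
  cfg <- smallConfig(c(a = 20L, b = 20L), 2L, epochs = 50L,
                     learningRate = 3e-3)
  m <- trainModel(buildModel(cfg), d$Xs, d$y)
  acc <- accuracyScore(d$y, predictEvents(m, d$Xs))
  expect_gte(acc, 0.99)
  h <- m$history$trainLoss
  expect_lt(median(tail(h, 5)), median(head(h, 5)))
})

test_that("training is reproducible for a fixed seed", {
  d <- toyData(120)
  cfg <- smallConfig(c(a = 20L, b = 20L), d$E, epochs = 5L, seed = 77L)
  m1 <- trainModel(buildModel(cfg), d$Xs, d$y)
  m2 <- trainModel(buildModel(cfg), d$Xs, d$y)
  expect_equal(predictProba(m1, d$Xs), predictProba(m2, d$Xs),
               tolerance = 1e-12)
})

test_that("average fusion trains and yields simplex rows", {
  d <- toyData(150)
  cfg <- modelConfig(c(a = 20L, b = 20L), d$E, fusion = "average",
                     denseSizes = c(16L, 8L), epochs = 15L, batchSize = 32L,
                     patience = 0L)
  m <- trainModel(buildModel(cfg), d$Xs, d$y)
  P <- predictProba(m, d$Xs)
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-5)
  expect_gt(accuracyScore(d$y, max.col(P) - 1L), 1 / d$E)
})

test_that("the compiled training path matches the R reference loop", {
  # deterministic setting: no dropout, one batch per epoch, so the two
  # paths consume no divergent randomness; the compiled path runs in
  # single precision, hence the tolerance
  set.seed(34)
  n <- 48L; L <- 24L; E <- 4L
  Xs <- list(a = matrix(runif(n * L), n, L), b = matrix(runif(n * L), n, L))
  y <- sample(0:(E - 1L), n, replace = TRUE)
  cfg <- modelConfig(c(a = L, b = L), E, denseSizes = c(12L, 6L),
                     dropout = 0, epochs = 8L, batchSize = n,
                     patience = 0L, seed = 11L)
  m0 <- buildModel(cfg)
  fitC <- ddiFusion:::withSeed(12L, ddiFusion:::.cnnTrainConcat(
    unname(Xs), y, unname(cfg$submodels), m0$params, list(), integer(),
    E, 8L, n, 1e-3, 0L, FALSE))
  fitR <- ddiFusion:::withSeed(12L, ddiFusion:::trainLoopR(
    m0$params, cfg, Xs, y, E, NULL, NULL, FALSE, FALSE))
  expect_equal(fitC$history[, 2], fitR$history$trainLoss, tolerance = 1e-4)
  expect_equal(fitC$params$head$W, fitR$params$head$W, tolerance = 1e-4)
  expect_equal(fitC$params$branches[[1]]$dense[[1]]$W,
               fitR$params$branches[[1]]$dense[[1]]$W, tolerance = 1e-4)
})

test_that("gradients match numerical differentiation on a tiny network", {
  set.seed(33)
  lens <- c(a = 9L)
  cfg <- modelConfig(lens, 3L, denseSizes = c(4L), dropout = 0,
                     batchNorm = FALSE, epochs = 1L)
  m <- buildModel(cfg)
  X <- list(a = matrix(runif(5 * 9), 5, 9))
  y <- c(0L, 1L, 2L, 1L, 0L)
  Yhot <- oneHotLocal(y, 3L)
  lossAt <- function(params) {
    P <- ddiFusion:::modelForward(params, cfg, X, training = FALSE)$P
    -mean(log(rowSums(P * Yhot)))
  }
  fwd <- ddiFusion:::modelForward(m$params, cfg, X, training = TRUE)
  gr <- ddiFusion:::modelBackward(m$params, cfg, fwd, Yhot)
  eps <- 1e-6
  # spot-check one coordinate of every parameter tensor
  # positional indices: the gradient structure mirrors the parameters
  # but its branch list is unnamed
  checks <- list(
    list(path = list("branches", 1L, "convW"), idx = 2L),
    list(path = list("branches", 1L, "convB"), idx = 1L),
    list(path = list("branches", 1L, "dense", 1L, "W"), idx = 7L),
    list(path = list("branches", 1L, "dense", 1L, "b"), idx = 2L),
    list(path = list("head", "W"), idx = 5L),
    list(path = list("head", "b"), idx = 3L))
  pluck <- function(x, path) { for (k in path) x <- x[[k]]; x }
  bump <- function(x, path, idx, delta) {
    if (length(path) == 0L) { x[idx] <- x[idx] + delta; return(x) }
    x[[path[[1]]]] <- bump(x[[path[[1]]]], path[-1], idx, delta)
    x
  }
  for (ck in checks) {
    num <- (lossAt(bump(m$params, ck$path, ck$idx, eps)) -
            lossAt(bump(m$params, ck$path, ck$idx, -eps))) / (2 * eps)
    ana <- pluck(gr, ck$path)[ck$idx]
    expect_equal(ana, num, tolerance = 1e-4)
  }
})

test_that("model checkpoints round-trip through save/load", {
  d <- toyData(80)
  cfg <- smallConfig(c(a = 20L, b = 20L), d$E, epochs = 3L)
  m <- trainModel(buildModel(cfg), d$Xs, d$y)
  base <- tempfile("ckpt")
  saveModel(m, base)
  m2 <- loadModel(base)
  expect_equal(predictProba(m2, d$Xs), predictProba(m, d$Xs),
               tolerance = 1e-12)
  expect_equal(m2$config$nEvents, m$config$nEvents)
})
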