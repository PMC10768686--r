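test_that("architectures have the specified shapes and parameter counts", {
  m <- buildPatchCnn(seed = 1)
  X <- matrix(rnorm(2 * 27 * 45), 2)
  out <- dcsd:::modelForward(m, X)$pred
  expect_identical(dim(out), c(2L, 45L))
  # closed-form count: conv1 45*45+45, conv2/conv3 1215*45+45 each,
  # dense 45*200+200 and 200*45+45, batch norm 2*(45*3 + 200)
  expect_identical(modelParameterCount(m),
                   (45L * 45L + 45L) + 2L * (1215L * 45L + 45L) +
                     (45L * 200L + 200L) + (200L * 45L + 45L) +
                     2L * (3L * 45L + 200L))
  mm <- buildVoxelMlp(seed = 1)
  expect_identical(dim(dcsd:::modelForward(mm, X)$pred), c(2L, 45L))
  expect_identical(modelParameterCount(mm),
                   (45L * 400L + 400L) + (400L * 45L + 45L) +
                     (45L * 200L + 200L) + (200L * 45L + 45L))
  # deterministic initialization
  expect_identical(buildPatchCnn(seed = 5)$params,
                   buildPatchCnn(seed = 5)$params)
  # zeroed output layer maps anything to zero
  mz <- buildVoxelMlp(seed = 1)
  mz$params$W4[] <- 0; mz$params$b4[] <- 0
  expect_true(all(dcsd:::modelForward(mz, X)$pred == 0))
})

test_that("backpropagation matches numerical gradients", {
  set.seed(7)
  nCh <- 5; N <- 4
  X <- matrix(rnorm(N * 27 * nCh), N)
  Y <- matrix(rnorm(N * nCh), N)
  for (m in list(buildPatchCnn(nCoef = nCh, hidden = 6, seed = 2),
                 buildPatchCnn(nCoef = nCh, hidden = 6, seed = 2,
                               shortcut = "avgpool"),
                 buildVoxelMlp(nCoef = nCh, widths = c(9L, 5L, 7L, 5L),
                               seed = 2))) {
    fw <- dcsd:::modelForward(m, X, training = TRUE)
    gr <- dcsd:::modelBackward(m, fw$cache, 2 * (fw$pred - Y) / N)
    lossAt <- function(mod) {
      mod$bn <- lapply(mod$bn, dcsd:::bnStateClone)
      lossFit(dcsd:::modelForward(mod, X, training = TRUE)$pred, Y)
    }
    eps <- 1e-5
    for (nm in names(m$params)) {
      i <- sample(length(m$params[[nm]]), 1)
      up <- m; up$params[[nm]][i] <- up$params[[nm]][i] + eps
      dn <- m; dn$params[[nm]][i] <- dn$params[[nm]][i] - eps
      num <- (lossAt(up) - lossAt(dn)) / (2 * eps)
      ana <- gr[[nm]][i]
      expect_lt(abs(num - ana), 1e-4 * max(1, abs(num)))
    }
  }
})

test_that("losses match a naive double-loop oracle", {
  set.seed(9)
  for (rep in 1:5) {
    N <- sample(2:6, 1)
    pred <- matrix(rnorm(N * 45), N)
    truth <- matrix(rnorm(N * 45), N)
    oracle <- 0
    for (i in seq_len(N)) for (j in 1:45)
      oracle <- oracle + (truth[i, j] - pred[i, j])^2
    oracle <- oracle / N
    expect_equal(lossFit(pred, truth), oracle, tolerance = 1e-12)
    expect_equal(lossPair(pred, truth), oracle, tolerance = 1e-12)
  }
  z <- matrix(0, 1, 45)
  expect_identical(lossFit(z, z), 0)
  one <- z; one[1, 7] <- 1
  expect_identical(lossFit(one, z), 1)
  u <- z; u[1, 3] <- 1; v <- z; v[1, 3] <- -1
  expect_identical(lossPair(u, v), 4)
  expect_identical(lossTotal(2, 3, lossWeights(1, 1)), 5)
  expect_identical(lossTotal(2, 3, lossWeights(1, 0)), 2)
  expect_identical(lossTotal(2, 3, lossWeights(0, 0)), 0)
  expect_error(lossWeights(-1, 0), "non-negative")
})

test_that("triplet streams have the contracted shapes and determinism", {
  st <- fxStudy(1)
  labeled <- list(list(signals = list(st$signalScan), label = st$labels,
                       mask = st$split$train))
  paired <- list(list(u = st$signalScan, v = st$signalRescan,
                      mask = st$split$train))
  stream <- sampleTriplets(labeled, paired, batchSize = 8, seed = 3)
  b <- stream(1)
  expect_identical(dim(b$X), c(8L, 27L * 45L))
  expect_identical(dim(b$Y), c(8L, 45L))
  expect_identical(dim(b$U), dim(b$X))
  expect_identical(dim(b$V), dim(b$X))
  b2 <- sampleTriplets(labeled, paired, batchSize = 8, seed = 3)(1)
  expect_identical(b, b2)
  expect_false(identical(stream(2)$X, b$X))
  # paired patches come from identical voxel coordinates: with the rescan
  # field replaced by the scan field, U and V are identical
  pairedSame <- list(list(u = st$signalScan, v = st$signalScan,
                          mask = st$split$train))
  bs <- sampleTriplets(labeled, pairedSame, batchSize = 8, seed = 3)(1)
  expect_identical(bs$U, bs$V)
})

test_that("short training reduces both loss terms (smoke test)", {
  st <- fxStudy(1)
  labeled <- list(list(signals = list(st$signalScan), label = st$labels,
                       mask = st$split$train))
  paired <- list(list(u = st$signalScan, v = st$signalRescan,
                      mask = st$split$train))
  stream <- sampleTriplets(labeled, paired, batchSize = 32, seed = 5)
  m <- trainModel(buildPatchCnn(seed = 1), stream, lossWeights(1, 1),
                  nSteps = 60)
  h <- m$history
  expect_lt(mean(tail(h$loss1, 10)), h$loss1[1])
  expect_lt(mean(tail(h$loss2, 10)), mean(head(h$loss2, 5)))
  # bit-reproducible given identical seeds
  m2 <- trainModel(buildPatchCnn(seed = 1), stream, lossWeights(1, 1),
                   nSteps = 60)
  expect_identical(m$params, m2$params)
  expect_identical(m$history, m2$history)
})

test_that("finetuning updates only the dense head", {
  st <- fxStudy(1)
  labeled <- list(list(signals = list(st$signalScan), label = st$labels,
                       mask = st$split$train))
  stream <- sampleTriplets(labeled, NULL, batchSize = 16, seed = 2)
  m0 <- buildPatchCnn(seed = 3)
  head <- denseHeadParameters(m0)
  m1 <- trainModel(m0, stream, lossWeights(1, 0), nSteps = 10,
                   trainable = head)
  frozen <- setdiff(names(m0$params), head)
  for (nm in frozen) expect_identical(m1$params[[nm]], m0$params[[nm]])
  expect_false(identical(m1$params$Wd2, m0$params$Wd2))
})

test_that("volume prediction respects mask, borders and translation", {
  m <- buildPatchCnn(seed = 4)
  # spatially constant input: constant prediction everywhere, including
  # border voxels (reflect padding preserves constancy)
  set.seed(12)
  v <- rnorm(45)
  arr <- array(rep(v, each = 6 * 6 * 6), c(6, 6, 6, 45))
  f <- SHField(arr, kind = "signal")
  mask <- array(TRUE, c(6, 6, 6))
  pred <- coefArray(predictVolume(m, f, mask))
  flat <- matrix(pred, ncol = 45)
  expect_lt(max(abs(sweep(flat, 2, flat[1, ]))), 1e-9)
  # empty mask: zero field
  p0 <- predictVolume(m, f, array(FALSE, c(6, 6, 6)))
  expect_true(all(coefArray(p0) == 0))
  # masked voxels only
  m1 <- array(FALSE, c(6, 6, 6)); m1[3, 3, 3] <- TRUE
  p1 <- coefArray(predictVolume(m, f, m1))
  expect_true(all(p1[2, 2, 2, ] == 0))
  expect_false(all(p1[3, 3, 3, ] == 0))
})

test_that("model JSON round trip preserves weights and predictions", {
  m <- buildPatchCnn(seed = 6)
  X <- matrix(rnorm(3 * 27 * 45), 3)
  path <- withr::local_tempfile(fileext = ".json")
  saveModel(m, path, meta = list(alpha = 1, beta = 0.5, seed = 6))
  m2 <- loadModel(path)
  expect_equal(m2$params, m$params, tolerance = 1e-12)
  expect_equal(dcsd:::modelForward(m2, X)$pred,
               dcsd:::modelForward(m, X)$pred, tolerance = 1e-12)
  expect_equal(m2$meta$beta, 0.5)
})
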