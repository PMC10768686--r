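test_that("electrostatic schemes are uniform, well conditioned, reproducible", {
  sch <- fxScheme96()
  expect_identical(nDirections(sch), 96L)
  expect_gt(minPairwiseAngle(sch), 5)
  B <- shDesignMatrix(directions(sch), 8)
  expect_lt(kappa(B, exact = TRUE), 10)
  again <- makeGradientScheme(96, bValue = 2000, nB0 = 3, seed = 7)
  expect_identical(directions(sch), directions(again))
  expect_identical(nDirections(makeGradientScheme(6, 1000, 0, seed = 1)), 6L)
  expect_error(makeGradientScheme(4), "at least 6")
})

test_that("multi-tensor signal matches closed forms", {
  sch <- fxScheme96()
  s0 <- 2.5
  # pure isotropic voxel
  iso <- simulateSignal(fiberConfig(matrix(numeric(0), 0, 3), numeric(0)),
                        sch, s0 = s0)
  expect_equal(iso[1:3], rep(s0, 3))
  expect_equal(iso[-(1:3)],
               rep(s0 * exp(-2000 * defaultTissue()$dIso), 96))
  # single fiber along z sampled along z
  ez <- c(0, 0, 1)
  schZ <- GradientScheme(rbind(ez, c(1, 0, 0)), 2000, 0L)
  sig <- simulateSignal(fiberConfig(ez, 1), schZ, s0 = 1)
  ev <- defaultTissue()$eigenvalues
  expect_equal(sig[1], exp(-2000 * ev[1]), tolerance = 1e-12)
  expect_equal(sig[2], exp(-2000 * ev[2]), tolerance = 1e-12)
  # mixture linearity: two fibers at 90 degrees = average of singles
  cfgA <- fiberConfig(c(1, 0, 0), 1)
  cfgB <- fiberConfig(c(0, 1, 0), 1)
  cfgAB <- fiberConfig(rbind(c(1, 0, 0), c(0, 1, 0)), c(0.5, 0.5))
  expect_equal(simulateSignal(cfgAB, sch),
               (simulateSignal(cfgA, sch) + simulateSignal(cfgB, sch)) / 2,
               tolerance = 1e-12)
  expect_error(fiberConfig(c(1, 0, 0), 1.2), "fractions")
})

test_that("order-8 SH captures the b=2000 tensor signal to <2% off-sample", {
  schFit <- fxScheme96()
  schTest <- makeGradientScheme(40, 2000, 0, seed = 99)
  for (cfg in list(fiberConfig(c(0, 0, 1), 0.7),
                   fiberConfig(rbind(c(1, 0, 0), c(0, 1, 0)), c(0.4, 0.4)))) {
    ampFit <- simulateSignal(cfg, schFit)[-(1:3)]
    cc <- fitSH(ampFit, directions(schFit), 8)
    pred <- shToAmplitudes(cc, directions(schTest))
    truth <- simulateSignal(cfg, schTest)
    expect_lt(max(abs(pred - truth) / truth), 0.02)
  }
})

test_that("ground-truth fODF matches a per-voxel dense-quadrature oracle", {
  # oracle: project the polished canonical lobe numerically after rotating
  # it to the fiber direction (independent of the addition-theorem path)
  zon <- dcsd:::watsonLobeZonal(8, 50)
  idx <- shIndexTable(8)
  zCoef <- numeric(45)
  zCoef[idx$m == 0] <- zon
  mu <- c(1, 2, -0.5); mu <- mu / sqrt(sum(mu^2))
  R <- dcsd:::rotationToZ(mu) # maps mu -> z
  # rotated-lobe amplitude evaluated pointwise, then projected numerically
  lobeAt <- function(G) shToAmplitudes(zCoef, G %*% t(R))
  oracle <- 0.7 * oracleShProject(lobeAt, 8)
  got <- groundTruthFodf(fiberConfig(mu, 0.7), 8, 50)
  # isotropic remainder only shifts the order-0 term
  expect_equal(got[-1], oracle[-1], tolerance = 1e-6)
})

test_that("ground-truth fODF symmetry and rotation invariants hold", {
  # axial fiber along z: no m != 0 terms
  cz <- groundTruthFodf(fiberConfig(c(0, 0, 1), 0.8))
  idx <- shIndexTable(8)
  expect_lt(max(abs(cz[idx$m != 0])), 1e-12)
  # two orthogonal equal lobes: equal amplitude at both peaks
  cx <- groundTruthFodf(fiberConfig(rbind(c(1, 0, 0), c(0, 1, 0)),
                                    c(0.4, 0.4)))
  amps <- shToAmplitudes(cx, rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(amps[1], amps[2], tolerance = 1e-12)
  # per-order energy is rotation invariant
  cc1 <- groundTruthFodf(fiberConfig(c(1, 0, 0), 0.7))
  cc2 <- groundTruthFodf(fiberConfig(c(0, 0, 1), 0.7))
  e1 <- tapply(cc1^2, idx$k, sum)
  e2 <- tapply(cc2^2, idx$k, sum)
  expect_equal(e1, e2, tolerance = 1e-10)
})

test_that("ground-truth lobes are nonnegative and peak on the fibers", {
  probe <- dcsd:::fibonacciSphereSym(3000)
  for (cfg in list(fiberConfig(c(0, 0, 1), 0.7),
                   fiberConfig(rbind(c(1, 0, 0), c(0, 1, 0)), c(0.4, 0.4)))) {
    cc <- groundTruthFodf(cfg)
    expect_gt(min(shToAmplitudes(cc, probe)), -1e-6)
    pk <- peakDirections(cc)
    expect_identical(nrow(pk), nrow(cfg$directions))
    for (i in seq_len(nrow(cfg$directions))) {
      errs <- apply(pk, 1, function(p) dcsd:::angleDeg(p, cfg$directions[i, ]))
      expect_lt(min(errs), 2)
    }
  }
})

test_that("Rician noise has the documented statistics and determinism", {
  s <- rep(0, 1e6)
  noisy <- addRicianNoise(s, snr = 10, seed = 3, s0 = 1)
  sigma <- 1 / 10
  # zero signal: Rayleigh with mean sigma * sqrt(pi/2)
  expect_equal(mean(noisy), sigma * sqrt(pi / 2), tolerance = 0.01)
  expect_identical(addRicianNoise(s[1:100], 10, seed = 3),
                   addRicianNoise(s[1:100], 10, seed = 3))
  x <- runif(50)
  expect_identical(addRicianNoise(x, 1e12, seed = 1), x)
  expect_error(addRicianNoise(x, -1, seed = 1), "positive")
})

test_that("phantom construction is deterministic with both region types", {
  ph <- fxPhantom16()
  expect_gt(sum(wmMask(ph)), 200)
  nPop <- vapply(seq_len(prod(ph@shape)), function(i) {
    cfg <- ph@fiberConfigs[[i]]
    if (is.null(cfg)) 0L else nrow(cfg$directions)
  }, integer(1))
  expect_gt(sum(nPop == 1L), 100) # coherent single-fiber region
  expect_gt(sum(nPop == 2L), 20)  # 90-degree crossing region
  # crossing voxels really hold orthogonal populations
  i2 <- which(nPop == 2L)[1]
  cfg <- ph@fiberConfigs[[i2]]
  ang <- dcsd:::angleDeg(cfg$directions[1, ], cfg$directions[2, ])
  expect_gt(ang, 80); expect_lt(ang, 100)
  expect_identical(coefArray(gtFodf(makePhantom(c(16, 16, 16), seed = 1))),
                   coefArray(gtFodf(ph)))
  expect_error(makePhantom(c(6, 16, 16)), "at least 8")
})

test_that("fiber orientations vary smoothly within bundles", {
  ph <- fxPhantom16()
  sf <- singleFiberMask(ph)
  vox <- which(sf, arr.ind = TRUE)
  worst <- 0
  for (i in seq_len(nrow(vox))) {
    x <- vox[i, 1]; y <- vox[i, 2]; z <- vox[i, 3]
    if (x < 16 && sf[x + 1, y, z]) {
      a <- fiberConfigAt(ph, x, y, z)$directions[1, ]
      b <- fiberConfigAt(ph, x + 1, y, z)$directions[1, ]
      worst <- max(worst, dcsd:::angleDeg(a, b))
    }
  }
  expect_lt(worst, 15)
})

test_that("scan/rescan pairs degrade gracefully under the perturbation model", {
  ph <- fxPhantom16()
  sch <- fxScheme96()
  # degenerate perturbation with a forced shared noise stream: identical
  pert0 <- rescanPerturbation(snrScan = 30, snrRescan = 30,
                              biasAmplitude = 0, schemeRotationDeg = 0)
  clean <- simulatePhantomDwi(ph, sch)
  a <- addRicianNoise(dwiData(clean), 30, seed = 5)
  b <- addRicianNoise(dwiData(clean), 30, seed = 5)
  expect_identical(a, b)
  # default perturbation: high but imperfect WM signal correlation
  pair <- makeScanRescan(ph, sch, rescanPerturbation(), seed = 3)
  wm <- which(array(wmMask(ph), dim(wmMask(ph))))
  su <- matrix(dwiData(pair$scan), prod(ph@shape))[wm, ]
  sv <- matrix(dwiData(pair$rescan), prod(ph@shape))[wm, ]
  r <- cor(as.vector(su), as.vector(sv))
  expect_gt(r, 0.9); expect_lt(r, 0.9999)
  # bias field at amplitude 0.1 keeps the mean ratio within [0.9, 1.1]
  bf <- dcsd:::biasField(c(16L, 16L, 16L), 0.1, seed = 2)
  expect_true(all(bf >= 0.9 & bf <= 1.1))
  # reproducibility
  pair2 <- makeScanRescan(ph, sch, rescanPerturbation(), seed = 3)
  expect_identical(dwiData(pair$rescan), dwiData(pair2$rescan))
})

test_that("DWI volumes show signal decay and positive signals", {
  ph <- fxPhantom16()
  pair <- makeScanRescan(ph, fxScheme96(), seed = 3)
  d <- dwiData(pair$scan)
  expect_true(all(d >= 0) && all(is.finite(d)))
  wm <- wmMask(ph)
  b0 <- apply(d[, , , 1:3, drop = FALSE], 1:3, mean)
  dw <- apply(d[, , , -(1:3), drop = FALSE], 1:3, mean)
  expect_true(all(b0[wm] > dw[wm]))
})
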