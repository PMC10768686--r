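test_that("response estimation reproduces the single-fiber signal", {
  fx <- fxNoiseless()
  sch <- fxScheme96()
  resp <- fx$response
  # reconvolving a unit-z delta with the kernel must reproduce the
  # aligned single-fiber signal profile (forward simulation oracle)
  delta <- as.numeric(shDesignMatrix(matrix(c(0, 0, 1), 1), 8))
  sigSh <- forwardConvolve(delta, resp)
  probe <- directions(makeGradientScheme(60, 2000, 0, seed = 12))
  pred <- shToAmplitudes(sigSh, probe)
  cfg <- fiberConfig(c(0, 0, 1), 0.7) # phantom single-fiber composition
  truth <- simulateSignal(cfg, GradientScheme(probe, 2000, 0L))
  # order-8 band-limit of the tensor profile bounds the attainable match
  expect_lt(max(abs(pred - truth)) / max(truth), 0.02)
  # averaging idempotence: duplicated voxels give the identical response
  ph <- fx$phantom
  sf <- singleFiberMask(ph)
  one <- which(sf, arr.ind = TRUE)[1, , drop = FALSE]
  m1 <- array(FALSE, ph@shape); m1[one] <- TRUE
  r1 <- estimateResponse(fx$dwi, m1)
  expect_equal(zonalCoeffs(r1), zonalCoeffs(estimateResponse(fx$dwi, m1)))
  expect_error(estimateResponse(fx$dwi, array(FALSE, ph@shape)), "empty")
})

test_that("isotropic voxels give a near-zonal-free response", {
  sch <- fxScheme96()
  iso <- simulateSignal(fiberConfig(matrix(numeric(0), 0, 3), numeric(0)), sch)
  dat <- array(rep(iso, each = 8), c(2, 2, 2, length(iso)))
  dwi <- new("DWIVolume", data = dat, scheme = sch, mask = NULL)
  resp <- estimateResponse(dwi, array(TRUE, c(2, 2, 2)))
  expect_lt(max(abs(zonalCoeffs(resp)[-1])), 1e-6 * zonalCoeffs(resp)[1])
})

test_that("forward convolution obeys the zonal convolution theorem", {
  resp <- fxNoiseless()$response
  expect_equal(forwardConvolve(numeric(45), resp), numeric(45))
  # identity kernel: exact identity map
  set.seed(21)
  cc <- rnorm(45)
  expect_equal(forwardConvolve(cc, identityResponse(8)), cc,
               tolerance = 1e-12)
  # linearity
  c2 <- rnorm(45)
  expect_equal(forwardConvolve(cc + 2 * c2, resp),
               forwardConvolve(cc, resp) + 2 * forwardConvolve(c2, resp),
               tolerance = 1e-12)
  # dense-quadrature spherical convolution oracle:
  # (f * h)(d) = integral over the sphere of f(w) h(w . d)
  G <- dcsd:::fibonacciSphereSym(10000)
  fAmp <- shToAmplitudes(cc, G)
  idx <- shIndexTable(8)
  zCoef <- numeric(45); zCoef[idx$m == 0] <- zonalCoeffs(resp)
  probe <- dcsd:::fibonacciSphereSym(64)
  conv <- vapply(seq_len(nrow(probe)), function(i) {
    ct <- pmin(1, pmax(-1, as.numeric(G %*% probe[i, ])))
    # kernel value at angle acos(ct) from the probe axis
    hv <- shToAmplitudes(zCoef, cbind(sqrt(1 - ct^2), 0, ct))
    sum(fAmp * hv) * 4 * pi / nrow(G)
  }, numeric(1))
  pred <- shToAmplitudes(forwardConvolve(cc, resp), probe)
  expect_lt(max(abs(pred - conv)) / max(abs(pred)), 5e-3)
})

test_that("CSD inverts the forward model for noiseless voxels", {
  fx <- fxNoiseless()
  sch <- fxScheme96()
  resp <- fx$response
  # single fiber along z: peak within 2 degrees
  amp <- simulateSignal(fiberConfig(c(0, 0, 1), 0.7), sch)[-(1:3)]
  fit <- csdFit(amp, sch, resp)
  pk <- peakDirections(fit)
  expect_identical(nrow(pk), 1L)
  expect_lt(dcsd:::angleDeg(pk[1, ], c(0, 0, 1)), 2)
  # isotropic voxel: >= 99% of energy in the order-0 term
  ampIso <- simulateSignal(fiberConfig(matrix(numeric(0), 0, 3),
                                       numeric(0)), sch)[-(1:3)]
  fitIso <- csdFit(ampIso, sch, resp)
  expect_gt(fitIso[1]^2 / sum(fitIso^2), 0.99)
  expect_identical(nrow(peakDirections(fitIso)), 0L)
  # 90-degree crossing: two peaks within 5 degrees, balanced amplitudes
  ampX <- simulateSignal(fiberConfig(rbind(c(1, 0, 0), c(0, 1, 0)),
                                     c(0.4, 0.4)), sch)[-(1:3)]
  fitX <- csdFit(ampX, sch, resp)
  pkX <- peakDirections(fitX)
  expect_identical(nrow(pkX), 2L)
  errs <- c(min(apply(pkX, 1, dcsd:::angleDeg, v = c(1, 0, 0))),
            min(apply(pkX, 1, dcsd:::angleDeg, v = c(0, 1, 0))))
  expect_lt(max(errs), 5)
  a <- shToAmplitudes(fitX, rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_gt(a[1] / a[2], 0.8); expect_lt(a[1] / a[2], 1.25)
})

test_that("deconvolution inverts convolution for nonnegative band-limited fODFs", {
  sch <- fxScheme96()
  resp <- fxNoiseless()$response
  set.seed(31)
  for (rep in 1:5) {
    mu <- rnorm(3); mu <- mu / sqrt(sum(mu^2))
    f <- groundTruthFodf(fiberConfig(mu, 0.8))
    amp <- shToAmplitudes(forwardConvolve(f, resp), directions(sch))
    # with the amplitude threshold at zero the constraint only guards
    # against negativity and the deconvolution nearly inverts the
    # convolution; the default threshold intentionally biases amplitudes
    # near zero toward zero, which costs shape fidelity on lobes that
    # graze zero (its purpose under noise)
    expect_gt(acc(csdFit(amp, sch, resp, tau = 0), f), 0.95)
    expect_gt(acc(csdFit(amp, sch, resp), f), 0.80)
  }
})

test_that("fitted fODFs are near-nonnegative on the constraint sphere", {
  fx <- fxNoiseless()
  est <- coefArray(fx$csd)
  sg <- dcsd:::sphereGrid(724, 8)
  vox <- which(wmMask(fx$phantom), arr.ind = TRUE)
  set.seed(2)
  for (i in sample(nrow(vox), 50)) {
    a <- sg$design %*% est[vox[i, 1], vox[i, 2], vox[i, 3], ]
    expect_gt(min(a), -0.03 * max(a))
  }
})

test_that("volume CSD is deterministic, masked and accurate on the phantom", {
  fx <- fxNoiseless()
  est <- coefArray(fx$csd)
  expect_identical(attr(est, "nFailed"), 0L)
  expect_true(all(est[, , , 1][!wmMask(fx$phantom)] == 0))
  m <- meanAcc(accMap(fx$csd, gtFodf(fx$phantom), wmMask(fx$phantom)))
  expect_gte(m$mean, 0.95)
  # empty mask: all-zero field
  empty <- fitCsdVolume(fx$dwi, array(FALSE, fx$phantom@shape), fx$response)
  expect_true(all(coefArray(empty) == 0))
})

test_that("fewer directions degrade CSD agreement monotonically", {
  fx <- fxNoiseless()
  ph <- fx$phantom
  # evaluate on a fixed subsample of WM voxels for speed
  vox <- which(wmMask(ph), arr.ind = TRUE)
  set.seed(5)
  sub <- vox[sample(nrow(vox), 120), ]
  mask <- array(FALSE, ph@shape); mask[sub] <- TRUE
  sch <- fxScheme96()
  full <- fitCsdVolume(fx$dwi, mask, fx$response)
  # noisy acquisition so direction count matters
  noisy <- new("DWIVolume",
               data = addRicianNoise(dwiData(fx$dwi), 30, seed = 8),
               scheme = sch, mask = wmMask(ph))
  accs <- vapply(c(96L, 75L, 60L, 45L), function(nk) {
    idx <- if (nk == 96L) seq_len(96L)
      else dropoutDirections(sch, nk, seed = 17)
    sub <- subsetVolume(noisy, idx)
    est <- fitCsdVolume(sub, mask, fx$response)
    meanAcc(accMap(est, full, mask))$mean
  }, numeric(1))
  expect_true(all(diff(accs) < 0))
})

test_that("peak extraction matches a brute-force dense-grid argmax", {
  set.seed(41)
  for (rep in 1:5) {
    mu <- rnorm(3); mu <- mu / sqrt(sum(mu^2))
    cc <- groundTruthFodf(fiberConfig(mu, 0.9))
    pk <- peakDirections(cc)
    # oracle: argmax on a very dense independent grid
    Gd <- dcsd:::fibonacciSphereSym(20000)
    best <- Gd[which.max(shToAmplitudes(cc, Gd)), ]
    expect_identical(nrow(pk), 1L)
    expect_lt(dcsd:::angleDeg(pk[1, ], best), 1)
    expect_lt(dcsd:::angleDeg(pk[1, ], mu), 2)
  }
  expect_identical(nrow(peakDirections(numeric(45))), 0L)
})
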