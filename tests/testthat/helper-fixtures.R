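# Shared fixtures, memoised so expensive objects are built once per run.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fxScheme96 <- function() fixture("scheme96", function()
  makeGradientScheme(96, bValue = 2000, nB0 = 3, seed = 7))

fxPhantom16 <- function() fixture("phantom16", function()
  makePhantom(c(16L, 16L, 16L), seed = 1))

# noiseless acquisition of the 16^3 phantom + response + full CSD field
fxNoiseless <- function() fixture("noiseless", function() {
  ph <- fxPhantom16()
  dwi <- simulatePhantomDwi(ph, fxScheme96())
  resp <- estimateResponse(dwi, singleFiberMask(ph))
  csd <- fitCsdVolume(dwi, wmMask(ph), resp)
  list(phantom = ph, dwi = dwi, response = resp, csd = csd)
})

fxStudy <- function(seed = 1) {
  fixture(paste0("study", seed), function() referenceStudy(seed = seed))
}

fxStudyModel <- function(seed, arch, beta = 0, augment = FALSE) {
  key <- sprintf("model_%d_%s_b%g_a%d", seed, arch, beta, augment)
  fixture(key, function()
    trainStudyModel(fxStudy(seed), arch, beta = beta, augment = augment))
}

# independent dense-quadrature SH projection (oracle for fitSH/groundTruthFodf)
oracleShProject <- function(fn, maxOrder, n = 5000L) {
  G <- dcsd:::fibonacciSphereSym(n)
  B <- shDesignMatrix(G, maxOrder)
  as.numeric(solve(crossprod(B), crossprod(B, fn(G))))
}

randomUnitVectors <- function(n, seed = 1) {
  withr::with_seed(seed, {
    M <- matrix(rnorm(n * 3), ncol = 3)
    M / sqrt(rowSums(M^2))
  })
}
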