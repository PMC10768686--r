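# Synthetic scan/rescan DWI phantoms with analytic ground-truth fODFs.
#
# The generator emulates the study conditions the estimator is meant for:
# single-shell HARDI (one b-value, ~90-96 uniform directions), paired
# acquisitions of the same anatomy with independent Rician noise, a mild
# multiplicative intensity bias and a small gradient-frame rotation, and
# white matter containing both coherent single-fiber and 90-degree-crossing
# regions.

#' Per-voxel fiber configuration
#'
#' @param directions p x 3 matrix (or length-3 vector) of unit fiber
#'   directions.
#' @param fractions length-p volume fractions, sum <= 1; the remainder is
#'   isotropic.
#' @return a list with elements `directions` and `fractions`.
#' @export
fiberConfig <- function(directions, fractions) {
  if (is.null(dim(directions))) directions <- matrix(directions, nrow = 1L)
  checkUnitDirections(directions, tol = 1e-6)
  fractions <- as.numeric(fractions)
  if (length(fractions) != nrow(directions))
    stop("one fraction per fiber population required")
  if (any(fractions < 0) || any(fractions > 1) || sum(fractions) > 1 + 1e-12)
    stop("fractions must lie in [0,1] and sum to at most 1")
  list(directions = directions, fractions = fractions)
}

#' Default tissue parameters of the multi-tensor signal model
#'
#' Prolate fiber tensor with eigenvalues (1.7, 0.2, 0.2) x 1e-3 mm^2/s and
#' a free-water-like isotropic compartment with D = 3.0e-3 mm^2/s --
#' standard adult-white-matter values for single-shell simulation.
#'
#' @return list with `eigenvalues` (length 3) and `dIso`.
#' @export
defaultTissue <- function() {
  list(eigenvalues = c(1.7e-3, 0.2e-3, 0.2e-3), dIso = 3.0e-3)
}

#' Simulate the noiseless multi-tensor signal of one voxel
#'
#' \eqn{S(g) = s_0 [ \sum_i f_i \exp(-b g^T D_i g) + f_{iso} \exp(-b D_{iso}) ]}
#' with axially symmetric fiber tensors \eqn{D_i} of the given eigenvalues
#' aligned with each fiber direction.  b=0 entries (the first `nB0(scheme)`
#' outputs) equal `s0`.
#'
#' @param config a [fiberConfig()].
#' @param scheme a [GradientScheme-class].
#' @param eigenvalues fiber tensor eigenvalues, \eqn{\lambda_1 \ge \lambda_2 = \lambda_3 > 0}.
#' @param dIso isotropic diffusivity.
#' @param s0 b=0 signal level.
#' @return numeric vector of length `nB0(scheme) + nDirections(scheme)`.
#' @export
simulateSignal <- function(config, scheme, eigenvalues = defaultTissue()$eigenvalues,
                           dIso = defaultTissue()$dIso, s0 = 1) {
  stopifnot(is(scheme, "GradientScheme"))
  if (any(eigenvalues <= 0) || eigenvalues[1] < eigenvalues[2])
    stop("eigenvalues must be positive with lambda1 >= lambda2")
  f <- config$fractions
  if (sum(f) > 1 + 1e-12) stop("fractions must sum to at most 1")
  fIso <- 1 - sum(f)
  b <- scheme@bValue
  G <- scheme@directions
  s <- rep(s0 * fIso * exp(-b * dIso), nrow(G))
  for (i in seq_along(f)) {
    mu <- config$directions[i, ]
    ct2 <- as.numeric(G %*% mu)^2 # cos^2 of angle to the fiber
    adc <- eigenvalues[2] + (eigenvalues[1] - eigenvalues[2]) * ct2
    s <- s + s0 * f[i] * exp(-b * adc)
  }
  c(rep(s0, scheme@nB0), s)
}

# --- ground-truth fODF lobes ------------------------------------------------

# Canonical zonal profile of the antipodally symmetric Watson-like lobe
# exp(kappa * cos^2 theta), normalized to unit integral.  A plain order-8
# truncation of this lobe rings negative (about -11% of peak at kappa=50),
# which no nonnegative density can match; the ground-truth lobe is
# therefore the nonnegative band-limited approximation of the Watson,
# computed by alternating projections between the band-limited subspace
# and the nonnegative cone on a dense quadrature grid, followed by the
# minimal isotropic floor covering residual between-grid negativity.
# Returns the m=0 coefficient per even order (z-aligned).  Memoized.
.lobeCache <- new.env(parent = emptyenv())

watsonLobeZonal <- function(maxOrder, kappa, nQuad = 1448L, nPolish = 80L) {
  key <- sprintf("L%d_k%.6g_q%d", maxOrder, kappa, nQuad)
  if (!is.null(.lobeCache[[key]])) return(.lobeCache[[key]])
  if (kappa <= 0) stop("sharpness kappa must be positive")
  G <- fibonacciSphereSym(nQuad)
  B <- shDesignMatrix(G, maxOrder)
  BtBinv <- solve(crossprod(B))
  w <- exp(kappa * G[, 3L]^2)
  w <- w / (sum(w) * 4 * pi / nQuad) # unit integral
  cc <- BtBinv %*% crossprod(B, w)
  f <- as.numeric(B %*% cc)
  for (i in seq_len(nPolish)) {
    f <- pmax(f, 0)
    cc <- BtBinv %*% crossprod(B, f)
    f <- as.numeric(B %*% cc)
  }
  idx <- shIndexTable(maxOrder)
  cc[idx$m != 0L] <- 0 # exact axial symmetry about z
  probe <- shDesignMatrix(fibonacciSphereSym(5000L), maxOrder)
  mn <- min(probe %*% cc)
  if (mn < 0) cc[1L] <- cc[1L] + (-mn + 1e-9) * sqrt(4 * pi)
  zonal <- cc[idx$m == 0L] # one per even order
  .lobeCache[[key]] <- as.numeric(zonal)
  .lobeCache[[key]]
}

#' Analytic ground-truth fODF of a fiber configuration
#'
#' Mixture of antipodally symmetric Watson-like lobes (one per fiber
#' population, weighted by its volume fraction) plus a uniform component
#' carrying the isotropic fraction, expressed in the even-order SH basis.
#' The canonical z-aligned lobe is the nonnegative band-limited
#' approximation of the Watson kernel (dense-quadrature projection with an
#' alternating-projection nonnegativity polish);
#' per-voxel lobes are obtained exactly by the SH addition theorem
#' (rotation of a zonal function), so per-order energies are exactly
#' rotation-invariant and peaks sit exactly on the configured fiber
#' directions.
#'
#' @param config a [fiberConfig()].
#' @inheritParams nCoeffs
#' @param sharpness Watson concentration kappa (> 0); default 50.
#' @return coefficient vector of length `nCoeffs(maxOrder)`; the function
#'   integrates to 1 over the sphere.
#' @export
groundTruthFodf <- function(config, maxOrder = 8L, sharpness = 50) {
  zonal <- watsonLobeZonal(maxOrder, sharpness)
  idx <- shIndexTable(maxOrder)
  nc <- nCoeffs(maxOrder)
  cc <- numeric(nc)
  f <- config$fractions
  if (length(f)) {
    Bmu <- shDesignMatrix(config$directions, maxOrder) # Y_km at fiber dirs
    scale <- sqrt(4 * pi / (2 * idx$k + 1))
    zPerCoef <- zonal[idx$k / 2L + 1L]
    for (i in seq_along(f))
      cc <- cc + f[i] * scale * zPerCoef * Bmu[i, ]
  }
  fIso <- 1 - sum(f)
  cc[1L] <- cc[1L] + fIso / sqrt(4 * pi)
  cc
}

#' Add Rician noise to a magnitude signal
#'
#' Each entry S is replaced by \eqn{\sqrt{(S+\epsilon_1)^2 + \epsilon_2^2}}
#' with \eqn{\epsilon \sim N(0, s_0/\mathrm{snr})} -- the magnitude of a
#' complex Gaussian perturbation, the standard noise model of magnitude MR
#' images.  `snr >= 1e12` is treated as noiseless.  A `"gaussian"` model
#' (additive, clamped at 0) is retained for debugging.
#'
#' @param signal non-negative numeric vector or array.
#' @param snr positive scalar, b=0 signal-to-noise ratio.
#' @param seed integer RNG seed (deterministic output).
#' @param s0 the b=0 level defining the noise scale.
#' @param model `"rician"` (default) or `"gaussian"`.
#' @return noisy signal, same shape as the input.
#' @export
addRicianNoise <- function(signal, snr, seed, s0 = 1, model = c("rician", "gaussian")) {
  model <- match.arg(model)
  if (snr <= 0) stop("snr must be positive")
  if (any(signal < 0)) stop("signal must be non-negative")
  if (snr >= 1e12) return(signal)
  sigma <- s0 / snr
  withSeed(deriveSeed(seed, "noise", model), {
    if (model == "rician") {
      e1 <- stats::rnorm(length(signal), 0, sigma)
      e2 <- stats::rnorm(length(signal), 0, sigma)
      out <- sqrt((signal + e1)^2 + e2^2)
    } else {
      out <- pmax(signal + stats::rnorm(length(signal), 0, sigma), 0)
    }
    if (!is.null(dim(signal))) dim(out) <- dim(signal)
    out
  })
}

#' Construct a scan/rescan perturbation model
#'
#' Defaults (scan SNR 30, rescan SNR 25, 5% bias field, 3 degree gradient
#' rotation) are chosen to visibly degrade naive scan/rescan CSD
#' consistency while keeping recovery feasible -- a mild intersite/
#' intrasession variability regime.
#'
#' @param snrScan,snrRescan b=0 SNR of the two acquisitions.
#' @param biasAmplitude relative strength of the multiplicative
#'   low-frequency intensity field on the rescan, in `[0, 0.2]`.
#' @param schemeRotationDeg rigid rotation of the rescan gradient set, in
#'   `[0, 10]` degrees.
#' @return a [RescanPerturbation-class].
#' @export
rescanPerturbation <- function(snrScan = 30, snrRescan = 25,
                               biasAmplitude = 0.05, schemeRotationDeg = 3) {
  new("RescanPerturbation", snrScan = snrScan, snrRescan = snrRescan,
      biasAmplitude = biasAmplitude, schemeRotationDeg = schemeRotationDeg)
}

voxelIndex <- function(x, y, z, shape) {
  x + (y - 1L) * shape[1] + (z - 1L) * shape[1] * shape[2]
}

#' Fiber configuration of one phantom voxel
#'
#' @param phantom a [Phantom-class].
#' @param x,y,z 1-based voxel coordinates.
#' @return a [fiberConfig()] list, or `NULL` for non-WM voxels.
#' @export
fiberConfigAt <- function(phantom, x, y, z) {
  stopifnot(is(phantom, "Phantom"))
  phantom@fiberConfigs[[voxelIndex(x, y, z, phantom@shape)]]
}

#' Generate a two-bundle digital phantom
#'
#' Builds a deterministic (seeded) phantom containing a coherent
#' single-fiber bundle (gently bending around the x axis), a second bundle
#' along y crossing the first at 90 degrees in their overlap, and an
#' isotropic non-WM background.  Within-bundle orientations vary smoothly
#' (neighbor angular change well under 15 degrees).  The white-matter mask
#' marks fiber-bearing voxels; ground-truth fODFs are generated with
#' [groundTruthFodf()].
#'
#' @param shape integer length-3 grid size, each dimension >= 8.
#' @param seed integer RNG seed.
#' @inheritParams groundTruthFodf
#' @param singleFraction fiber fraction of single-population voxels.
#' @param crossingFraction per-population fraction in crossing voxels.
#' @param voxelSize voxel edge lengths in mm.
#' @return a [Phantom-class].
#' @examples
#' ph <- makePhantom(c(8, 8, 8), seed = 1)
#' sum(wmMask(ph))
#' @export
makePhantom <- function(shape = c(16L, 16L, 16L), seed = 1L, maxOrder = 8L,
                        sharpness = 50, singleFraction = 0.7,
                        crossingFraction = 0.4, voxelSize = c(2, 2, 2)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop("each spatial dimension must be at least 8 (3x3x3 interior patches)")
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  jitter <- withSeed(deriveSeed(seed, "phantom"), stats::runif(4, -1, 1))
  # bundle A: along x, bending in the x-y plane
  ayr <- seq.int(max(2L, ceiling(0.20 * ny)), floor(0.55 * ny))
  azr <- seq.int(max(2L, ceiling(0.25 * nz)), floor(0.60 * nz))
  # bundle B: along y, crossing A where the z ranges overlap
  bxr <- seq.int(max(2L, ceiling(0.30 * nx)), floor(0.75 * nx))
  bzr <- seq.int(max(2L, ceiling(0.45 * nz)), floor(0.80 * nz))
  bendA <- (6 + 2 * jitter[1]) * pi / 180
  bendB <- (6 + 2 * jitter[2]) * pi / 180
  configs <- vector("list", nx * ny * nz)
  wm <- array(FALSE, shape)
  dirA <- function(x) {
    d <- bendA * sin(2 * pi * x / nx + jitter[3])
    c(cos(d), sin(d), 0)
  }
  dirB <- function(y) {
    d <- bendB * sin(2 * pi * y / ny + jitter[4])
    c(-sin(d), cos(d), 0)
  }
  for (z in seq_len(nz)) for (y in seq_len(ny)) for (x in seq_len(nx)) {
    inA <- (y %in% ayr) && (z %in% azr)
    inB <- (x %in% bxr) && (z %in% bzr)
    li <- voxelIndex(x, y, z, shape)
    if (inA && inB) {
      configs[[li]] <- fiberConfig(rbind(dirA(x), dirB(y)),
                                   c(crossingFraction, crossingFraction))
    } else if (inA) {
      configs[[li]] <- fiberConfig(dirA(x), singleFraction)
    } else if (inB) {
      configs[[li]] <- fiberConfig(dirB(y), singleFraction)
    }
    wm[x, y, z] <- inA || inB
  }
  nc <- nCoeffs(maxOrder)
  gt <- array(0, c(shape, nc))
  for (z in seq_len(nz)) for (y in seq_len(ny)) for (x in seq_len(nx)) {
    cfg <- configs[[voxelIndex(x, y, z, shape)]]
    if (!is.null(cfg))
      gt[x, y, z, ] <- groundTruthFodf(cfg, maxOrder, sharpness)
  }
  tissue <- defaultTissue()
  new("Phantom", shape = shape, fiberConfigs = configs, wmMask = wm,
      gtFodf = SHField(gt, SHBasis(maxOrder), voxelSize, kind = "fodf"),
      eigenvalues = tissue$eigenvalues, dIso = tissue$dIso)
}

#' Noiseless DWI volume of a phantom
#'
#' Evaluates the multi-tensor forward model at every voxel.  Non-WM voxels
#' are purely isotropic.
#'
#' @param phantom a [Phantom-class].
#' @param scheme a [GradientScheme-class].
#' @param s0 b=0 signal level.
#' @return a [DWIVolume-class] carrying the phantom's WM mask.
#' @export
simulatePhantomDwi <- function(phantom, scheme, s0 = 1) {
  stopifnot(is(phantom, "Phantom"))
  shape <- phantom@shape
  nvol <- scheme@nB0 + nDirections(scheme)
  dat <- array(0, c(shape, nvol))
  iso <- simulateSignal(fiberConfig(matrix(numeric(0), 0, 3), numeric(0)),
                        scheme, phantom@eigenvalues, phantom@dIso, s0)
  for (z in seq_len(shape[3])) for (y in seq_len(shape[2])) for (x in seq_len(shape[1])) {
    cfg <- phantom@fiberConfigs[[voxelIndex(x, y, z, shape)]]
    dat[x, y, z, ] <- if (is.null(cfg)) iso
      else simulateSignal(cfg, scheme, phantom@eigenvalues, phantom@dIso, s0)
  }
  new("DWIVolume", data = dat, scheme = scheme, mask = phantom@wmMask)
}

# Smooth multiplicative bias field 1 + a * prod(sin(...)), bounded in [1-a, 1+a].
biasField <- function(shape, amplitude, seed) {
  ph <- withSeed(deriveSeed(seed, "bias"), stats::runif(3, 0, 2 * pi))
  gx <- sin(2 * pi * seq_len(shape[1]) / shape[1] + ph[1])
  gy <- sin(2 * pi * seq_len(shape[2]) / shape[2] + ph[2])
  gz <- sin(2 * pi * seq_len(shape[3]) / shape[3] + ph[3])
  1 + amplitude * outer(outer(gx, gy), gz)
}

#' Simulate a registered scan/rescan acquisition pair
#'
#' Both volumes share the phantom geometry (voxelwise aligned).  The scan
#' uses the given scheme at `snrScan`; the rescan uses the scheme rotated
#' by `schemeRotationDeg` about a seeded random axis, a multiplicative
#' low-frequency bias field of relative amplitude `biasAmplitude`, and
#' `snrRescan`, with an independent noise stream.  Deterministic given the
#' seed.
#'
#' @inheritParams simulatePhantomDwi
#' @param perturbation a [RescanPerturbation-class].
#' @param seed integer RNG seed.
#' @return list with elements `scan` and `rescan`, both [DWIVolume-class].
#' @export
makeScanRescan <- function(phantom, scheme,
                           perturbation = rescanPerturbation(), seed = 1L,
                           s0 = 1) {
  stopifnot(is(perturbation, "RescanPerturbation"))
  clean <- simulatePhantomDwi(phantom, scheme, s0)
  scan <- new("DWIVolume",
              data = addRicianNoise(clean@data, perturbation@snrScan,
                                    deriveSeed(seed, "scan"), s0),
              scheme = scheme, mask = phantom@wmMask)
  axis <- withSeed(deriveSeed(seed, "rotaxis"), stats::rnorm(3))
  schemeR <- if (perturbation@schemeRotationDeg > 0)
    rotateScheme(scheme, perturbation@schemeRotationDeg, axis) else scheme
  cleanR <- simulatePhantomDwi(phantom, schemeR, s0)
  datR <- cleanR@data
  if (perturbation@biasAmplitude > 0) {
    bf <- biasField(phantom@shape, perturbation@biasAmplitude, seed)
    datR <- datR * as.vector(bf) # recycled over the 4th axis
  }
  rescan <- new("DWIVolume",
                data = addRicianNoise(datR, perturbation@snrRescan,
                                      deriveSeed(seed, "rescan"), s0),
                scheme = schemeR, mask = phantom@wmMask)
  list(scan = scan, rescan = rescan)
}

#' Signal-SH representation of a DWI volume
#'
#' Normalizes each voxel's diffusion-weighted signal by its mean b=0 value
#' and fits the even-order SH basis, producing the "signal ODF" field used
#' as model input.  Voxels with non-positive mean b=0 are set to zero.
#'
#' @param dwi a [DWIVolume-class].
#' @inheritParams fitSH
#' @param voxelSize voxel size recorded on the output field.
#' @return an [SHField-class] with `kind = "signal"`.
#' @export
dwiToSignalSH <- function(dwi, maxOrder = 8L, lbWeight = 0,
                          voxelSize = c(2, 2, 2)) {
  stopifnot(is(dwi, "DWIVolume"))
  sch <- dwi@scheme
  d <- dim(dwi@data)
  nvox <- prod(d[1:3])
  flat <- matrix(dwi@data, nrow = nvox) # voxels x volumes
  b0idx <- seq_len(sch@nB0)
  s0 <- if (sch@nB0 > 0) rowMeans(flat[, b0idx, drop = FALSE]) else rep(1, nvox)
  amp <- t(flat[, sch@nB0 + seq_len(nDirections(sch)), drop = FALSE]) # dirs x voxels
  ok <- s0 > 0
  amp[, ok] <- sweep(amp[, ok, drop = FALSE], 2L, s0[ok], "/")
  amp[, !ok] <- 0
  C <- fitSH(amp, sch@directions, maxOrder, lbWeight = lbWeight)
  C[, !ok] <- 0
  arr <- array(t(C), c(d[1:3], nCoeffs(maxOrder)))
  SHField(arr, SHBasis(maxOrder), voxelSize, kind = "signal")
}
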