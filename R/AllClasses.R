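#' @import methods
NULL

#' Even-order real spherical-harmonic basis specification
#'
#' Describes the antipodally symmetric real spherical-harmonic (SH) basis
#' used throughout the package: only even orders \eqn{k \le L} are kept, so a
#' basis of maximum order \eqn{L} has \eqn{(L+1)(L+2)/2} functions (45 at
#' \eqn{L = 8}).  The normalization in use is recorded as a convention label;
#' see [shDesignMatrix()] for the exact functional form.
#'
#' @slot maxOrder even integer, the truncation order \eqn{L}.
#' @slot convention character label of the real-SH normalization variant.
#'
#' @seealso [SHBasis()], [nCoeffs()], [shIndexTable()]
#' @export
setClass("SHBasis", representation(
  maxOrder = "integer",
  convention = "character"
))

setValidity("SHBasis", function(object) {
  L <- object@maxOrder
  if (length(L) != 1L || is.na(L) || L < 0L)
    return("maxOrder must be a single non-negative integer")
  if (L %% 2L != 0L)
    return("maxOrder must be even (antipodally symmetric basis)")
  if (length(object@convention) != 1L || !nzchar(object@convention))
    return("convention must be a non-empty string")
  TRUE
})

#' Volumetric field of spherical-harmonic coefficient vectors
#'
#' A 4D array (X, Y, Z, n_coef) holding one SH coefficient vector per voxel,
#' together with the basis it is expressed in and the voxel size.  Used both
#' for the SH representation of the normalized diffusion signal ("signal
#' ODF", the model input) and for fODF fields (the model output), which the
#' `kind` slot distinguishes.
#'
#' @slot data numeric 4D array, last axis of length `nCoeffs(maxOrder(basis))`.
#' @slot basis an [SHBasis-class] object.
#' @slot voxelSize numeric length-3, voxel edge lengths in mm.
#' @slot kind `"signal"` or `"fodf"`.
#'
#' @seealso [SHField()], [coefArray()], [writeShField()]
#' @export
setClass("SHField", representation(
  data = "array",
  basis = "SHBasis",
  voxelSize = "numeric",
  kind = "character"
))

setValidity("SHField", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L)
    return("data must be a 4D array (X, Y, Z, n_coef)")
  nc <- nCoeffs(object@basis@maxOrder)
  if (d[4L] != nc)
    return(sprintf("coefficient axis has length %d; basis requires %d", d[4L], nc))
  if (any(!is.finite(object@data)))
    return("all coefficients must be finite")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive numbers (mm)")
  if (!object@kind %in% c("signal", "fodf"))
    return("kind must be 'signal' or 'fodf'")
  TRUE
})

#' Single-shell diffusion gradient scheme
#'
#' The acquisition geometry: unit gradient directions for one shell, the
#' shell b-value, and the number of interleaved b=0 volumes.  Directions are
#' defined up to sign (antipodal identification).
#'
#' @slot directions numeric n x 3 matrix of unit vectors.
#' @slot bValue single positive numeric, s/mm^2.
#' @slot nB0 integer count of b=0 volumes.
#'
#' @seealso [makeGradientScheme()], [subsetScheme()], [rotateScheme()]
#' @export
setClass("GradientScheme", representation(
  directions = "matrix",
  bValue = "numeric",
  nB0 = "integer"
))

setValidity("GradientScheme", function(object) {
  d <- object@directions
  if (!is.numeric(d) || ncol(d) != 3L || nrow(d) < 1L)
    return("directions must be an n x 3 numeric matrix")
  nrm <- sqrt(rowSums(d^2))
  if (any(abs(nrm - 1) > 1e-6))
    return("all directions must be unit-norm (tolerance 1e-6)")
  if (length(object@bValue) != 1L || object@bValue <= 0)
    return("bValue must be a single positive number")
  if (object@nB0 < 0L)
    return("nB0 must be non-negative")
  TRUE
})

setClassUnion("arrayOrNULL", c("array", "NULL"))

#' 4D diffusion-weighted MRI volume
#'
#' Signal array with its gradient scheme.  The 4th axis stacks the `nB0`
#' b=0 volumes first, then one volume per diffusion direction.
#'
#' @slot data numeric 4D array (X, Y, Z, nB0 + n directions), non-negative.
#' @slot scheme a [GradientScheme-class].
#' @slot mask logical 3D array (white-matter mask), or `NULL` when absent.
#'
#' @seealso [makeScanRescan()], [readDwi()], [dwiToSignalSH()]
#' @export
setClass("DWIVolume", representation(
  data = "array",
  scheme = "GradientScheme",
  mask = "arrayOrNULL"
))

setValidity("DWIVolume", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L)
    return("data must be a 4D array")
  nvol <- object@scheme@nB0 + nrow(object@scheme@directions)
  if (d[4L] != nvol)
    return(sprintf("4th axis length %d does not match scheme (%d volumes)", d[4L], nvol))
  if (any(!is.finite(object@data)) || any(object@data < 0))
    return("signals must be finite and non-negative")
  if (!is.null(object@mask)) {
    if (!is.logical(object@mask))
      return("mask must be a logical array")
    if (!identical(dim(object@mask), d[1:3]))
      return("mask shape must match the spatial grid")
  }
  TRUE
})

#' Synthetic phantom with known fiber configurations
#'
#' Desk-scale digital phantom: per-voxel fiber populations (direction +
#' volume fraction), a white-matter mask, the analytic ground-truth fODF
#' field, and the tissue parameters of the multi-tensor signal model.
#'
#' `fiberConfigs` is a flat list in column-major voxel order (x fastest);
#' each element is either `NULL` (non-WM) or a list with `directions`
#' (p x 3 unit rows) and `fractions` (length p, sum <= 1; the remainder is
#' isotropic).  Use [fiberConfigAt()] for 3D indexing.
#'
#' @slot shape integer length-3 grid dimensions.
#' @slot fiberConfigs list with `dim` attribute `shape`.
#' @slot wmMask logical 3D array.
#' @slot gtFodf an [SHField-class] with `kind = "fodf"`.
#' @slot eigenvalues numeric length-3 fiber-tensor eigenvalues (mm^2/s).
#' @slot dIso single numeric isotropic diffusivity (mm^2/s).
#'
#' @seealso [makePhantom()]
#' @export
setClass("Phantom", representation(
  shape = "integer",
  fiberConfigs = "list",
  wmMask = "array",
  gtFodf = "SHField",
  eigenvalues = "numeric",
  dIso = "numeric"
))

setValidity("Phantom", function(object) {
  if (length(object@shape) != 3L || any(object@shape < 1L))
    return("shape must be 3 positive integers")
  if (length(object@fiberConfigs) != prod(object@shape))
    return("fiberConfigs must have one element per voxel")
  if (!identical(dim(object@wmMask), object@shape))
    return("wmMask shape mismatch")
  if (!identical(dim(object@gtFodf@data)[1:3], object@shape))
    return("gtFodf shape mismatch")
  if (length(object@eigenvalues) != 3L || any(object@eigenvalues <= 0))
    return("eigenvalues must be 3 positive numbers")
  c00 <- object@gtFodf@data[, , , 1L]
  if (any(c00[object@wmMask] <= 0))
    return("ground-truth fODF zeroth coefficient must be positive inside the WM mask")
  TRUE
})

#' Axially symmetric single-fiber response function
#'
#' The CSD deconvolution kernel: the m=0 ("zonal") SH coefficients per even
#' order of the signal profile of an idealized single coherent fiber
#' population aligned with +z, plus the b=0 scale it was estimated at.
#'
#' @slot zonal numeric vector, one coefficient per even order 0..maxOrder.
#' @slot maxOrder even integer.
#' @slot s0 single positive numeric.
#'
#' @seealso [estimateResponse()], [forwardConvolve()], [csdFit()]
#' @export
setClass("ResponseFunction", representation(
  zonal = "numeric",
  maxOrder = "integer",
  s0 = "numeric"
))

setValidity("ResponseFunction", function(object) {
  L <- object@maxOrder
  if (L < 0L || L %% 2L != 0L) return("maxOrder must be even and non-negative")
  if (length(object@zonal) != L / 2L + 1L)
    return("zonal must have one entry per even order 0..maxOrder")
  if (any(!is.finite(object@zonal))) return("zonal coefficients must be finite")
  if (object@zonal[1L] <= 0) return("order-0 zonal coefficient must be positive")
  if (length(object@s0) != 1L || object@s0 <= 0) return("s0 must be positive")
  TRUE
})

#' Voxelwise angular-correlation-coefficient map
#'
#' 3D grid of ACC values in `[-1, 1]`; `NA` outside the mask and at voxels
#' where the ACC is undefined (zero energy above order 0 in either field).
#'
#' @slot data numeric 3D array.
#' @slot nUndefined integer count of in-mask voxels with undefined ACC.
#' @slot provenance character length-2: labels of the two compared fields.
#'
#' @seealso [accMap()], [meanAcc()]
#' @export
setClass("ACCMap", representation(
  data = "array",
  nUndefined = "integer",
  provenance = "character"
))

setValidity("ACCMap", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3D array")
  v <- object@data[!is.na(object@data)]
  if (length(v) && (any(v > 1 + 1e-9) | any(v < -1 - 1e-9)))
    return("ACC values must lie in [-1, 1] (tolerance 1e-9)")
  TRUE
})

#' Scan/rescan acquisition perturbation model
#'
#' The measurement-variability model separating a rescan from its scan:
#' independent Rician noise at (possibly different) SNR, a multiplicative
#' low-frequency intensity bias field, and a small rigid rotation of the
#' gradient set (scanner frame misalignment).
#'
#' @slot snrScan,snrRescan positive numerics (b=0 SNR).
#' @slot biasAmplitude relative bias-field strength, in `[0, 0.2]`.
#' @slot schemeRotationDeg rotation of the rescan gradient set, in `[0, 10]` degrees.
#'
#' @seealso [rescanPerturbation()], [makeScanRescan()]
#' @export
setClass("RescanPerturbation", representation(
  snrScan = "numeric",
  snrRescan = "numeric",
  biasAmplitude = "numeric",
  schemeRotationDeg = "numeric"
))

setValidity("RescanPerturbation", function(object) {
  if (object@snrScan <= 0 || object@snrRescan <= 0)
    return("SNR values must be positive")
  if (object@biasAmplitude < 0 || object@biasAmplitude > 0.2)
    return("biasAmplitude must lie in [0, 0.2]")
  if (object@schemeRotationDeg < 0 || object@schemeRotationDeg > 10)
    return("schemeRotationDeg must lie in [0, 10]")
  TRUE
})

#' Gradient-direction dropout specification
#'
#' Controls the intrasubject augmentation: how many directions to retain
#' (uniformly drawn in `[nKeepMin, nKeepMax]`), how many augmented copies to
#' generate, and the seed of the subset stream.  At SH order 8 at least 45
#' directions must be retained.
#'
#' @slot nKeepMin,nKeepMax integer bounds on the retained subset size.
#' @slot nRepeats integer number of augmented copies.
#' @slot seed integer RNG seed.
#'
#' @seealso [dropoutSpec()], [dropoutDirections()], [augmentTrainingPairs()]
#' @export
setClass("DropoutSpec", representation(
  nKeepMin = "integer",
  nKeepMax = "integer",
  nRepeats = "integer",
  seed = "integer"
))

setValidity("DropoutSpec", function(object) {
  if (object@nKeepMin < 1L) return("nKeepMin must be positive")
  if (object@nKeepMax < object@nKeepMin) return("nKeepMax must be >= nKeepMin")
  if (object@nRepeats < 1L) return("nRepeats must be positive")
  TRUE
})
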