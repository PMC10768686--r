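# Intrasubject gradient-direction-dropout augmentation with a b-vector
# coverage check.  Inputs are refit from the retained directions; labels
# always remain the full-direction CSD field.

#' Construct a dropout specification
#'
#' @param nKeepMin,nKeepMax bounds on the retained subset size; at model
#'   order 8 at least 45 directions (the basis size) must be kept.
#' @param nRepeats number of augmented copies.
#' @param seed integer RNG seed of the subset stream.
#' @param maxOrder SH order the subsets must support.
#' @return a [DropoutSpec-class].
#' @export
dropoutSpec <- function(nKeepMin = 45L, nKeepMax = nKeepMin, nRepeats = 10L,
                        seed = 1L, maxOrder = 8L) {
  if (nKeepMin < nCoeffs(maxOrder))
    stop(sprintf("nKeepMin must be at least %d (the order-%d basis size)",
                 nCoeffs(maxOrder), maxOrder))
  new("DropoutSpec", nKeepMin = as.integer(nKeepMin),
      nKeepMax = as.integer(nKeepMax), nRepeats = as.integer(nRepeats),
      seed = as.integer(seed))
}

#' Spherical coverage check of a gradient subset
#'
#' A retained direction set is "well distributed" when (a) the SH design
#' matrix it induces is well conditioned and (b) it leaves no large empty
#' spherical cap: the largest angular radius of a cap (after antipodal
#' symmetrization, measured on a fixed symmetric probe grid) free of any
#' direction must not exceed `maxGapDeg`.
#'
#' @param scheme a [GradientScheme-class] (typically a subset).
#' @inheritParams nCoeffs
#' @param condLimit maximum admissible design-matrix condition number.
#' @param maxGapDeg maximum admissible empty-cap angular radius (degrees).
#' @param nProbe probe grid size.
#' @return list with `pass` (logical), `conditionNumber` and `maxGapDeg`.
#' @export
coverageCheck <- function(scheme, maxOrder = 8L, condLimit = 1e3,
                          maxGapDeg = 30, nProbe = 724L) {
  stopifnot(is(scheme, "GradientScheme"))
  if (nDirections(scheme) < nCoeffs(maxOrder))
    stop(sprintf("subset has %d directions; order %d requires at least %d",
                 nDirections(scheme), maxOrder, nCoeffs(maxOrder)))
  B <- shDesignMatrix(scheme@directions, maxOrder)
  kap <- kappa(B, exact = TRUE)
  probe <- sphereGrid(nProbe, 0L)$points
  # angular distance from each probe point to the nearest direction,
  # after antipodal identification
  ct <- abs(probe %*% t(scheme@directions))
  gap <- max(acos(pmin(1, apply(ct, 1L, max)))) * 180 / pi
  list(pass = kap <= condLimit && gap <= maxGapDeg,
       conditionNumber = as.numeric(kap), maxGapDeg = as.numeric(gap))
}

#' Draw a well-distributed random direction subset
#'
#' Uniformly samples `nKeep` of the scheme's directions without
#' replacement, deterministically given the seed, resampling (up to
#' `maxAttempts` times) until [coverageCheck()] passes.
#'
#' @param scheme a [GradientScheme-class].
#' @param nKeep subset size (between `nCoeffs(maxOrder)` and the scheme's
#'   direction count).
#' @param seed integer RNG seed.
#' @inheritParams coverageCheck
#' @param maxAttempts resampling budget.
#' @return sorted integer index vector of the retained directions, with
#'   the accepted [coverageCheck()] result as attribute `coverage`.
#' @export
dropoutDirections <- function(scheme, nKeep, seed = 1L, maxOrder = 8L,
                              condLimit = 1e3, maxGapDeg = 30,
                              maxAttempts = 100L) {
  stopifnot(is(scheme, "GradientScheme"))
  nd <- nDirections(scheme)
  if (nKeep < nCoeffs(maxOrder) || nKeep > nd)
    stop(sprintf("nKeep must lie in [%d, %d]", nCoeffs(maxOrder), nd))
  if (nKeep == nd) {
    idx <- seq_len(nd)
    attr(idx, "coverage") <- coverageCheck(scheme, maxOrder, condLimit, maxGapDeg)
    return(idx)
  }
  for (attempt in seq_len(maxAttempts)) {
    idx <- withSeed(deriveSeed(seed, "dropout", attempt),
                    sort(sample.int(nd, nKeep)))
    cov <- coverageCheck(subsetScheme(scheme, idx), maxOrder, condLimit,
                         maxGapDeg)
    if (cov$pass) {
      attr(idx, "coverage") <- cov
      return(idx)
    }
  }
  stop(sprintf("no %d-direction subset passed the coverage check in %d attempts",
               nKeep, maxAttempts))
}

#' Generate augmented training pairs by direction dropout
#'
#' For each accepted random subset, the signal-SH input field is refit
#' from the retained directions only, while the label stays the
#' full-direction CSD field, bit-identical across all copies -- the model
#' learns to map sparse-acquisition inputs onto the full-direction silver
#' standard.
#'
#' @param dwi a [DWIVolume-class] (full scheme).
#' @param fullLabelField the [SHField-class] of full-direction CSD fODF
#'   labels.
#' @param spec a [DropoutSpec-class].
#' @inheritParams coverageCheck
#' @return list with `inputs` (list of signal [SHField-class], one per
#'   repeat), `label` (the unchanged `fullLabelField`), `subsets` (list of
#'   index vectors) and `nKeep` (integer vector).
#' @export
augmentTrainingPairs <- function(dwi, fullLabelField, spec, maxOrder = 8L,
                                 condLimit = 1e3, maxGapDeg = 30) {
  stopifnot(is(dwi, "DWIVolume"), is(fullLabelField, "SHField"),
            is(spec, "DropoutSpec"))
  nd <- nDirections(dwi@scheme)
  if (spec@nKeepMax > nd)
    stop("nKeepMax exceeds the scheme's direction count")
  inputs <- vector("list", spec@nRepeats)
  subsets <- vector("list", spec@nRepeats)
  nKeeps <- integer(spec@nRepeats)
  for (r in seq_len(spec@nRepeats)) {
    nKeep <- if (spec@nKeepMax > spec@nKeepMin)
      withSeed(deriveSeed(spec@seed, "nkeep", r),
               sample(seq.int(spec@nKeepMin, spec@nKeepMax), 1L))
      else spec@nKeepMin
    idx <- dropoutDirections(dwi@scheme, nKeep,
                             seed = deriveSeed(spec@seed, "rep", r),
                             maxOrder = maxOrder, condLimit = condLimit,
                             maxGapDeg = maxGapDeg)
    sub <- subsetVolume(dwi, idx)
    inputs[[r]] <- dwiToSignalSH(sub, maxOrder)
    subsets[[r]] <- idx
    nKeeps[r] <- nKeep
  }
  list(inputs = inputs, label = fullLabelField, subsets = subsets,
       nKeep = nKeeps)
}

#' Restrict a DWI volume to a direction subset
#'
#' Keeps all b=0 volumes (they are never dropped) and the selected
#' diffusion-weighted volumes.
#'
#' @param dwi a [DWIVolume-class].
#' @param idx indices into the scheme's directions.
#' @return a [DWIVolume-class].
#' @export
subsetVolume <- function(dwi, idx) {
  stopifnot(is(dwi, "DWIVolume"))
  sch <- dwi@scheme
  keep <- c(seq_len(sch@nB0), sch@nB0 + idx)
  new("DWIVolume", data = dwi@data[, , , keep, drop = FALSE],
      scheme = subsetScheme(sch, idx), mask = dwi@mask)
}
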