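# Reference phantom study protocol: the fixed desk-scale experiment
# (16^3 two-bundle phantom, 96-direction b=2000 shell, scan/rescan pair
# at the default perturbation) on which model orderings are evaluated.
# These wrappers exist so that tests, scripts and users run the exact
# same protocol.

#' Single-fiber voxel mask of a phantom
#'
#' Voxels whose configuration has exactly one fiber population -- the
#' analytically known single-fiber set used for response estimation.
#'
#' @param phantom a [Phantom-class].
#' @return logical 3D array.
#' @export
singleFiberMask <- function(phantom) {
  stopifnot(is(phantom, "Phantom"))
  out <- array(FALSE, phantom@shape)
  for (i in seq_along(phantom@fiberConfigs)) {
    cfg <- phantom@fiberConfigs[[i]]
    if (!is.null(cfg) && nrow(cfg$directions) == 1L) out[i] <- TRUE
  }
  out
}

#' Deterministic train/validation/test split of interior WM voxels
#'
#' @param mask logical 3D array.
#' @param fractions length-3 numeric (train, val, test), summing to 1.
#' @param seed integer seed.
#' @return list of three logical arrays `train`, `val`, `test` (all
#'   subsets of the interior of `mask`).
#' @export
splitVoxels <- function(mask, fractions = c(0.7, 0.15, 0.15), seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  vox <- interiorVoxels(mask)
  n <- nrow(vox)
  idx <- withSeed(deriveSeed(seed, "split"), sample.int(n))
  nTr <- floor(fractions[1] * n)
  nVa <- floor(fractions[2] * n)
  sets <- list(train = idx[seq_len(nTr)],
               val = idx[nTr + seq_len(nVa)],
               test = idx[(nTr + nVa + 1L):n])
  lapply(sets, function(s) {
    m <- array(FALSE, dim(mask))
    m[vox[s, , drop = FALSE]] <- TRUE
    m
  })
}

#' Build the reference scan/rescan phantom study
#'
#' Generates the reference conditions: a two-bundle phantom, a uniform
#' single-shell scheme, a scan/rescan pair under the default perturbation
#' model, signal-SH fields, the response function (from the phantom's
#' analytic single-fiber voxels), full-direction CSD fODF fields of both
#' acquisitions (the scan field is the training label / silver standard),
#' and a deterministic train/val/test voxel split.
#'
#' @param seed integer master seed (phantom geometry, noise, split).
#' @param shape phantom grid.
#' @param nDirs,bValue,nB0 acquisition scheme parameters.
#' @param perturbation a [RescanPerturbation-class].
#' @param schemeSeed seed of the gradient scheme (fixed by default so all
#'   study replicates share one acquisition geometry).
#' @return named list with the study components.
#' @export
referenceStudy <- function(seed = 1L, shape = c(16L, 16L, 16L),
                           nDirs = 96L, bValue = 2000, nB0 = 3L,
                           perturbation = rescanPerturbation(),
                           schemeSeed = 7L) {
  scheme <- makeGradientScheme(nDirs, bValue, nB0, seed = schemeSeed)
  phantom <- makePhantom(shape, seed = seed)
  pair <- makeScanRescan(phantom, scheme, perturbation,
                         seed = deriveSeed(seed, "pair"))
  signalScan <- dwiToSignalSH(pair$scan)
  signalRescan <- dwiToSignalSH(pair$rescan)
  response <- estimateResponse(pair$scan, singleFiberMask(phantom))
  labels <- fitCsdVolume(pair$scan, wmMask(phantom), response)
  labelsRescan <- fitCsdVolume(pair$rescan, wmMask(phantom), response)
  split <- splitVoxels(wmMask(phantom), seed = seed)
  list(seed = seed, scheme = scheme, phantom = phantom, pair = pair,
       signalScan = signalScan, signalRescan = signalRescan,
       response = response, labels = labels, labelsRescan = labelsRescan,
       split = split)
}

# Validation matrices (patches + labels) for model selection.
studyValidation <- function(study) {
  vox <- which(study$split$val, arr.ind = TRUE)
  d <- dim(study$split$val)
  lin <- vox[, 1] + (vox[, 2] - 1L) * d[1] + (vox[, 3] - 1L) * d[1] * d[2]
  list(X = patchMatrix(study$signalScan, vox),
       Y = matrix(study$labels@data, ncol = dim(study$labels@data)[4L])[
         lin, , drop = FALSE])
}

#' Train a model under the reference protocol
#'
#' Fixed protocol: Adam (lr 3e-3), batch 64, up to `nSteps` steps with
#' validation-ACC model selection every 50 steps (patience 5).  Labeled
#' patches are drawn from the training voxels of the scan volume with
#' full-direction CSD labels; with `beta > 0` the scan/rescan pair
#' supplies the paired patches; with `augment = TRUE` the labeled inputs
#' additionally include `nRepeats` direction-dropout copies.
#'
#' @param study a [referenceStudy()] list.
#' @param arch `"patch_cnn"` or `"voxel_mlp"`.
#' @param beta reproducibility loss weight (alpha is fixed at 1).
#' @param augment logical: apply direction-dropout augmentation to the
#'   labeled inputs.
#' @param nSteps maximum optimization steps.
#' @param batchSize patches per group and step.
#' @param seed model initialization / stream seed.
#' @param nKeep,nRepeats dropout augmentation parameters.
#' @return a trained `dcsdModel`.
#' @export
trainStudyModel <- function(study, arch = c("patch_cnn", "voxel_mlp"),
                            beta = 0, augment = FALSE, nSteps = 400L,
                            batchSize = 64L, seed = study$seed,
                            nKeep = 45L, nRepeats = 10L) {
  arch <- match.arg(arch)
  signals <- list(study$signalScan)
  if (augment) {
    aug <- augmentTrainingPairs(
      study$pair$scan, study$labels,
      dropoutSpec(nKeepMin = nKeep, nRepeats = nRepeats,
                  seed = deriveSeed(seed, "aug")))
    signals <- c(signals, aug$inputs)
  }
  labeled <- list(list(signals = signals, label = study$labels,
                       mask = study$split$train))
  paired <- if (beta > 0)
    list(list(u = study$signalScan, v = study$signalRescan,
              mask = study$split$train)) else NULL
  stream <- sampleTriplets(labeled, paired, batchSize = batchSize,
                           seed = deriveSeed(seed, "stream"))
  model <- if (arch == "patch_cnn") buildPatchCnn(seed = seed)
           else buildVoxelMlp(seed = seed)
  trainModel(model, stream, lossWeights(1, beta), nSteps = nSteps,
             lr = 3e-3, validation = studyValidation(study))
}

#' Mean ACC of model predictions against the silver standard
#'
#' Predicts fODFs on the requested voxel subset of the scan volume and
#' returns the NA-excluding mean ACC against the full-direction CSD
#' field.
#'
#' @param model a trained `dcsdModel`.
#' @param study a [referenceStudy()] list.
#' @param subset `"test"`, `"val"`, `"train"` or `"wm"`.
#' @return list as from [meanAcc()].
#' @export
studyAccuracy <- function(model, study, subset = "test") {
  mask <- if (subset == "wm") wmMask(study$phantom) else study$split[[subset]]
  pred <- predictVolume(model, study$signalScan, mask)
  meanAcc(accMap(pred, study$labels, mask, labels = c("model", "csd-full")))
}

#' Scan/rescan consistency of model predictions
#'
#' Predicts fODFs separately from the scan and rescan signal fields at
#' the same voxels and returns the mean ACC between the two predictions
#' -- the reproducibility figure the pairing loss is designed to improve.
#'
#' @inheritParams studyAccuracy
#' @return list as from [meanAcc()].
#' @export
studyConsistency <- function(model, study, subset = "test") {
  mask <- if (subset == "wm") wmMask(study$phantom) else study$split[[subset]]
  pu <- predictVolume(model, study$signalScan, mask)
  pv <- predictVolume(model, study$signalRescan, mask)
  meanAcc(accMap(pu, pv, mask, labels = c("scan", "rescan")))
}

#' Scan/rescan consistency of CSD itself
#'
#' Mean ACC between the full-direction CSD fields of the scan and the
#' rescan -- the model-free baseline that quantifies how much acquisition
#' variability leaks into conventional CSD estimates.
#'
#' @inheritParams studyAccuracy
#' @return list as from [meanAcc()].
#' @export
csdConsistency <- function(study, subset = "test") {
  mask <- if (subset == "wm") wmMask(study$phantom) else study$split[[subset]]
  meanAcc(accMap(study$labels, study$labelsRescan, mask,
                 labels = c("csd-scan", "csd-rescan")))
}

#' Direction-dropout comparison: augmented model vs reduced-direction CSD
#'
#' For `nRepeats` accepted random `nKeep`-direction subsets of the scan,
#' compares two routes to the full-direction silver standard on the test
#' voxels: (a) the model's prediction from the subset's signal-SH field
#' and (b) CSD refit from the subset.  Returns the per-repeat mean ACC of
#' both routes.
#'
#' @param model a trained (typically augmented) `dcsdModel`.
#' @param study a [referenceStudy()] list.
#' @param nKeep retained directions per repeat.
#' @param nRepeats number of random dropouts.
#' @param seed subset stream seed.
#' @param subset voxel subset to evaluate on.
#' @return data.frame with columns `repeat_`, `accModel`, `accCsd`.
#' @export
dropoutComparison <- function(model, study, nKeep = 45L, nRepeats = 10L,
                              seed = study$seed, subset = "test") {
  mask <- if (subset == "wm") wmMask(study$phantom) else study$split[[subset]]
  out <- data.frame(repeat_ = seq_len(nRepeats), accModel = NA_real_,
                    accCsd = NA_real_)
  for (r in seq_len(nRepeats)) {
    idx <- dropoutDirections(study$scheme, nKeep,
                             seed = deriveSeed(seed, "cmp", r))
    sub <- subsetVolume(study$pair$scan, idx)
    sigSub <- dwiToSignalSH(sub)
    pred <- predictVolume(model, sigSub, mask)
    out$accModel[r] <- meanAcc(accMap(pred, study$labels, mask))$mean
    csdSub <- fitCsdVolume(sub, mask, study$response)
    out$accCsd[r] <- meanAcc(accMap(csdSub, study$labels, mask))$mean
  }
  out
}
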