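# The learning core: a 3x3x3-patch residual CNN and a voxel-wise MLP
# mapping signal-SH inputs to fODF-SH outputs, the accuracy +
# scan/rescan-reproducibility loss, triplet sampling, training and volume
# inference.
#
# Patch memory layout: a batch of patches is a matrix [N x 27*nCh] whose
# column (v-1)*nCh + c holds channel c of patch voxel v, with voxels
# enumerated x-fastest over the 3x3x3 cube (center voxel v = 14).

PATCH_VOXELS <- 27L
CENTER_VOXEL <- 14L

# ---------------------------------------------------------------------------
# architectures

#' Build the 3x3x3-patch residual CNN
#'
#' Three convolutional layers (conv1: 1x1x1 kernel, 45 filters; conv2:
#' 3x3x3 kernel, zero padding 1, 45 filters; conv3: 3x3x3 kernel, no
#' padding, 45 filters) followed by two dense layers predicting the 45
#' fODF coefficients of the patch's center voxel.  A residual shortcut
#' adds the conv1 activation to the conv3 output; since conv3 reduces the
#' patch to 1x1x1 while conv1 preserves 3x3x3, the shortcut takes either
#' the center voxel of the conv1 activation (default) or its spatial
#' average, selected by `shortcut`.  Hidden layers use batch normalization
#' (after the affine, before the activation) and ReLU; the output layer is
#' linear, as SH coefficients are signed.
#'
#' @param nCoef channels per voxel (45 for order 8).
#' @param hidden width of the first dense layer.
#' @param seed integer seed for the (He-normal) initialization.
#' @param shortcut `"center"` or `"avgpool"`.
#' @return a `dcsdModel` object.
#' @export
buildPatchCnn <- function(nCoef = 45L, hidden = 200L, seed = 1L,
                          shortcut = c("center", "avgpool")) {
  shortcut <- match.arg(shortcut)
  params <- withSeed(deriveSeed(seed, "init", "cnn"), list(
    W1 = nnInitMatrix(nCoef, nCoef), b1 = numeric(nCoef),
    g1 = rep(1, nCoef), be1 = numeric(nCoef),
    W2 = nnInitMatrix(PATCH_VOXELS * nCoef, nCoef), b2 = numeric(nCoef),
    g2 = rep(1, nCoef), be2 = numeric(nCoef),
    W3 = nnInitMatrix(PATCH_VOXELS * nCoef, nCoef), b3 = numeric(nCoef),
    g3 = rep(1, nCoef), be3 = numeric(nCoef),
    Wd1 = nnInitMatrix(nCoef, hidden), bd1 = numeric(hidden),
    g4 = rep(1, hidden), be4 = numeric(hidden),
    Wd2 = nnInitMatrix(hidden, nCoef), bd2 = numeric(nCoef)
  ))
  structure(list(
    arch = "patch_cnn", nCoef = as.integer(nCoef), hidden = as.integer(hidden),
    shortcut = shortcut, seed = as.integer(seed), params = params,
    bn = list(bn1 = bnStateInit(nCoef), bn2 = bnStateInit(nCoef),
              bn3 = bnStateInit(nCoef), bn4 = bnStateInit(hidden))
  ), class = "dcsdModel")
}

#' Build the voxel-wise MLP baseline
#'
#' Four fully connected layers of widths 400, 45, 200 and 45 mapping a
#' single voxel's 45 signal-SH coefficients to its 45 fODF coefficients;
#' ReLU on hidden layers, linear output.
#'
#' @inheritParams buildPatchCnn
#' @param widths hidden/output layer widths.
#' @return a `dcsdModel` object.
#' @export
buildVoxelMlp <- function(nCoef = 45L, widths = c(400L, 45L, 200L, 45L),
                          seed = 1L) {
  stopifnot(length(widths) == 4L, widths[4] == nCoef)
  d <- c(nCoef, widths)
  params <- withSeed(deriveSeed(seed, "init", "mlp"), {
    p <- list()
    for (i in 1:4) {
      p[[paste0("W", i)]] <- nnInitMatrix(d[i], d[i + 1])
      p[[paste0("b", i)]] <- numeric(d[i + 1])
    }
    p
  })
  structure(list(arch = "voxel_mlp", nCoef = as.integer(nCoef),
                 widths = as.integer(widths), seed = as.integer(seed),
                 params = params, bn = list()),
            class = "dcsdModel")
}

#' @export
print.dcsdModel <- function(x, ...) {
  cat(sprintf("dcsdModel <%s>: %d parameters (%d SH channels)\n",
              x$arch, modelParameterCount(x), x$nCoef))
  invisible(x)
}

#' Total trainable parameter count of a model
#'
#' @param model a `dcsdModel`.
#' @return integer.
#' @export
modelParameterCount <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# conv2 source-voxel table: for output voxel v and kernel offset slot t,
# the input voxel index (1..27) or 28 for the zero pad.
conv2SourceTable <- function() {
  coords <- as.matrix(expand.grid(i = 1:3, j = 1:3, k = 1:3))
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  src <- matrix(28L, PATCH_VOXELS, PATCH_VOXELS) # [t, vout]
  for (t in 1:PATCH_VOXELS) for (v in 1:PATCH_VOXELS) {
    p <- coords[v, ] + offs[t, ]
    if (all(p >= 1L & p <= 3L))
      src[t, v] <- which(coords[, 1] == p[1] & coords[, 2] == p[2] &
                           coords[, 3] == p[3])
  }
  src
}
.conv2Src <- conv2SourceTable()

# layout helpers: patch matrix [N x 27*nCh] <-> voxel-major [(27N) x nCh]
toVoxMajor <- function(X, nCh) {
  N <- nrow(X)
  matrix(aperm(array(X, c(N, nCh, PATCH_VOXELS)), c(1L, 3L, 2L)),
         N * PATCH_VOXELS, nCh)
}

fromVoxMajor <- function(M, nCh) {
  N <- nrow(M) / PATCH_VOXELS
  matrix(aperm(array(M, c(N, PATCH_VOXELS, nCh)), c(1L, 3L, 2L)),
         N, nCh * PATCH_VOXELS)
}

# zero-padded im2col on the 3x3x3 grid (voxel-major input)
conv2Im2col <- function(M, nCh) {
  N <- nrow(M) / PATCH_VOXELS
  Mz <- rbind(M, matrix(0, N, nCh)) # pad block = voxel 28
  out <- matrix(0, N * PATCH_VOXELS, PATCH_VOXELS * nCh)
  base <- seq_len(N)
  for (t in 1:PATCH_VOXELS) {
    idx <- rep((.conv2Src[t, ] - 1L) * N, each = N) + base
    out[, (t - 1L) * nCh + seq_len(nCh)] <- Mz[idx, ]
  }
  out
}

conv2Col2im <- function(dXcol, nCh) {
  N <- nrow(dXcol) / PATCH_VOXELS
  dMz <- matrix(0, N * (PATCH_VOXELS + 1L), nCh)
  base <- seq_len(N)
  for (t in 1:PATCH_VOXELS) {
    idx <- rep((.conv2Src[t, ] - 1L) * N, each = N) + base
    dMz[idx, ] <- dMz[idx, ] + dXcol[, (t - 1L) * nCh + seq_len(nCh)]
  }
  dMz[seq_len(N * PATCH_VOXELS), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# forward / backward

modelForward <- function(model, X, training = FALSE) {
  if (model$arch == "patch_cnn") patchCnnForward(model, X, training)
  else mlpForward(model, X, training)
}

patchCnnForward <- function(model, X, training) {
  p <- model$params; nCh <- model$nCoef
  N <- nrow(X)
  M0 <- toVoxMajor(X, nCh)                       # (27N) x 45
  a1 <- affineForward(M0, p$W1, p$b1)            # conv1 (1x1x1)
  n1 <- bnForward(a1$Y, p$g1, p$be1, model$bn$bn1, training)
  r1 <- reluForward(n1$Y)
  x2 <- conv2Im2col(r1$Y, nCh)                   # conv2 (3x3x3, pad 1)
  a2 <- affineForward(x2, p$W2, p$b2)
  n2 <- bnForward(a2$Y, p$g2, p$be2, model$bn$bn2, training)
  r2 <- reluForward(n2$Y)
  x3 <- fromVoxMajor(r2$Y, nCh)                  # conv3 (3x3x3, valid)
  a3 <- affineForward(x3, p$W3, p$b3)
  ctrRows <- (CENTER_VOXEL - 1L) * N + seq_len(N)
  sc <- if (model$shortcut == "center") r1$Y[ctrRows, , drop = FALSE]
        else apply(array(r1$Y, c(N, PATCH_VOXELS, nCh)), c(1L, 3L), mean)
  y3 <- a3$Y + sc                                # residual shortcut
  n3 <- bnForward(y3, p$g3, p$be3, model$bn$bn3, training)
  r3 <- reluForward(n3$Y)
  a4 <- affineForward(r3$Y, p$Wd1, p$bd1)        # dense 1
  n4 <- bnForward(a4$Y, p$g4, p$be4, model$bn$bn4, training)
  r4 <- reluForward(n4$Y)
  a5 <- affineForward(r4$Y, p$Wd2, p$bd2)        # dense 2 (linear)
  list(pred = a5$Y,
       cache = list(N = N, ctrRows = ctrRows, a1 = a1, n1 = n1, r1 = r1,
                    x2 = x2, a2 = a2, n2 = n2, r2 = r2, a3 = a3, n3 = n3,
                    r3 = r3, a4 = a4, n4 = n4, r4 = r4, a5 = a5))
}

patchCnnBackward <- function(model, cache, dPred) {
  p <- model$params; nCh <- model$nCoef
  N <- cache$N
  g <- list()
  b5 <- affineBackward(cache$a5, p$Wd2, dPred)
  g$Wd2 <- b5$dW; g$bd2 <- b5$db
  dr4 <- reluBackward(cache$r4, b5$dX)
  b4 <- bnBackward(cache$n4, p$g4, dr4)
  g$g4 <- b4$dgamma; g$be4 <- b4$dbeta
  ba4 <- affineBackward(cache$a4, p$Wd1, b4$dX)
  g$Wd1 <- ba4$dW; g$bd1 <- ba4$db
  dr3 <- reluBackward(cache$r3, ba4$dX)
  b3 <- bnBackward(cache$n3, p$g3, dr3)
  g$g3 <- b3$dgamma; g$be3 <- b3$dbeta
  dy3 <- b3$dX
  ba3 <- affineBackward(cache$a3, p$W3, dy3)
  g$W3 <- ba3$dW; g$b3 <- ba3$db
  dr2 <- reluBackward(cache$r2, toVoxMajor(ba3$dX, nCh))
  b2 <- bnBackward(cache$n2, p$g2, dr2)
  g$g2 <- b2$dgamma; g$be2 <- b2$dbeta
  ba2 <- affineBackward(cache$a2, p$W2, b2$dX)
  g$W2 <- ba2$dW; g$b2 <- ba2$db
  dr1 <- conv2Col2im(ba2$dX, nCh)
  if (model$shortcut == "center") {
    dr1[cache$ctrRows, ] <- dr1[cache$ctrRows, ] + dy3
  } else {
    spread <- dy3 / PATCH_VOXELS
    for (v in 1:PATCH_VOXELS)
      dr1[(v - 1L) * N + seq_len(N), ] <-
        dr1[(v - 1L) * N + seq_len(N), ] + spread
  }
  dr1 <- reluBackward(cache$r1, dr1)
  b1 <- bnBackward(cache$n1, p$g1, dr1)
  g$g1 <- b1$dgamma; g$be1 <- b1$dbeta
  ba1 <- affineBackward(cache$a1, p$W1, b1$dX)
  g$W1 <- ba1$dW; g$b1 <- ba1$db
  g
}

mlpForward <- function(model, X, training) {
  p <- model$params
  # patch input: use the center voxel only
  if (ncol(X) == PATCH_VOXELS * model$nCoef)
    X <- X[, (CENTER_VOXEL - 1L) * model$nCoef + seq_len(model$nCoef),
           drop = FALSE]
  a1 <- affineForward(X, p$W1, p$b1); r1 <- reluForward(a1$Y)
  a2 <- affineForward(r1$Y, p$W2, p$b2); r2 <- reluForward(a2$Y)
  a3 <- affineForward(r2$Y, p$W3, p$b3); r3 <- reluForward(a3$Y)
  a4 <- affineForward(r3$Y, p$W4, p$b4)
  list(pred = a4$Y, cache = list(a1 = a1, r1 = r1, a2 = a2, r2 = r2,
                                 a3 = a3, r3 = r3, a4 = a4))
}

mlpBackward <- function(model, cache, dPred) {
  p <- model$params
  g <- list()
  b4 <- affineBackward(cache$a4, p$W4, dPred); g$W4 <- b4$dW; g$b4 <- b4$db
  d3 <- reluBackward(cache$r3, b4$dX)
  b3 <- affineBackward(cache$a3, p$W3, d3); g$W3 <- b3$dW; g$b3 <- b3$db
  d2 <- reluBackward(cache$r2, b3$dX)
  b2 <- affineBackward(cache$a2, p$W2, d2); g$W2 <- b2$dW; g$b2 <- b2$db
  d1 <- reluBackward(cache$r1, b2$dX)
  b1 <- affineBackward(cache$a1, p$W1, d1); g$W1 <- b1$dW; g$b1 <- b1$db
  g
}

modelBackward <- function(model, cache, dPred) {
  if (model$arch == "patch_cnn") patchCnnBackward(model, cache, dPred)
  else mlpBackward(model, cache, dPred)
}

# ---------------------------------------------------------------------------
# losses

#' Accuracy loss: mean over samples of the summed squared coefficient error
#'
#' \deqn{L_1 = \frac{1}{N} \sum_{i=1}^N \sum_{k,m}
#'   ((c_k^m)_{true,i} - (c_k^m)_{pred,i})^2}
#' summed over all coefficients including order 0, averaged over the batch.
#'
#' @param pred,truth numeric matrices `[N x nCoef]`.
#' @return scalar loss.
#' @export
lossFit <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  sum((truth - pred)^2) / nrow(pred)
}

#' Reproducibility loss: mean summed squared difference of paired outputs
#'
#' \deqn{L_2 = \frac{1}{N} \sum_{i=1}^N \sum_{k,m}
#'   ((c_k^m)_{u,i} - (c_k^m)_{v,i})^2}
#' over predictions for corresponding scan/rescan voxels; its expectation
#' is 0 for a perfectly reproducible estimator.
#'
#' @param predU,predV numeric matrices `[N x nCoef]`.
#' @return scalar loss.
#' @export
lossPair <- function(predU, predV) {
  if (!identical(dim(predU), dim(predV))) stop("shape mismatch")
  sum((predU - predV)^2) / nrow(predU)
}

#' Total loss: weighted sum of accuracy and reproducibility terms
#'
#' `alpha * loss1 + beta * loss2`; `beta` is 0 when no scan/rescan data
#' participate in training.
#'
#' @param loss1,loss2 non-negative scalars.
#' @param weights list with non-negative `alpha` and `beta` (see
#'   [lossWeights()]).
#' @return scalar.
#' @export
lossTotal <- function(loss1, loss2, weights) {
  if (weights$alpha < 0 || weights$beta < 0)
    stop("loss weights must be non-negative")
  weights$alpha * loss1 + weights$beta * loss2
}

#' Loss weights
#'
#' @param alpha weight of the accuracy term.
#' @param beta weight of the scan/rescan reproducibility term; set 0 when
#'   no paired data are supplied.
#' @return list with `alpha` and `beta`.
#' @export
lossWeights <- function(alpha = 1, beta = 1) {
  if (alpha < 0 || beta < 0) stop("loss weights must be non-negative")
  list(alpha = alpha, beta = beta)
}

# ---------------------------------------------------------------------------
# patch extraction and triplet sampling

# Interior voxels of a mask: full 3x3x3 neighborhood inside the volume.
interiorVoxels <- function(mask) {
  d <- dim(mask)
  vox <- which(mask, arr.ind = TRUE)
  keep <- vox[, 1] > 1L & vox[, 1] < d[1] & vox[, 2] > 1L & vox[, 2] < d[2] &
    vox[, 3] > 1L & vox[, 3] < d[3]
  vox[keep, , drop = FALSE]
}

#' Extract 3x3x3 patches around voxels of an SH field
#'
#' Returns one row per voxel in the packed patch layout (channel fastest
#' within each of the 27 cube voxels, x-fastest cube enumeration).  All
#' voxels must have their full neighborhood inside the volume unless the
#' field has been reflect-padded upstream.
#'
#' @param field an [SHField-class].
#' @param voxels integer matrix `[n x 3]` of 1-based center coordinates.
#' @return numeric matrix `[n x 27*nCoef]`.
#' @export
patchMatrix <- function(field, voxels) {
  arr <- field@data
  d <- dim(arr)
  nCh <- d[4L]
  nvox <- prod(d[1:3])
  Fmat <- matrix(arr, nvox, nCh)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  out <- matrix(0, nrow(voxels), PATCH_VOXELS * nCh)
  for (v in 1:PATCH_VOXELS) {
    lin <- (voxels[, 1] + offs[v, 1]) +
      (voxels[, 2] + offs[v, 2] - 1L) * d[1] +
      (voxels[, 3] + offs[v, 3] - 1L) * d[1] * d[2]
    out[, (v - 1L) * nCh + seq_len(nCh)] <- Fmat[lin, , drop = FALSE]
  }
  out
}

#' Deterministic triplet batch stream for training
#'
#' Assembles the three patch groups of each training step: labeled patches
#' (signal-SH input, full-direction CSD label at the center voxel) from
#' the labeled volumes, and paired patches extracted at identical voxel
#' coordinates from the two volumes of a scan/rescan pair.  When a labeled
#' entry carries several input fields (direction-dropout augmentation),
#' each sample draws one at random; labels never change.  The stream is a
#' function of the step index and is fully deterministic given the seed.
#'
#' @param labeled list of entries, each a list with `signals` (list of one
#'   or more signal [SHField-class]s), `label` (fODF [SHField-class]) and
#'   `mask` (logical array).
#' @param paired list of entries, each a list with `u`, `v` (signal
#'   [SHField-class]s of a registered scan/rescan pair) and `mask`; may be
#'   `NULL` when training without the reproducibility term.
#' @param batchSize patches per group and step.
#' @param seed integer stream seed.
#' @return function `(step)` returning a list with `X`, `Y` and, when
#'   paired data exist, `U`, `V` (matrices in the packed patch layout).
#' @export
sampleTriplets <- function(labeled, paired = NULL, batchSize = 64L,
                           seed = 1L) {
  prepL <- lapply(labeled, function(e) {
    vox <- interiorVoxels(e$mask)
    if (nrow(vox) == 0L) stop("a labeled volume has no interior WM voxels")
    nCh <- dim(e$label@data)[4L]
    labMat <- matrix(e$label@data, ncol = nCh)[
      vox[, 1] + (vox[, 2] - 1L) * dim(e$mask)[1] +
        (vox[, 3] - 1L) * dim(e$mask)[1] * dim(e$mask)[2], , drop = FALSE]
    list(patches = lapply(e$signals, patchMatrix, voxels = vox),
         labels = labMat, n = nrow(vox))
  })
  prepP <- if (!is.null(paired)) lapply(paired, function(e) {
    vox <- interiorVoxels(e$mask)
    if (nrow(vox) == 0L) stop("a paired volume has no interior WM voxels")
    list(u = patchMatrix(e$u, vox), v = patchMatrix(e$v, vox), n = nrow(vox))
  }) else NULL
  function(step) {
    withSeed(deriveSeed(seed, "batch", step), {
      li <- sample.int(length(prepL), batchSize, replace = TRUE)
      out <- list()
      rows <- vapply(li, function(i) sample.int(prepL[[i]]$n, 1L), integer(1))
      fld <- vapply(li, function(i)
        sample.int(length(prepL[[i]]$patches), 1L), integer(1))
      out$X <- do.call(rbind, lapply(seq_len(batchSize), function(s)
        prepL[[li[s]]]$patches[[fld[s]]][rows[s], , drop = FALSE]))
      out$Y <- do.call(rbind, lapply(seq_len(batchSize), function(s)
        prepL[[li[s]]]$labels[rows[s], , drop = FALSE]))
      if (!is.null(prepP)) {
        pi_ <- sample.int(length(prepP), batchSize, replace = TRUE)
        prow <- vapply(pi_, function(i) sample.int(prepP[[i]]$n, 1L), integer(1))
        out$U <- do.call(rbind, lapply(seq_len(batchSize), function(s)
          prepP[[pi_[s]]]$u[prow[s], , drop = FALSE]))
        out$V <- do.call(rbind, lapply(seq_len(batchSize), function(s)
          prepP[[pi_[s]]]$v[prow[s], , drop = FALSE]))
      }
      out
    })
  }
}

# ---------------------------------------------------------------------------
# training

#' Train a model with the combined accuracy/reproducibility loss
#'
#' Runs Adam on the total loss: each step forwards the labeled batch and,
#' when `weights$beta > 0`, the paired scan/rescan batches through the
#' same network, backpropagates `alpha * loss1 + beta * loss2`, and
#' updates the weights.  Model selection: when a validation set is given,
#' the mean validation ACC is evaluated every `valEvery` steps, the best
#' parameters are kept, and training stops early after `patience`
#' evaluations without improvement.  Bit-reproducible given (model seed,
#' stream seed).
#'
#' @param model a `dcsdModel` from [buildPatchCnn()] or [buildVoxelMlp()].
#' @param stream a batch stream from [sampleTriplets()].
#' @param weights a [lossWeights()] list.
#' @param nSteps maximum optimization steps.
#' @param lr Adam learning rate.
#' @param validation optional list with `X` (patch matrix) and `Y` (label
#'   matrix) for model selection.
#' @param valEvery validation period (steps).
#' @param patience early-stopping patience (validation rounds).
#' @param trainable optional character vector of parameter names to
#'   update (finetuning); others stay frozen.
#' @return the trained `dcsdModel` with a `history` data.frame (step,
#'   loss1, loss2, total) and `valAcc` attached.
#' @export
trainModel <- function(model, stream, weights = lossWeights(1, 0),
                       nSteps = 400L, lr = 1e-3, validation = NULL,
                       valEvery = 50L, patience = 5L, trainable = NULL) {
  opt <- adamInit(model$params)
  hist <- data.frame(step = integer(0), loss1 = numeric(0),
                     loss2 = numeric(0), total = numeric(0))
  best <- list(acc = -Inf, params = model$params,
               bn = lapply(model$bn, bnStateClone))
  badRounds <- 0L
  for (step in seq_len(nSteps)) {
    b <- stream(step)
    N <- nrow(b$X)
    fw <- modelForward(model, b$X, training = TRUE)
    l1 <- lossFit(fw$pred, b$Y)
    grads <- modelBackward(model, fw$cache,
                           weights$alpha * 2 * (fw$pred - b$Y) / N)
    l2 <- 0
    if (weights$beta > 0) {
      if (is.null(b$U))
        stop("beta > 0 requires paired scan/rescan batches in the stream")
      fu <- modelForward(model, b$U, training = TRUE)
      fv <- modelForward(model, b$V, training = TRUE)
      l2 <- lossPair(fu$pred, fv$pred)
      dU <- weights$beta * 2 * (fu$pred - fv$pred) / N
      grads <- addGrads(grads, modelBackward(model, fu$cache, dU))
      grads <- addGrads(grads, modelBackward(model, fv$cache, -dU))
    }
    tot <- lossTotal(l1, l2, weights)
    if (!is.finite(tot))
      stop(sprintf("non-finite loss at step %d (loss1=%g, loss2=%g)",
                   step, l1, l2))
    hist[nrow(hist) + 1L, ] <- list(step, l1, l2, tot)
    upd <- adamStep(model$params, grads, opt, lr = lr, trainable = trainable)
    model$params <- upd$params
    opt <- upd$state
    if (!is.null(validation) && (step %% valEvery == 0L || step == nSteps)) {
      va <- validationAcc(model, validation)
      if (va > best$acc) {
        best <- list(acc = va, params = model$params,
                     bn = lapply(model$bn, bnStateClone))
        badRounds <- 0L
      } else {
        badRounds <- badRounds + 1L
        if (badRounds >= patience) break
      }
    }
  }
  if (!is.null(validation) && is.finite(best$acc)) {
    model$params <- best$params
    model$bn <- best$bn
    model$valAcc <- best$acc
  }
  model$history <- hist
  model
}

# Mean ACC of model predictions against labels (inference mode).
validationAcc <- function(model, validation) {
  pred <- modelForward(model, validation$X, training = FALSE)$pred
  U <- pred[, -1L, drop = FALSE]
  V <- validation$Y[, -1L, drop = FALSE]
  nu <- sqrt(rowSums(U^2)); nv <- sqrt(rowSums(V^2))
  ok <- nu > 0 & nv > 0
  if (!any(ok)) return(-Inf)
  mean(rowSums(U[ok, , drop = FALSE] * V[ok, , drop = FALSE]) /
         (nu[ok] * nv[ok]))
}

#' Parameter names of the two dense head layers
#'
#' Convenience for the finetuning protocol in which all layers except the
#' final two dense layers are frozen.
#'
#' @param model a `dcsdModel`.
#' @return character vector usable as `trainable` in [trainModel()].
#' @export
denseHeadParameters <- function(model) {
  if (model$arch == "patch_cnn")
    c("Wd1", "bd1", "g4", "be4", "Wd2", "bd2")
  else c("W3", "b3", "W4", "b4")
}

# ---------------------------------------------------------------------------
# inference

#' Predict an fODF field from a signal-SH field
#'
#' Applies the trained model to the 3x3x3 neighborhood of every mask
#' voxel (reflect-padded at the volume border) in inference mode (batch
#' normalization uses running statistics); voxels outside the mask are
#' zero.  Deterministic.
#'
#' @param model a trained `dcsdModel`.
#' @param signalField [SHField-class] of kind `"signal"`, order matching
#'   the model.
#' @param mask logical 3D array.
#' @param batchSize voxels per forward pass.
#' @return an [SHField-class] of kind `"fodf"`.
#' @export
predictVolume <- function(model, signalField, mask, batchSize = 1024L) {
  stopifnot(is(signalField, "SHField"))
  d <- dim(signalField@data)
  if (d[4L] != model$nCoef)
    stop(sprintf("field has %d coefficients; model expects %d", d[4L],
                 model$nCoef))
  if (!identical(dim(mask), d[1:3])) stop("mask shape mismatch")
  # reflect padding by one voxel on each side
  ix <- c(2L, seq_len(d[1]), d[1] - 1L)
  iy <- c(2L, seq_len(d[2]), d[2] - 1L)
  iz <- c(2L, seq_len(d[3]), d[3] - 1L)
  padded <- SHField(signalField@data[ix, iy, iz, , drop = FALSE],
                    signalField@basis, signalField@voxelSize, kind = "signal")
  vox <- which(mask, arr.ind = TRUE)
  out <- array(0, c(d[1:3], model$nCoef))
  outMat <- matrix(out, prod(d[1:3]), model$nCoef)
  if (nrow(vox)) {
    for (start in seq(1L, nrow(vox), by = batchSize)) {
      sel <- start:min(start + batchSize - 1L, nrow(vox))
      X <- patchMatrix(padded, vox[sel, , drop = FALSE] + 1L)
      pred <- modelForward(model, X, training = FALSE)$pred
      lin <- vox[sel, 1] + (vox[sel, 2] - 1L) * d[1] +
        (vox[sel, 3] - 1L) * d[1] * d[2]
      outMat[lin, ] <- pred
    }
  }
  SHField(array(outMat, c(d[1:3], model$nCoef)), signalField@basis,
          signalField@voxelSize, kind = "fodf")
}
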