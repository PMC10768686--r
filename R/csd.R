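# Single-shell single-tissue constrained spherical deconvolution:
# response estimation, spherical forward convolution, the iterative
# hard-threshold nonnegativity-constrained fit, volume fitting and fODF
# peak extraction.

# Memoized symmetric sphere grids with their SH design matrices.
.sphereCache <- new.env(parent = emptyenv())

sphereGrid <- function(n = 724L, maxOrder = 8L) {
  key <- sprintf("n%d_L%d", n, maxOrder)
  if (is.null(.sphereCache[[key]])) {
    pts <- fibonacciSphereSym(n)
    .sphereCache[[key]] <- list(points = pts,
                                design = shDesignMatrix(pts, maxOrder))
  }
  .sphereCache[[key]]
}

# Nearest-neighbor index matrix on the grid (for local-maximum search).
sphereNeighbors <- function(n = 724L, k = 8L) {
  key <- sprintf("nb_n%d_k%d", n, k)
  if (is.null(.sphereCache[[key]])) {
    pts <- sphereGrid(n)$points
    Gdot <- pts %*% t(pts)
    diag(Gdot) <- -Inf
    .sphereCache[[key]] <- t(apply(Gdot, 1L, function(r)
      order(r, decreasing = TRUE)[seq_len(k)]))
  }
  .sphereCache[[key]]
}

#' Single-fiber response function estimation
#'
#' For each voxel of the single-fiber mask, the diffusion-weighted signal
#' (normalized by the voxel's mean b=0) is reoriented so that the principal
#' axis of a log-linear tensor fit aligns with +z; the pooled reoriented
#' samples are then fit with the m=0 (zonal) even-order SH terms, giving
#' one kernel coefficient per even order.  Deterministic.
#'
#' @param dwi a [DWIVolume-class].
#' @param singleFiberMask logical 3D array marking single-fiber voxels.
#' @inheritParams nCoeffs
#' @return a [ResponseFunction-class] (s0 = 1: the kernel is expressed on
#'   b0-normalized signals).
#' @export
estimateResponse <- function(dwi, singleFiberMask, maxOrder = 8L) {
  stopifnot(is(dwi, "DWIVolume"))
  vox <- which(singleFiberMask, arr.ind = TRUE)
  if (nrow(vox) == 0L) stop("single-fiber mask is empty")
  sch <- dwi@scheme
  G <- sch@directions
  nd <- nrow(G)
  dirsAll <- vector("list", nrow(vox))
  ampsAll <- vector("list", nrow(vox))
  for (i in seq_len(nrow(vox))) {
    s <- dwi@data[vox[i, 1], vox[i, 2], vox[i, 3], ]
    s0 <- if (sch@nB0 > 0) mean(s[seq_len(sch@nB0)]) else 1
    if (s0 <= 0) next
    amp <- s[sch@nB0 + seq_len(nd)] / s0
    e1 <- tensorPrincipalAxis(amp, G, sch@bValue)
    R <- rotationToZ(e1)
    dirsAll[[i]] <- G %*% t(R)
    ampsAll[[i]] <- amp
  }
  D <- do.call(rbind, dirsAll)
  A <- unlist(ampsAll)
  if (is.null(D)) stop("no usable voxels in the single-fiber mask")
  idx <- shIndexTable(maxOrder)
  B <- shDesignMatrix(D / sqrt(rowSums(D^2)), maxOrder)
  Bz <- B[, idx$m == 0L, drop = FALSE]
  zonal <- qr.solve(Bz, A)
  new("ResponseFunction", zonal = as.numeric(zonal),
      maxOrder = as.integer(maxOrder), s0 = 1)
}

# Principal diffusion axis from a log-linear tensor fit on b>0 samples.
tensorPrincipalAxis <- function(amp, directions, bValue) {
  y <- -log(pmax(amp, 1e-6)) / bValue
  G <- directions
  X <- cbind(G[, 1]^2, G[, 2]^2, G[, 3]^2,
             2 * G[, 1] * G[, 2], 2 * G[, 1] * G[, 3], 2 * G[, 2] * G[, 3])
  d <- qr.solve(X, y)
  Dt <- matrix(c(d[1], d[4], d[5], d[4], d[2], d[6], d[5], d[6], d[3]), 3, 3)
  ev <- eigen(Dt, symmetric = TRUE)
  ev$vectors[, 1L]
}

# Rotation taking unit vector v to +z.
rotationToZ <- function(v) {
  v <- v / sqrt(sum(v^2))
  z <- c(0, 0, 1)
  c_ <- sum(v * z)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  axis <- c(v[2] * z[3] - v[3] * z[2], v[3] * z[1] - v[1] * z[3],
            v[1] * z[2] - v[2] * z[1])
  rotationMatrix(axis, acos(c_))
}

# Per-coefficient convolution scale factors of a zonal kernel.
convolutionScale <- function(response, maxOrder = response@maxOrder) {
  idx <- shIndexTable(maxOrder)
  r <- response@zonal[idx$k / 2L + 1L]
  r * sqrt(4 * pi / (2 * idx$k + 1))
}

#' Forward spherical convolution with a zonal kernel
#'
#' Maps fODF coefficients to signal-SH coefficients by the spherical
#' convolution theorem: each coefficient is scaled by
#' \eqn{r_k \sqrt{4\pi/(2k+1)}} where \eqn{r_k} is the kernel's zonal
#' coefficient of order k.  Linear in both arguments.
#'
#' @param fodf coefficient vector (length `nCoeffs(maxOrder)` of the
#'   response's order).
#' @param response a [ResponseFunction-class].
#' @return signal-SH coefficient vector of the same length.
#' @export
forwardConvolve <- function(fodf, response) {
  stopifnot(is(response, "ResponseFunction"))
  nc <- nCoeffs(response@maxOrder)
  if (length(fodf) != nc)
    stop(sprintf("fODF has %d coefficients; response order %d requires %d",
                 length(fodf), response@maxOrder, nc))
  as.numeric(fodf * convolutionScale(response))
}

#' Response whose convolution scale factors are all 1
#'
#' Identity kernel for testing: `forwardConvolve` with it is the identity
#' map.
#'
#' @inheritParams nCoeffs
#' @return a [ResponseFunction-class].
#' @export
identityResponse <- function(maxOrder = 8L) {
  ks <- seq(0L, as.integer(maxOrder), by = 2L)
  new("ResponseFunction", zonal = sqrt((2 * ks + 1) / (4 * pi)),
      maxOrder = as.integer(maxOrder), s0 = 1)
}

# Precompute the per-scheme deconvolution system shared by all voxels.
csdPrecompute <- function(scheme, response, maxOrder = 8L, lambda = 1,
                          nSphere = 724L) {
  B <- shDesignMatrix(scheme@directions, maxOrder)
  scale <- convolutionScale(response, maxOrder)
  A <- sweep(B, 2L, scale, "*") # fODF coeffs -> signal amplitudes
  sg <- sphereGrid(nSphere, maxOrder)
  idx <- shIndexTable(maxOrder)
  list(A = A, AtA = crossprod(A), P = sg$design, lambda = lambda,
       order4 = which(idx$k <= 4L), maxOrder = maxOrder)
}

#' Constrained spherical deconvolution of one voxel
#'
#' Tournier-style iterative hard-threshold CSD: the fit is initialized
#' from the unconstrained deconvolution truncated at order 4; at each
#' iteration, constraint-sphere amplitudes below `tau` times the mean
#' initial amplitude define an active set penalized with weight `lambda`,
#' and the penalized least-squares system is re-solved.  Iteration stops
#' when the active set stabilizes or after `nIter` iterations.
#'
#' @param amplitudes b0-normalized diffusion-weighted amplitudes, one per
#'   scheme direction.
#' @param scheme a [GradientScheme-class].
#' @param response a [ResponseFunction-class].
#' @inheritParams nCoeffs
#' @param lambda nonnegativity penalty weight.
#' @param tau relative amplitude threshold defining the active set.
#' @param nIter maximum iterations.
#' @param nSphere size of the symmetric constraint sphere (>= 300).
#' @return fODF coefficient vector with attributes `iterations` and
#'   `converged`.
#' @export
csdFit <- function(amplitudes, scheme, response, maxOrder = 8L, lambda = 1,
                   tau = 0.1, nIter = 50L, nSphere = 724L) {
  pre <- csdPrecompute(scheme, response, maxOrder, lambda, nSphere)
  csdFitCore(amplitudes, pre, tau, nIter)
}

csdFitCore <- function(amplitudes, pre, tau = 0.1, nIter = 50L) {
  A <- pre$A; P <- pre$P; lambda <- pre$lambda
  if (length(amplitudes) != nrow(A))
    stop("amplitude length does not match the scheme")
  Atb <- crossprod(A, amplitudes)
  # order-4 truncated unconstrained initialization
  o4 <- pre$order4
  x <- numeric(ncol(A))
  x[o4] <- tryCatch(qr.solve(A[, o4, drop = FALSE], amplitudes),
                    error = function(e) stop("conditioning error in CSD initialization: ",
                                             conditionMessage(e)))
  ampInit <- P %*% x
  thr <- tau * mean(ampInit)
  active <- integer(0)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(nIter)) {
    amp <- P %*% x
    newActive <- which(amp < thr)
    if (it > 1L && length(newActive) == length(active) &&
        all(newActive == active)) { converged <- TRUE; break }
    active <- newActive
    M <- pre$AtA
    if (length(active))
      M <- M + lambda^2 * crossprod(P[active, , drop = FALSE])
    x <- tryCatch(solve(M, Atb),
                  error = function(e) stop("conditioning error in CSD iteration: ",
                                           conditionMessage(e)))
  }
  x <- as.numeric(x)
  attr(x, "iterations") <- it
  attr(x, "converged") <- converged
  x
}

#' Voxelwise CSD over a masked volume
#'
#' Runs [csdFit()] (with a shared precomputed system) on every mask voxel
#' of the b0-normalized DWI volume; voxels outside the mask, and voxels
#' whose fit fails, are zero.  Failures are counted in the `nFailed`
#' attribute.
#'
#' @param dwi a [DWIVolume-class].
#' @param mask logical 3D array; defaults to the volume's own mask.
#' @param response a [ResponseFunction-class]; estimated from `singleFiberMask`
#'   when missing is not supported -- pass one explicitly.
#' @inheritParams csdFit
#' @param voxelSize voxel size recorded on the output field.
#' @return an [SHField-class] with `kind = "fodf"` and attribute `nFailed`
#'   on its data array.
#' @export
fitCsdVolume <- function(dwi, mask = wmMask(dwi), response, maxOrder = 8L,
                         lambda = 1, tau = 0.1, nIter = 50L, nSphere = 724L,
                         voxelSize = c(2, 2, 2)) {
  stopifnot(is(dwi, "DWIVolume"))
  if (is.null(mask)) stop("a mask is required")
  pre <- csdPrecompute(dwi@scheme, response, maxOrder, lambda, nSphere)
  sch <- dwi@scheme
  nd <- nDirections(sch)
  nc <- nCoeffs(maxOrder)
  out <- array(0, c(dim(mask), nc))
  vox <- which(mask, arr.ind = TRUE)
  nFailed <- 0L
  for (i in seq_len(nrow(vox))) {
    s <- dwi@data[vox[i, 1], vox[i, 2], vox[i, 3], ]
    s0 <- if (sch@nB0 > 0) mean(s[seq_len(sch@nB0)]) else 1
    if (s0 <= 0) { nFailed <- nFailed + 1L; next }
    amp <- s[sch@nB0 + seq_len(nd)] / s0
    fit <- tryCatch(csdFitCore(amp, pre, tau, nIter), error = function(e) NULL)
    if (is.null(fit)) { nFailed <- nFailed + 1L; next }
    out[vox[i, 1], vox[i, 2], vox[i, 3], ] <- fit
  }
  attr(out, "nFailed") <- nFailed
  SHField(out, SHBasis(maxOrder), voxelSize, kind = "fodf")
}

#' Extract fODF peak directions
#'
#' Finds local maxima of the fODF on a fixed symmetric sphere grid,
#' refines each by a deterministic shrinking-cap local search, discards
#' maxima below `relThreshold` times the global maximum, and merges peaks
#' closer than `minSepDeg` (keeping the larger), returning one unit vector
#' per antipodal peak pair.  Near-isotropic fODFs -- anisotropy contrast
#' (maximum minus spherical mean) under 2% of the maximum -- carry no
#' orientation information and yield no peaks; without this guard the
#' tiny ripples of an isotropic fit would all clear a threshold defined
#' relative to a maximum dominated by the isotropic baseline.
#'
#' @param fodf coefficient vector.
#' @param relThreshold relative amplitude threshold in (0, 1).
#' @param minSepDeg minimum angular separation between peaks (degrees).
#' @param nSphere search grid size.
#' @return matrix with one unit row vector per peak (0 rows if none).
#' @export
peakDirections <- function(fodf, relThreshold = 0.25, minSepDeg = 25,
                           nSphere = 724L) {
  L <- orderFromNCoeffs(length(fodf))
  sg <- sphereGrid(nSphere, L)
  amp <- as.numeric(sg$design %*% fodf)
  if (all(abs(amp) < 1e-12)) return(matrix(numeric(0), 0L, 3L))
  mx <- max(amp)
  if (mx <= 0 || mx - mean(amp) < 0.02 * mx)
    return(matrix(numeric(0), 0L, 3L)) # no meaningful anisotropy
  nb <- sphereNeighbors(nSphere)
  isMax <- vapply(seq_len(nSphere),
                  function(i) amp[i] > 0 && all(amp[i] >= amp[nb[i, ]]),
                  logical(1))
  cand <- which(isMax)
  if (!length(cand)) return(matrix(numeric(0), 0L, 3L))
  peaks <- t(vapply(cand, function(i) refinePeak(sg$points[i, ], fodf, L),
                    numeric(4)))
  vals <- peaks[, 4L]
  dirs <- peaks[, 1:3, drop = FALSE]
  keep <- vals >= relThreshold * max(vals)
  dirs <- dirs[keep, , drop = FALSE]
  vals <- vals[keep]
  # canonical hemisphere, then greedy merge (largest first)
  flip <- dirs[, 3L] < 0 | (dirs[, 3L] == 0 & dirs[, 1L] < 0)
  dirs[flip, ] <- -dirs[flip, , drop = FALSE]
  ord <- order(vals, decreasing = TRUE)
  outD <- matrix(numeric(0), 0L, 3L)
  for (i in ord) {
    d <- dirs[i, ]
    if (nrow(outD) == 0L ||
        all(acos(pmin(1, abs(outD %*% d))) * 180 / pi >= minSepDeg))
      outD <- rbind(outD, d)
  }
  rownames(outD) <- NULL
  outD
}

# Deterministic shrinking-cap refinement of a spherical local maximum.
refinePeak <- function(d0, fodf, L, radii = c(6, 2.5, 1, 0.4, 0.15)) {
  d <- d0
  for (r in radii) {
    # small tangent-plane grid of candidate directions around d
    u <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    t1 <- u - d * sum(u * d); t1 <- t1 / sqrt(sum(t1^2))
    t2 <- c(d[2] * t1[3] - d[3] * t1[2], d[3] * t1[1] - d[1] * t1[3],
            d[1] * t1[2] - d[2] * t1[1])
    ang <- r * pi / 180
    offs <- rbind(c(0, 0), ang * cbind(cos(seq(0, 2 * pi, length.out = 9)[-9]),
                                       sin(seq(0, 2 * pi, length.out = 9)[-9])),
                  0.5 * ang * cbind(cos(seq(0, 2 * pi, length.out = 7)[-7] + 0.3),
                                    sin(seq(0, 2 * pi, length.out = 7)[-7] + 0.3)))
    cands <- t(apply(offs, 1L, function(o) {
      v <- d + o[1] * t1 + o[2] * t2
      v / sqrt(sum(v^2))
    }))
    a <- shToAmplitudes(fodf, cands, L)
    d <- cands[which.max(a), ]
  }
  c(d, shToAmplitudes(fodf, matrix(d, 1L), L))
}
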