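# Gradient scheme construction and manipulation.

#' Construct a gradient scheme
#'
#' @param directions n x 3 matrix of unit vectors.
#' @param bValue shell b-value in s/mm^2.
#' @param nB0 number of b=0 volumes.
#' @return a [GradientScheme-class].
#' @export
GradientScheme <- function(directions, bValue, nB0 = 0L) {
  new("GradientScheme", directions = directions, bValue = as.numeric(bValue),
      nB0 = as.integer(nB0))
}

#' Generate a uniformly distributed gradient scheme
#'
#' Places `nDirs` directions on the half-sphere by minimizing an
#' electrostatic-repulsion energy over antipodal pairs
#' (\eqn{\sum_{i<j} 1/\|d_i-d_j\|^2 + 1/\|d_i+d_j\|^2}), by projected
#' gradient descent from a seeded random start.  Deterministic given the
#' seed.  This emulates the uniform single-shell HARDI schemes of typical
#' research acquisitions (90-96 directions at one b-value).
#'
#' @param nDirs number of diffusion directions (>= 6).
#' @param bValue shell b-value in s/mm^2.
#' @param nB0 number of b=0 volumes.
#' @param seed integer RNG seed.
#' @param nIter descent iterations.
#' @return a [GradientScheme-class].
#' @examples
#' sch <- makeGradientScheme(30, bValue = 2000, seed = 1)
#' nDirections(sch)
#' @export
makeGradientScheme <- function(nDirs, bValue = 2000, nB0 = 3L, seed = 1L,
                               nIter = 400L) {
  if (nDirs < 6L) stop("nDirs must be at least 6")
  D <- withSeed(deriveSeed(seed, "scheme"), {
    M <- matrix(stats::rnorm(nDirs * 3L), ncol = 3L)
    M / sqrt(rowSums(M^2))
  })
  # flip to upper hemisphere for a canonical representation
  flip <- D[, 3L] < 0
  D[flip, ] <- -D[flip, ]
  eta <- 0.1
  for (it in seq_len(nIter)) {
    G <- gradSchemeForces(D)
    # tangential projection and normalized step
    G <- G - D * rowSums(G * D)
    gn <- sqrt(rowSums(G^2))
    scale <- eta / max(gn, 1e-12)
    D <- D + scale * G
    D <- D / sqrt(rowSums(D^2))
    eta <- eta * 0.985
  }
  GradientScheme(D, bValue, nB0)
}

# Repulsive forces between antipodal direction pairs (vectorized).
gradSchemeForces <- function(D) {
  Gdot <- D %*% t(D)
  d2m <- pmax(2 - 2 * Gdot, 1e-9) # |di - dj|^2
  d2p <- pmax(2 + 2 * Gdot, 1e-9) # |di + dj|^2
  diag(d2m) <- Inf; diag(d2p) <- Inf
  wm <- 1 / d2m^2
  wp <- 1 / d2p^2
  # force on i: sum_j 2*(di-dj)/|di-dj|^4 + 2*(di+dj)/|di+dj|^4
  2 * (rowSums(wm + wp) * D - (wm - wp) %*% D)
}

#' Minimum pairwise angle of a scheme (degrees, antipodal)
#'
#' @param scheme a [GradientScheme-class] or n x 3 direction matrix.
#' @return smallest pairwise angle after antipodal identification.
#' @export
minPairwiseAngle <- function(scheme) {
  D <- if (is(scheme, "GradientScheme")) scheme@directions else scheme
  G <- abs(D %*% t(D))
  diag(G) <- 0
  acos(pmin(1, max(G))) * 180 / pi
}

#' Retain a subset of a scheme's directions
#'
#' @param scheme a [GradientScheme-class].
#' @param idx integer indices of the directions to keep.
#' @return a [GradientScheme-class] with the retained directions (b0 count
#'   unchanged: b=0 volumes are never dropped).
#' @export
subsetScheme <- function(scheme, idx) {
  stopifnot(is(scheme, "GradientScheme"))
  if (any(idx < 1L | idx > nDirections(scheme)))
    stop("subset indices out of range")
  GradientScheme(scheme@directions[idx, , drop = FALSE], scheme@bValue,
                 scheme@nB0)
}

#' Rigidly rotate a scheme's directions
#'
#' @param scheme a [GradientScheme-class].
#' @param angleDeg rotation angle in degrees.
#' @param axis rotation axis (3-vector, need not be unit).
#' @return the rotated [GradientScheme-class].
#' @export
rotateScheme <- function(scheme, angleDeg, axis = c(0, 0, 1)) {
  stopifnot(is(scheme, "GradientScheme"))
  R <- rotationMatrix(axis, angleDeg * pi / 180)
  D <- scheme@directions %*% t(R)
  D <- D / sqrt(rowSums(D^2))
  GradientScheme(D, scheme@bValue, scheme@nB0)
}
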