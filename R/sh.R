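# Even-order real spherical-harmonic basis: indexing, evaluation on unit
# directions, least-squares fitting and resampling.
#
# Convention ("real-sym-orthonormal"): with thetab the polar angle from +z
# and phi the azimuth from +x, and Pbar_k^m the fully normalized associated
# Legendre function WITHOUT the Condon-Shortley phase,
#   Pbar_k^m(x) = sqrt((2k+1)/(4*pi) * (k-m)!/(k+m)!) * P_k^m(x),
# the basis function of order k and degree m is
#   m  < 0 :  sqrt(2) * Pbar_k^|m|(cos theta) * sin(|m| phi)
#   m == 0 :  Pbar_k^0(cos theta)
#   m  > 0 :  sqrt(2) * Pbar_k^m(cos theta) * cos(m phi).
# The basis is orthonormal on the sphere; only even k are used, so every
# basis function is antipodally symmetric.

#' Number of even-order SH coefficients
#'
#' For an antipodally symmetric basis truncated at even order `maxOrder`,
#' the number of basis functions is \eqn{(L+1)(L+2)/2}: 45 at \eqn{L = 8}.
#'
#' @param maxOrder even non-negative integer.
#' @return integer coefficient count.
#' @examples
#' nCoeffs(8) # 45
#' @export
nCoeffs <- function(maxOrder) {
  if (length(maxOrder) != 1L || !is.finite(maxOrder) || maxOrder < 0 ||
      maxOrder != round(maxOrder) || maxOrder %% 2 != 0)
    stop("maxOrder must be a single even non-negative integer")
  L <- as.integer(maxOrder)
  (L + 1L) * (L + 2L) %/% 2L
}

#' Index table of the even-order SH basis
#'
#' Coefficients are ordered by increasing even order k, and within each
#' order by degree m from -k to +k.
#'
#' @inheritParams nCoeffs
#' @return data.frame with integer columns `k` and `m`, one row per basis
#'   function.
#' @examples
#' shIndexTable(2)
#' @export
shIndexTable <- function(maxOrder) {
  nCoeffs(maxOrder) # validates
  ks <- seq(0L, as.integer(maxOrder), by = 2L)
  k <- unlist(lapply(ks, function(kk) rep(kk, 2L * kk + 1L)))
  m <- unlist(lapply(ks, function(kk) seq(-kk, kk)))
  data.frame(k = as.integer(k), m = as.integer(m))
}

# Fully normalized associated Legendre functions Pbar_k^m(x) for all
# 0 <= m <= k <= L at a vector of abscissae, by the standard stable
# three-term recurrence (no Condon-Shortley phase).  Returns a list over k
# of matrices [length(x) x (k+1)] with columns m = 0..k.
normalizedLegendre <- function(L, x) {
  s <- sqrt(pmax(0, 1 - x^2)) # sin(theta)
  P <- vector("list", L + 1L) # P[[k+1]] has cols m=0..k
  P[[1L]] <- matrix(1 / sqrt(4 * pi), length(x), 1L)
  if (L >= 1L) {
    # build sectoral terms Pbar_m^m then recur upward in k
    sect <- vector("list", L + 1L)
    sect[[1L]] <- P[[1L]][, 1L]
    for (m in 1:L)
      sect[[m + 1L]] <- sqrt((2 * m + 1) / (2 * m)) * s * sect[[m]]
    for (k in 1:L) {
      Pk <- matrix(0, length(x), k + 1L)
      for (m in 0:k) {
        if (m == k) {
          Pk[, m + 1L] <- sect[[k + 1L]]
        } else if (m == k - 1L) {
          Pk[, m + 1L] <- sqrt(2 * m + 3) * x * sect[[m + 1L]]
        } else {
          a <- sqrt((2 * k - 1) * (2 * k + 1) / ((k - m) * (k + m)))
          b <- sqrt((2 * k + 1) * (k + m - 1) * (k - m - 1) /
                      ((k - m) * (k + m) * (2 * k - 3)))
          Pk[, m + 1L] <- a * x * P[[k]][, m + 1L] - b * P[[k - 1L]][, m + 1L]
        }
      }
      P[[k + 1L]] <- Pk
    }
  }
  P
}

#' Evaluate the even-order real SH basis at unit directions
#'
#' Returns the design matrix whose entry (i, j) is basis function j
#' evaluated at direction i, under the package convention (see the file
#' header of the SH module and [SHBasis()]).  Rows for a direction and its
#' antipode are identical (even orders only).
#'
#' @param directions n x 3 matrix of unit vectors.
#' @inheritParams nCoeffs
#' @return numeric matrix `[n x nCoeffs(maxOrder)]`.
#' @export
shDesignMatrix <- function(directions, maxOrder) {
  checkUnitDirections(directions)
  nc <- nCoeffs(maxOrder)
  L <- as.integer(maxOrder)
  x <- pmin(1, pmax(-1, directions[, 3L]))
  phi <- atan2(directions[, 2L], directions[, 1L])
  P <- normalizedLegendre(L, x)
  B <- matrix(0, nrow(directions), nc)
  idx <- shIndexTable(L)
  for (j in seq_len(nc)) {
    k <- idx$k[j]; m <- idx$m[j]
    if (m == 0L) {
      B[, j] <- P[[k + 1L]][, 1L]
    } else if (m > 0L) {
      B[, j] <- sqrt(2) * P[[k + 1L]][, m + 1L] * cos(m * phi)
    } else {
      B[, j] <- sqrt(2) * P[[k + 1L]][, -m + 1L] * sin(-m * phi)
    }
  }
  B
}

#' Least-squares SH fit of spherical samples
#'
#' Fits even-order SH coefficients to per-direction amplitudes by linear
#' least squares, optionally with a plain ridge or a Laplace-Beltrami
#' weighted ridge penalty (weight \eqn{(k(k+1))^2} per order, useful for
#' low-direction fits; both default to 0).  With both penalties zero the
#' fit requires at least `nCoeffs(maxOrder)` directions and a design-matrix
#' condition number below `condLimit`.
#'
#' @param amplitudes numeric vector (one sample per direction) or matrix
#'   `[n_dirs x n_signals]` for many signals sharing one direction set.
#' @param directions n x 3 unit vectors.
#' @inheritParams nCoeffs
#' @param ridge non-negative plain ridge weight.
#' @param lbWeight non-negative Laplace-Beltrami ridge weight.
#' @param condLimit condition-number guard for the unpenalized fit.
#' @return coefficient vector (or matrix `[nCoeffs x n_signals]`).
#' @seealso [shToAmplitudes()]
#' @export
fitSH <- function(amplitudes, directions, maxOrder, ridge = 0, lbWeight = 0,
                  condLimit = 1e6) {
  B <- shDesignMatrix(directions, maxOrder)
  vec <- is.null(dim(amplitudes))
  Y <- if (vec) matrix(amplitudes, ncol = 1L) else amplitudes
  if (nrow(Y) != nrow(B))
    stop("amplitudes length does not match the number of directions")
  if (any(!is.finite(Y))) stop("amplitudes must be finite")
  if (ridge == 0 && lbWeight == 0) {
    if (nrow(B) < ncol(B))
      stop(sprintf("rank deficiency: %d directions < %d coefficients; use a ridge",
                   nrow(B), ncol(B)))
    kap <- kappa(B, exact = TRUE)
    if (!is.finite(kap) || kap > condLimit)
      stop(sprintf("ill-conditioned design matrix (condition number %.3g > %.3g)",
                   kap, condLimit))
    C <- qr.solve(B, Y)
  } else {
    idx <- shIndexTable(maxOrder)
    pen <- ridge + lbWeight * (idx$k * (idx$k + 1))^2
    C <- solve(crossprod(B) + diag(pen, ncol(B)), crossprod(B, Y))
  }
  if (vec) as.numeric(C) else C
}

#' Resample an SH function at unit directions
#'
#' Evaluates the band-limited function described by `coeffs` at the given
#' directions: the matrix-vector product of the design matrix with the
#' coefficients.
#'
#' @param coeffs coefficient vector of length `nCoeffs(maxOrder)`, or a
#'   matrix `[nCoeffs x n_signals]`.
#' @inheritParams fitSH
#' @param maxOrder even order; inferred from `coeffs` length when missing.
#' @return amplitude vector (or matrix `[n_dirs x n_signals]`).
#' @export
shToAmplitudes <- function(coeffs, directions, maxOrder = NULL) {
  vec <- is.null(dim(coeffs))
  C <- if (vec) matrix(coeffs, ncol = 1L) else coeffs
  if (is.null(maxOrder)) maxOrder <- orderFromNCoeffs(nrow(C))
  if (nrow(C) != nCoeffs(maxOrder))
    stop(sprintf("coefficient length %d does not match order %d (%d expected)",
                 nrow(C), maxOrder, nCoeffs(maxOrder)))
  A <- shDesignMatrix(directions, maxOrder) %*% C
  if (vec) as.numeric(A) else A
}

# Inverse of nCoeffs: the even order whose basis has n functions.
orderFromNCoeffs <- function(n) {
  L <- (sqrt(8 * n + 1) - 3) / 2
  if (abs(L - round(L)) > 1e-9 || round(L) %% 2 != 0)
    stop(sprintf("%d is not the size of an even-order SH basis", n))
  as.integer(round(L))
}
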