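# Evaluation layer: the angular correlation coefficient, voxelwise ACC
# maps, zeroth-coefficient maps, and the paired Wilcoxon signed-rank test.

#' Angular correlation coefficient of two SH coefficient vectors
#'
#' Normalized inner product of the order >= 1 coefficient blocks (the
#' order-0 term is excluded; the basis is real, so the conjugate in the
#' complex definition is the identity):
#' \deqn{ACC = \frac{\sum_{k \ge 1} \sum_m u_k^m v_k^m}
#'   {(\sum |u_k^m|^2)^{1/2} (\sum |v_k^m|^2)^{1/2}}.}
#' The result lies in \eqn{[-1, 1]}; 1 means identical angular shape.
#' A voxel whose order >= 1 block is entirely zero (purely isotropic) has
#' an undefined ACC (0/0) and raises an error rather than returning 0.
#'
#' @param u,v numeric coefficient vectors of equal length (an even-order
#'   basis size).
#' @return scalar in `[-1, 1]`.
#' @examples
#' u <- c(1, rnorm(44))
#' acc(u, u) # 1
#' @export
acc <- function(u, v) {
  if (length(u) != length(v))
    stop("coefficient vectors must have equal length")
  orderFromNCoeffs(length(u)) # validates basis size
  a <- u[-1L]; b <- v[-1L]
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("undefined ACC: an argument has no energy above order 0")
  max(-1, min(1, sum(a * b) / (na * nb)))
}

#' Voxelwise ACC map of two SH fields
#'
#' Computes [acc()] at every mask voxel.  Voxels with undefined ACC
#' (zero order >= 1 energy in either field) are recorded as `NA` and
#' counted; voxels outside the mask are `NA`.
#'
#' @param fieldU,fieldV aligned [SHField-class] objects of equal order.
#' @param mask logical 3D array.
#' @param labels character length-2 provenance labels.
#' @return an [ACCMap-class].
#' @export
accMap <- function(fieldU, fieldV, mask, labels = c("u", "v")) {
  stopifnot(is(fieldU, "SHField"), is(fieldV, "SHField"))
  du <- dim(fieldU@data); dv <- dim(fieldV@data)
  if (!identical(du, dv)) stop("field shapes differ")
  if (!identical(dim(mask), du[1:3])) stop("mask shape differs from the fields")
  U <- matrix(fieldU@data, ncol = du[4L])[, -1L, drop = FALSE]
  V <- matrix(fieldV@data, ncol = du[4L])[, -1L, drop = FALSE]
  num <- rowSums(U * V)
  nu <- sqrt(rowSums(U^2)); nv <- sqrt(rowSums(V^2))
  vals <- ifelse(nu > 0 & nv > 0, num / (nu * nv), NA_real_)
  vals <- pmax(-1, pmin(1, vals))
  vals[!as.vector(mask)] <- NA_real_
  nUndef <- sum(as.vector(mask) & (nu == 0 | nv == 0))
  new("ACCMap", data = array(vals, du[1:3]), nUndefined = as.integer(nUndef),
      provenance = labels)
}

#' Summary statistics of an ACC map
#'
#' NA-excluding mean and standard deviation over the defined voxels,
#' with the defined-voxel count.
#'
#' @param map an [ACCMap-class].
#' @return list with `mean`, `sd`, `n` (defined voxels) and `nUndefined`.
#' @export
meanAcc <- function(map) {
  stopifnot(is(map, "ACCMap"))
  v <- map@data[!is.na(map@data)]
  list(mean = if (length(v)) mean(v) else NaN,
       sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
       n = length(v), nUndefined = map@nUndefined)
}

#' Zeroth-order coefficient map of an SH field
#'
#' Extracts the (0,0) coefficient per voxel -- the spherical mean times
#' \eqn{\sqrt{4\pi}}.  For fODF fields this is the quantity sometimes
#' loosely labelled "MD" in fODF harmonization work; [mdMap()] is provided
#' as an alias under that name, but note it is not a diffusivity in
#' physical units.
#'
#' @param field an [SHField-class].
#' @return numeric 3D array.
#' @export
zerothCoeffMap <- function(field) {
  stopifnot(is(field, "SHField"))
  field@data[, , , 1L]
}

#' @rdname zerothCoeffMap
#' @export
mdMap <- zerothCoeffMap

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Compares paired samples without a normality assumption: zero
#' differences are dropped, ties receive mid-ranks, the null distribution
#' is exact (computed by convolution over the signed mid-ranks) for 25 or
#' fewer non-zero differences, and a normal approximation with continuity
#' correction is used above that.
#'
#' @param x,y equal-length paired sample vectors (length >= 6).
#' @return list with `statistic` (V), `pValue` and `nEffective` (non-zero
#'   differences).
#' @export
pairedSignedRank <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  if (length(x) < 6L) stop("at least 6 pairs are required")
  d <- x - y
  d <- d[d != 0]
  if (!length(d)) stop("degenerate input: all paired differences are zero")
  n <- length(d)
  r <- rank(abs(d)) # mid-ranks for tied magnitudes
  V <- sum(r[d > 0])
  if (n <= 25L) {
    # exact null by shift convolution over doubled (integer) mid-ranks;
    # unlike the classical tables this remains valid under ties
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    dp <- numeric(tot + 1L); dp[1L] <- 1
    for (ri in r2)
      dp <- dp + c(numeric(ri), dp[seq_len(tot + 1L - ri)])
    dp <- dp / 2^n
    v2 <- as.integer(round(2 * V))
    pGe <- sum(dp[(v2:tot) + 1L])
    pLe <- sum(dp[seq_len(v2 + 1L)])
    p <- min(1, 2 * min(pGe, pLe))
  } else {
    ht <- suppressWarnings(stats::wilcox.test(d, alternative = "two.sided",
                                              mu = 0, exact = FALSE,
                                              correct = TRUE))
    p <- ht$p.value
  }
  list(statistic = V, pValue = p, nEffective = n)
}
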