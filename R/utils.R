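# Internal helpers: seeds, sphere grids, small geometry.

# Hierarchical seed derivation: one master seed, independent child streams
# per component.  Kept below 2^31 - 1.
deriveSeed <- function(seed, ...) {
  tags <- c(...)
  s <- as.double(seed) %% 2147483647
  for (tag in tags) {
    h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
    s <- (s * 69069 + h) %% 2147483647
  }
  as.integer(s)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Antipodally symmetric quasi-uniform sphere grid: a Fibonacci lattice on
# the upper hemisphere plus its antipodes.  n must be even; returns n x 3.
fibonacciSphereSym <- function(n = 724L) {
  stopifnot(n >= 2L, n %% 2L == 0L)
  half <- n %/% 2L
  i <- seq_len(half) - 0.5
  # z in (0, 1): upper hemisphere only, antipodes supply the lower one
  z <- i / half
  phi <- 2 * pi * i * (1 - 1 / ((1 + sqrt(5)) / 2))
  r <- sqrt(pmax(0, 1 - z^2))
  upper <- cbind(r * cos(phi), r * sin(phi), z)
  rbind(upper, -upper)
}

# Rotation matrix about a unit axis by angle (radians), Rodrigues form.
rotationMatrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Angle in degrees between unit vectors up to sign (antipodal identification).
angleDeg <- function(u, v) {
  d <- min(1, abs(sum(u * v)))
  acos(d) * 180 / pi
}

checkUnitDirections <- function(directions, tol = 1e-6) {
  if (!is.matrix(directions) || ncol(directions) != 3L)
    stop("directions must be an n x 3 matrix")
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > tol))
    stop("all directions must be unit vectors (tolerance ", tol, ")")
  invisible(directions)
}
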