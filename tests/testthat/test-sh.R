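test_that("coefficient counts match brute-force (k, m) enumeration", {
  bruteCount <- function(L) {
    n <- 0L
    for (k in seq(0L, L, by = 2L)) for (m in -k:k) n <- n + 1L
    n
  }
  for (L in c(0L, 2L, 4L, 6L, 8L, 10L))
    expect_identical(nCoeffs(L), bruteCount(L))
  expect_identical(nCoeffs(8), 45L)
  expect_error(nCoeffs(3), "even")
  expect_error(nCoeffs(-2), "even|negative")
})

test_that("index table is ordered by even order then degree", {
  expect_identical(shIndexTable(0), data.frame(k = 0L, m = 0L))
  expect_identical(shIndexTable(2),
                   data.frame(k = c(0L, 2L, 2L, 2L, 2L, 2L),
                              m = c(0L, -2L, -1L, 0L, 1L, 2L)))
  tab8 <- shIndexTable(8)
  expect_identical(nrow(tab8), 45L)
  expect_identical(unlist(tab8[45, ], use.names = FALSE), c(8L, 8L))
  expect_true(all(tab8$k %% 2 == 0))
  expect_true(all(abs(tab8$m) <= tab8$k))
})

test_that("design matrix matches direct closed-form Legendre evaluation", {
  # oracle: explicit Rodrigues-type associated Legendre from pracma,
  # normalized by hand (pracma uses the Condon-Shortley phase; the package
  # convention omits it, hence the (-1)^m correction)
  skip_if_not_installed("pracma")
  D <- randomUnitVectors(60, seed = 4)
  B <- shDesignMatrix(D, 8)
  theta <- acos(pmin(1, pmax(-1, D[, 3])))
  phi <- atan2(D[, 2], D[, 1])
  idx <- shIndexTable(8)
  oracle <- matrix(0, nrow(D), 45)
  for (j in seq_len(45)) {
    k <- idx$k[j]; m <- abs(idx$m[j])
    Pkm <- if (k == 0) rep(1, length(theta))
      else pracma::legendre(k, cos(theta))[m + 1, ] * (-1)^m
    norm <- sqrt((2 * k + 1) / (4 * pi) * factorial(k - m) / factorial(k + m))
    oracle[, j] <- if (idx$m[j] == 0) norm * Pkm
      else if (idx$m[j] > 0) sqrt(2) * norm * Pkm * cos(m * phi)
      else sqrt(2) * norm * Pkm * sin(m * phi)
  }
  expect_lt(max(abs(B - oracle)), 1e-10)
})

test_that("design matrix rows are antipodally symmetric at every order", {
  D <- randomUnitVectors(20, seed = 2)
  for (L in c(0L, 4L, 8L))
    expect_equal(shDesignMatrix(D, L), shDesignMatrix(-D, L),
                 tolerance = 1e-12)
})

test_that("design matrix rejects non-unit directions", {
  expect_error(shDesignMatrix(matrix(c(0, 0, 0.5), 1), 8), "unit")
})

test_that("constant amplitudes fit to a pure order-0 coefficient", {
  D <- directions(fxScheme96())
  cc <- fitSH(rep(3.2, nrow(D)), D, 8)
  expect_equal(cc[1], 3.2 * sqrt(4 * pi), tolerance = 1e-8)
  expect_lt(max(abs(cc[-1])), 1e-8)
})

test_that("fit/resample round trip is the identity on band-limited functions", {
  D <- directions(fxScheme96())
  set.seed(11)
  for (rep in 1:100) {
    cc <- rnorm(45)
    amp <- shToAmplitudes(cc, D)
    expect_lt(max(abs(fitSH(amp, D, 8) - cc)), 1e-8)
  }
})

test_that("least-squares fit agrees with an independent pseudo-inverse oracle", {
  set.seed(3)
  for (n in c(45, 60, 90)) {
    D <- directions(makeGradientScheme(n, 2000, 0, seed = n))
    B <- shDesignMatrix(D, 8)
    amp <- shToAmplitudes(rnorm(45), D) + rnorm(n, 0, 0.01)
    oracle <- solve(t(B) %*% B) %*% (t(B) %*% amp) # normal equations, by hand
    expect_lt(max(abs(fitSH(amp, D, 8) - as.numeric(oracle))), 1e-10)
  }
})

test_that("sh_to_amplitudes equals per-direction summation", {
  D <- randomUnitVectors(20, seed = 6)
  set.seed(8)
  cc <- rnorm(45)
  B <- shDesignMatrix(D, 8)
  direct <- vapply(seq_len(20), function(i) sum(B[i, ] * cc), numeric(1))
  expect_equal(shToAmplitudes(cc, D), direct, tolerance = 1e-12)
  expect_equal(shToAmplitudes(numeric(45), D), rep(0, 20))
  cc0 <- c(1, numeric(44))
  expect_equal(shToAmplitudes(cc0, D), rep(1 / sqrt(4 * pi), 20),
               tolerance = 1e-12)
})

test_that("underdetermined unpenalized fits are rejected, ridge rescues them", {
  D <- randomUnitVectors(30, seed = 5)
  amp <- rnorm(30)
  expect_error(fitSH(amp, D, 8), "rank")
  expect_length(fitSH(amp, D, 8, lbWeight = 1e-3), 45)
})

test_that("basis is orthonormal under dense quadrature", {
  G <- dcsd:::fibonacciSphereSym(10000)
  B <- shDesignMatrix(G, 8)
  gram <- crossprod(B) * (4 * pi / nrow(G))
  expect_lt(max(abs(gram - diag(45))), 5e-3)
})
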