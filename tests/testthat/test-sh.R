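# Real even-degree spherical harmonics and per-shell fits.

test_that("basis size and l = 0 column match the definitions", {
  dirs <- fibonacciSphere(50)
  B <- realEvenShBasis(dirs, 12)
  expect_equal(ncol(B), 91)
  expect_equal(B[, 1], rep(1 / sqrt(4 * pi), 50))
  expect_equal(ncol(realEvenShBasis(dirs, 4)), 15)
  expect_error(realEvenShBasis(dirs, 7), "even")
})

test_that("basis is orthonormal under uniform quadrature", {
  dirs <- fibonacciSphere(10000)
  B <- realEvenShBasis(dirs, 12)
  G <- crossprod(B) * (4 * pi / nrow(dirs))
  expect_lt(max(abs(G - diag(ncol(B)))), 1e-2)
})

test_that("band-limited signals round trip through the per-shell fit", {
  dirs <- sphereDirections(256, seed = 31)
  sc <- makeScheme(rbind(c(0, 0, 0), dirs), c(0, rep(3000, 256)),
                   delta = 12.9, Delta = 21.8)
  set.seed(32)
  cTrue <- rnorm(91, sd = 1 / (1 + rep(seq(0, 12, 2), 2 * seq(0, 12, 2) + 1)))
  y <- c(1, drop(realEvenShBasis(dirs, 12) %*% cTrue))
  feat <- fitShPerShell(y, sc, lmax = 12, lambda = 0)
  expect_equal(drop(feat@coefficients), cTrue, tolerance = 1e-8)
})

test_that("an isotropic shell excites only the l = 0 coefficient", {
  dirs <- sphereDirections(256, seed = 33)
  sc <- makeScheme(rbind(c(0, 0, 0), dirs), c(0, rep(1000, 256)),
                   delta = 12.9, Delta = 21.8)
  y <- c(1, rep(0.37, 256))
  feat <- fitShPerShell(y, sc, lmax = 12, lambda = 0)
  co <- drop(feat@coefficients)
  expect_equal(co[1], 0.37 * sqrt(4 * pi), tolerance = 1e-10)
  expect_lt(max(abs(co[-1])), 1e-10)
})

test_that("coefficients are robust to dropping measurements", {
  dirs <- sphereDirections(256, seed = 34)
  sc <- makeScheme(rbind(c(0, 0, 0), dirs), c(0, rep(3000, 256)),
                   delta = 12.9, Delta = 21.8)
  d <- tinyDict(sc, nFvf = 3, nDex = 1)
  set.seed(35)
  y <- drop(rotateDictionary(d, randomUnit())[, 2])
  full <- drop(fitShPerShell(y, sc, 12, 1e-3)@coefficients)
  keep <- c(1, 1 + sort(sample(256, 230)))    # drop ~10% of the shell
  sc2 <- makeScheme(directions(sc)[keep, ], bValues(sc)[keep],
                    delta = 12.9, Delta = 21.8)
  sub <- drop(fitShPerShell(y[keep], sc2, 12, 1e-3)@coefficients)
  expect_lt(sqrt(mean((sub - full)^2)) / sqrt(mean(full^2)), 0.05)
})

test_that("feature pipeline is invariant to measurement order within shells", {
  sc <- tinyScheme(nDir = 24, bs = c(1000, 2000))
  d <- tinyDict(sc, nFvf = 3, nDex = 1)
  vs <- generateDataset(5, d, synthConfig(K = 2), seed = 36)
  X1 <- fascicleMF:::.shFeatureMatrix(signals(vs), sc, 4, 1e-3)
  # permute measurements (rows) and the scheme coherently
  set.seed(37)
  p <- sample(nMeasurements(sc))
  sc2 <- makeScheme(directions(sc)[p, ], bValues(sc)[p],
                    delta = 12.9, Delta = 21.8)
  X2 <- fascicleMF:::.shFeatureMatrix(signals(vs)[p, ], sc2, 4, 1e-3)
  expect_equal(X1, X2, tolerance = 1e-10)
})

test_that("shells with too few directions are rejected", {
  sc <- makeScheme(rbind(c(0, 0, 0), diag(3), -diag(3)[1:2, ]),
                   c(0, rep(1000, 5)), delta = 10, Delta = 20)
  expect_error(fitShPerShell(rep(1, 6), sc, lmax = 2), "fewer than 6")
})
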