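# Metrics: angular error, fascicle matching, MAE, R^2, reports.

test_that("angular error is antipodal and clipped to [0, 90]", {
  expect_equal(angularError(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(angularError(c(0, 0, 1), c(0, 0, -1)), 0)
  expect_equal(angularError(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(angularError(c(0, 0, 1), c(0, sin(0.3), cos(0.3))),
               0.3 * 180 / pi, tolerance = 1e-9)
  expect_error(angularError(c(0, 0, 0), c(0, 0, 1)), "zero")
})

test_that("fascicle matching recovers permutations", {
  U <- rbind(c(0, 0, 1), c(1, 0, 0))
  expect_equal(matchFascicles(U, U), 1:2)
  expect_equal(matchFascicles(U[2:1, ], U), 2:1)
  # orientation-free estimates keep their labels
  expect_equal(matchFascicles(matrix(NA_real_, 2, 3), U), 1:2)
  # K = 3 against the exhaustive 6-permutation oracle
  set.seed(61)
  for (i in 1:20) {
    Ut <- t(replicate(3, randomUnit()))
    p0 <- sample(3)
    Ue <- Ut[p0, ] + matrix(rnorm(9, 0, 0.05), 3)
    Ue <- Ue / sqrt(rowSums(Ue^2))
    got <- matchFascicles(Ue, Ut)
    costs <- sapply(list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                         c(3, 1, 2), c(3, 2, 1)), function(p)
                           sum(angularError(Ue[p, ], Ut)))
    expect_equal(sum(angularError(Ue[got, ], Ut)), min(costs),
                 tolerance = 1e-9)
  }
})

makeToyPair <- function(nuE, nuT, fvfE = nuE) {
  n <- nrow(nuE)
  nuE <- nuE / rowSums(nuE)
  est <- new("FascicleEstimates", nu = nuE, fvf = fvfE, dex = fvfE,
             orientations = array(NA_real_, c(n, 3, 2)),
             residual = rep(0, n), method = "toy", nSolves = rep(0, n))
  sc <- tinyScheme(nDir = 6)
  Y <- matrix(1, nMeasurements(sc), n)
  U <- array(rep(c(0, 0, 1, 1, 0, 0), each = n), c(n, 3, 2))
  vs <- fascicleMF:::.newVoxelSet(Y, Y, nuT, nuT, nuT, U, rep(30, n), sc,
                                  list(), 1)
  list(est = est, vs = vs)
}

test_that("MAE and R^2 match their definitions", {
  nuT <- cbind(c(0.6, 0.7, 0.8), c(0.4, 0.3, 0.2))
  perfect <- makeToyPair(nuT, nuT)
  expect_equal(mae(perfect$est, perfect$vs, "nu"), 0)
  expect_equal(rSquared(perfect$est, perfect$vs, "nu"), 1)
  # constant predictor at the truth mean has R^2 = 0
  cm <- matrix(mean(nuT), 3, 2)
  constant <- makeToyPair(cm, nuT)
  expect_equal(rSquared(constant$est, constant$vs, "nu"), 0, tolerance = 1e-12)
  expect_equal(mae(constant$est, constant$vs, "nu"), mean(abs(cm - nuT)))
  # a predictor worse than the mean goes negative
  bad <- makeToyPair(1 - nuT, nuT)
  expect_lt(rSquared(bad$est, bad$vs, "nu"), 0)
  # zero-variance truth is rejected
  flat <- makeToyPair(nuT, matrix(0.5, 3, 2))
  expect_error(rSquared(flat$est, flat$vs, "nu"), "variance")
})

test_that("difference histograms integrate to one", {
  set.seed(62)
  nuT <- cbind(runif(200, 0.5, 0.9), 0)
  nuT[, 2] <- 1 - nuT[, 1]
  a <- makeToyPair(nuT, nuT, fvfE = pmin(nuT + 0.05, 1))
  b <- makeToyPair(nuT, nuT)
  h <- differenceHistogram(a$est, b$est, parameter = "fvf", fascicle = 1)
  expect_equal(sum(h$density * diff(h$breaks)), 1, tolerance = 1e-9)
})

test_that("metrics are invariant to voxel ordering", {
  sc <- tinyScheme(nDir = 10)
  d <- tinyDict(sc, nFvf = 3, nDex = 2)
  vs <- generateDataset(30, d, synthConfig(K = 2), seed = 63)
  est <- mfFit(vs, d)
  m1 <- mae(est, vs, "fvf")
  p <- sample(30)
  est2 <- new("FascicleEstimates", nu = est@nu[p, ], fvf = est@fvf[p, ],
              dex = est@dex[p, ], orientations = est@orientations[p, , ,
                                                                  drop = FALSE],
              residual = est@residual[p], method = est@method,
              nSolves = est@nSolves[p])
  vs2 <- vs[, p]
  expect_equal(mae(est2, vs2, "fvf"), m1, tolerance = 1e-12)
})
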