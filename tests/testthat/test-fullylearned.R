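# Fully-learned method: training behaviour and prediction contracts.

flTestSetup <- function(n = 100, seed = 41, nDir = 24) {
  sc <- tinyScheme(nDir = nDir, bs = c(1000, 3000))
  d <- tinyDict(sc, nFvf = 4, nDex = 2)
  list(sc = sc, d = d,
       vs = generateDataset(n, d, synthConfig(K = 2), seed = seed))
}

test_that("training overfits a tiny dataset and is seed-deterministic", {
  # lmax = 8 keeps the per-voxel features distinct enough to memorize
  s <- flTestSetup(100, nDir = 32)
  cfg <- flConfig(hidden = c(128, 96), branch = 64, keep = 1, lr = 3e-3,
                  lrDecay = 0.999, epochs = 1200, batch = 100, lmax = 8,
                  augmentRotations = FALSE)
  m1 <- trainFullyLearned(s$vs, grid = dictParams(s$d), config = cfg,
                          seed = 7)
  expect_lt(tail(m1@meta$lossHist, 1), 1e-2)
  m2 <- trainFullyLearned(s$vs, grid = dictParams(s$d), config = cfg,
                          seed = 7)
  expect_identical(m1@par, m2@par)
})

test_that("predicted orientations live on the unit half-sphere", {
  s <- flTestSetup(80)
  cfg <- flConfig(hidden = c(32), branch = 16, epochs = 3, lmax = 4)
  m <- trainFullyLearned(s$vs, grid = dictParams(s$d), config = cfg, seed = 8)
  test <- generateDataset(30, s$d, synthConfig(K = 2), seed = 42)
  est <- fitFullyLearned(m, test)
  for (k in 1:2) {
    U <- est@orientations[, , k]
    expect_true(all(abs(sqrt(rowSums(U^2)) - 1) < 1e-9))
    expect_true(all(U[, 3] >= 0))
  }
  expect_equal(rowSums(est@nu), rep(1, 30), tolerance = 1e-9)
  expect_true(all(est@fvf >= 0.06 - 1e-9 & est@fvf <= 0.8 + 1e-9))
  expect_equal(est@nSolves, rep(0, 30))
})

test_that("the orientation loss is antipodally symmetric", {
  ns <- asNamespace("fascicleMF")
  set.seed(43)
  U <- matrix(rnorm(12), 2)
  for (k in 1:2) {
    blk <- (k - 1) * 3 + (1:3)
    U[, blk] <- U[, blk] / sqrt(rowSums(U[, blk, drop = FALSE]^2))
  }
  Ut <- matrix(rnorm(12), 2)
  for (k in 1:2) {
    blk <- (k - 1) * 3 + (1:3)
    Ut[, blk] <- Ut[, blk] / sqrt(rowSums(Ut[, blk, drop = FALSE]^2))
  }
  l1 <- ns$.orientationLoss(U, Ut, 2)$loss
  l2 <- ns$.orientationLoss(U, -Ut, 2)$loss
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("training teaches the orientation head far beyond chance", {
  # a light run at toy scale: the acceptance suite exercises the documented
  # desk-scale training, where the mean angular error falls below the
  # 15-degree engineering bar
  sc <- tinyScheme(nDir = 32, bs = c(1000, 3000))
  d <- tinyDict(sc, nFvf = 4, nDex = 2)
  vs <- generateDataset(3000, d, synthConfig(K = 2), seed = 44)
  cfg <- flConfig(hidden = c(128, 96), branch = 64, lr = 3e-3,
                  lrDecay = 0.98, epochs = 60, batch = 256, lmax = 8,
                  orientWeightStart = 2, orientWeight = 0.5, pitFrom = 0.3)
  m <- trainFullyLearned(vs, grid = dictParams(d), config = cfg, seed = 9)
  test <- buildTestSetExp1(d, K = 2, seed = 45, n = 300, snrSet = 50)
  est <- fitFullyLearned(m, test)
  em <- fascicleMF:::.matchEstimates(est, test)
  Ut <- trueOrientations(test)
  ang <- mean(c(angularError(em@orientations[, , 1], Ut[, , 1]),
                angularError(em@orientations[, , 2], Ut[, , 2])))
  # chance level for matched pairs of random axes is ~41 degrees
  expect_lt(ang, 30)
})

test_that("model round-trips through serialization unchanged", {
  s <- flTestSetup(60)
  cfg <- flConfig(hidden = c(32), branch = 16, epochs = 2, lmax = 4)
  m <- trainFullyLearned(s$vs, grid = dictParams(s$d), config = cfg,
                         seed = 10)
  path <- tempfile(fileext = ".rds")
  saveRDS(m, path)
  m2 <- readRDS(path)
  test <- generateDataset(10, s$d, synthConfig(K = 2), seed = 46)
  expect_identical(fitFullyLearned(m, test), fitFullyLearned(m2, test))
})
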