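# Hybrid method: NNLS projection stage and the split-arm regressor.

test_that("projection of zero (b0-free) design handles trivial signals", {
  sc <- tinyScheme(nDir = 12)
  d <- tinyDict(sc, nFvf = 4, nDex = 2)
  des <- rotatedDesign(d, rbind(c(0, 0, 1), c(1, 0, 0)))
  # noiseless atom: zero residual, exact reconstruction
  y <- des@blocks[[1]][, 3]
  w <- nnlsProjection(y, des)
  expect_s4_class(w, "NNLSWeights")
  expect_equal(w@residual, 0, tolerance = 1e-8)
  A <- do.call(cbind, des@blocks)
  expect_equal(drop(A %*% w@w), y, tolerance = 1e-8)
  expect_equal(w@nSolves, 1)
  expect_equal(length(w@w), 2 * nAtoms(d))
})

test_that("relaxed projection residual never exceeds the exhaustive one", {
  sc <- tinyScheme(nDir = 14)
  d <- tinyDict(sc, nFvf = 5, nDex = 2)
  set.seed(21)
  for (i in 1:20) {
    U <- sampleOrientations(2)
    des <- rotatedDesign(d, U)
    rows <- sample(nAtoms(d), 2)
    nu1 <- runif(1, 0.05, 0.95)
    yc <- nu1 * des@blocks[[1]][, rows[1]] +
      (1 - nu1) * des@blocks[[2]][, rows[2]]
    y <- addNoise(yc, snr = runif(1, 10, 100))
    expect_lte(nnlsProjection(y, des)@residual,
               mfExhaustive(y, des)@residual + 1e-10)
  }
})

test_that("pipeline is invariant to global positive signal rescaling", {
  sc <- tinyScheme(nDir = 12)
  d <- tinyDict(sc, nFvf = 4, nDex = 2)
  des <- rotatedDesign(d, rbind(c(0, 0, 1), c(0, 1, 0)))
  set.seed(22)
  y <- addNoise(0.5 * des@blocks[[1]][, 2] + 0.5 * des@blocks[[2]][, 5], 30)
  w1 <- nnlsProjection(y, des)
  w2 <- nnlsProjection(173.5 * y, des)
  expect_equal(w1@w, w2@w, tolerance = 1e-9)
})

test_that("training overfits a small dataset and is seed-deterministic", {
  sc <- tinyScheme(nDir = 10)
  d <- tinyDict(sc, nFvf = 4, nDex = 2)
  vs <- generateDataset(100, d, synthConfig(K = 2), seed = 9)
  cfg <- hybridConfig(armWidth = 24, hidden = c(48, 32), keep = 1,
                      epochs = 300, batch = 100, lr = 3e-3, lrDecay = 1)
  m1 <- trainHybrid(vs, d, cfg, seed = 5)
  expect_lt(tail(m1@meta$lossHist, 1), 1e-3)
  m2 <- trainHybrid(vs, d, cfg, seed = 5)
  expect_identical(m1@par, m2@par)
  # training loss decreases
  expect_lt(m1@meta$lossHist[5], m1@meta$lossHist[1])
})

test_that("predictions stay inside scaling ranges with nu summing to 1", {
  sc <- tinyScheme(nDir = 10)
  d <- tinyDict(sc, nFvf = 4, nDex = 2)
  vs <- generateDataset(60, d, synthConfig(K = 2), seed = 10)
  m <- trainHybrid(vs, d, hybridConfig(armWidth = 16, hidden = c(24),
                                       epochs = 3), seed = 2)
  test <- generateDataset(20, d, synthConfig(K = 2), seed = 11)
  est <- fitHybrid(m, test, d)
  expect_equal(rowSums(est@nu), rep(1, 20), tolerance = 1e-9)
  expect_true(all(est@fvf >= 0.06 - 1e-9 & est@fvf <= 0.8 + 1e-9))
  expect_true(all(est@dex >= 0.6 - 1e-9 & est@dex <= 2.4 + 1e-9))
  expect_equal(est@nSolves, rep(1, 20))
})

test_that("weight-sharing arms give symmetric fascicle outputs", {
  sc <- tinyScheme(nDir = 10)
  d <- tinyDict(sc, nFvf = 4, nDex = 2)
  vs <- generateDataset(50, d, synthConfig(K = 2), seed = 12)
  cfg <- hybridConfig(armWidth = 16, hidden = c(24), epochs = 2,
                      shareArms = TRUE)
  m <- trainHybrid(vs, d, cfg, seed = 3)
  N <- nAtoms(d)
  set.seed(13)
  wBlock <- runif(N, 0, 0.5)
  est <- hybridPredict(m, matrix(c(wBlock, wBlock), 1))
  # identical inputs to weight-shared arms: fascicle outputs coincide
  expect_equal(est@nu[1, 1], est@nu[1, 2], tolerance = 1e-9)
  expect_equal(est@fvf[1, 1], est@fvf[1, 2], tolerance = 1e-9)
  expect_equal(est@dex[1, 1], est@dex[1, 2], tolerance = 1e-9)
})

test_that("model round-trips through serialization unchanged", {
  sc <- tinyScheme(nDir = 10)
  d <- tinyDict(sc, nFvf = 3, nDex = 2)
  vs <- generateDataset(40, d, synthConfig(K = 2), seed = 14)
  m <- trainHybrid(vs, d, hybridConfig(armWidth = 8, hidden = c(16),
                                       epochs = 2), seed = 4)
  path <- tempfile(fileext = ".rds")
  saveRDS(m, path)
  m2 <- readRDS(path)
  W <- matrix(runif(2 * 2 * nAtoms(d)), 2)
  expect_identical(hybridPredict(m, W), hybridPredict(m2, W))
})
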