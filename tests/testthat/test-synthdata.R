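# Synthetic voxel generator: sampling laws, noise model, reproducibility.

test_that("crossing angles respect the configured range", {
  set.seed(51)
  angs <- replicate(2000, {
    U <- sampleOrientations(2)
    angularError(U[1, ], U[2, ])
  })
  expect_true(all(angs >= 15 - 1e-6 & angs <= 90 + 1e-6))
  U <- sampleOrientations(3)
  expect_equal(dim(U), c(3, 3))
  for (i in 1:2) for (j in (i + 1):3) {
    a <- angularError(U[i, ], U[j, ])
    expect_true(a >= 15 - 1e-6 && a <= 90 + 1e-6)
  }
  expect_equal(sqrt(rowSums(U^2)), rep(1, 3), tolerance = 1e-12)
})

test_that("orientation sampling is reproducible under a fixed seed", {
  a <- withSeed(7, sampleOrientations(2))
  b <- withSeed(7, sampleOrientations(2))
  expect_identical(a, b)
})

test_that("the magnitude noise law has the stated moments", {
  # sigma = b0 / SNR; E[s^2] - s_clean^2 = sigma^2
  set.seed(52)
  yc <- rep(0.4, 1e6)
  s <- addNoise(yc, snr = 20, b0Value = 1)
  expect_true(all(s >= 0.4))                 # the printed law never decreases
  expect_equal(mean(s^2) - 0.16, 0.05^2, tolerance = 0.01)
  # infinite SNR returns the clean signal
  expect_equal(addNoise(yc[1:5], snr = 1e12), yc[1:5], tolerance = 1e-10)
  # two-channel variant is unbiased in the squared signal up to 2 sigma^2
  s2 <- addNoise(yc, snr = 20, mode = "rician2")
  expect_equal(mean(s2^2) - 0.16, 2 * 0.05^2, tolerance = 0.03)
})

test_that("generated datasets have the documented structure", {
  sc <- tinyScheme(nDir = 10)
  d <- tinyDict(sc, nFvf = 3, nDex = 2)
  vs <- generateDataset(200, d, synthConfig(K = 2), seed = 53)
  expect_s4_class(vs, "VoxelSet")
  expect_equal(ncol(vs), 200)
  nu <- trueNu(vs)
  expect_true(all(nu >= 0.05 - 1e-9 & nu <= 0.95 + 1e-9))
  expect_equal(rowSums(nu), rep(1, 200), tolerance = 1e-12)
  # (fvf, dex) pairs are dictionary grid rows
  g <- dictParams(d)
  key <- paste(g$fvf, g$dex)
  expect_true(all(paste(trueFvf(vs), trueDex(vs)) %in% key))
  # clean signals are exactly 1 at b = 0
  expect_equal(signalsClean(vs)[bValues(sc) == 0, ], rep(1, 200),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(voxelSnr(vs) >= 10 & voxelSnr(vs) <= 100))
})

test_that("Dirichlet(1) fractions for K = 3 are uniform on the simplex", {
  sc <- tinyScheme(nDir = 10)
  d <- tinyDict(sc, nFvf = 2, nDex = 1)
  vs <- generateDataset(3000, d, synthConfig(K = 3), seed = 54)
  nu <- trueNu(vs)
  expect_equal(colMeans(nu), rep(1 / 3, 3), tolerance = 0.02)
  # Dirichlet(1,1,1) marginals are Beta(1,2): variance 1/18
  expect_equal(apply(nu, 2, var), rep(1 / 18, 3), tolerance = 0.08)
})

test_that("noiseless signals are exact convex atom combinations", {
  sc <- tinyScheme(nDir = 12)
  d <- tinyDict(sc, nFvf = 3, nDex = 2)
  vs <- generateDataset(10, d, synthConfig(K = 2, snrLo = 1e9, snrHi = 1.1e9),
                        seed = 55)
  U <- trueOrientations(vs)
  for (v in 1:10) {
    des <- rotatedDesign(d, t(U[v, , ]))
    w <- nnlsProjection(signalsClean(vs)[, v], des)
    expect_lt(w@residual, 1e-10)
  }
})

test_that("the structured test set fixes nu1 and SNR levels", {
  sc <- tinyScheme(nDir = 10)
  d <- tinyDict(sc, nFvf = 3, nDex = 2)
  ts <- buildTestSetExp1(d, K = 2, seed = 56, n = 300)
  expect_true(all(voxelSnr(ts) %in% c(20, 30, 50)))
  expect_true(all(trueNu(ts)[, 1] >= 0.5))
  expect_true(all(round(trueNu(ts)[, 1], 6) %in% c(0.5, 0.6, 0.7, 0.8, 0.9)))
  ts2 <- buildTestSetExp1(d, K = 2, seed = 56, n = 300)
  expect_identical(signals(ts), signals(ts2))
  # K = 3 variant orders fractions descending
  ts3 <- buildTestSetExp1(d, K = 3, seed = 57, n = 60)
  expect_true(all(apply(trueNu(ts3), 1, function(x) all(diff(x) <= 0))))
})

test_that("vMF jitter is calibrated near the requested angular error", {
  set.seed(58)
  U <- array(rep(c(0, 0, 1), each = 600), dim = c(600, 3, 1))
  J <- jitterOrientations(U, kappa = 94)
  errs <- angularError(J[, , 1], U[, , 1])
  expect_gt(mean(errs), 5.5)
  expect_lt(mean(errs), 9.5)
})
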