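# Exhaustive combinatorial matching against brute-force oracles.

test_that("noiseless two-fascicle voxels are matched exactly", {
  sc <- tinyScheme(nDir = 16)
  d <- tinyDict(sc, nFvf = 5, nDex = 1)     # N = 5
  u1 <- c(0, 0, 1)
  u2 <- c(sin(pi / 3), 0, cos(pi / 3))
  des <- rotatedDesign(d, rbind(u1, u2))
  y <- 0.6 * des@blocks[[1]][, 2] + 0.4 * des@blocks[[2]][, 4]
  est <- mfExhaustive(y, des)
  expect_equal(est@nu[1, ], c(0.6, 0.4), tolerance = 1e-8)
  expect_equal(est@fvf[1, ], dictParams(d)$fvf[c(2, 4)])
  expect_equal(est@nSolves, 25)
  # independent oracle: per-pair NNLS over all 25 pairs
  best <- list(r = Inf)
  for (i in 1:5) for (j in 1:5) {
    A <- cbind(des@blocks[[1]][, i], des@blocks[[2]][, j])
    g <- pracma::lsqnonneg(A, y)
    r <- sqrt(sum((y - A %*% g$x)^2))
    if (r < best$r - 1e-12) best <- list(r = r, idx = c(i, j), w = g$x)
  }
  expect_equal(best$idx, c(2, 4))
  expect_lt(abs(est@residual - best$r), 1e-8)
})

test_that("a pure single-fascicle signal yields nu = (1, 0)", {
  sc <- tinyScheme(nDir = 16)
  d <- tinyDict(sc, nFvf = 5, nDex = 2)
  des <- rotatedDesign(d, rbind(c(0, 0, 1), c(1, 0, 0)))
  y <- des@blocks[[1]][, 7]
  est <- mfExhaustive(y, des)
  expect_equal(est@nu[1, ], c(1, 0), tolerance = 1e-9)
  expect_equal(est@fvf[1, 1], dictParams(d)$fvf[7])
})

test_that("N = 1, K = 2 reduces to a single two-column NNLS", {
  sc <- tinyScheme(nDir = 16)
  d <- tinyDict(sc, nFvf = 1, nDex = 1)
  des <- rotatedDesign(d, rbind(c(0, 0, 1), c(1, 0, 0)))
  set.seed(4)
  y <- runif(nMeasurements(sc), 0.2, 1)
  y[bValues(sc) == 0] <- 1
  est <- mfExhaustive(y, des)
  A <- cbind(des@blocks[[1]], des@blocks[[2]])
  f <- nnlsFit(A, y / mean(y[bValues(sc) == 0]))
  expect_equal(est@residual, f$residual, tolerance = 1e-10)
  expect_equal(est@nSolves, 1)
})

test_that("three-fascicle matching agrees with brute force", {
  sc <- tinyScheme(nDir = 20)
  d <- tinyDict(sc, nFvf = 3, nDex = 1)    # N = 3
  U <- rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))
  des <- rotatedDesign(d, U)
  set.seed(5)
  for (rep in 1:3) {
    yc <- 0.5 * des@blocks[[1]][, sample(3, 1)] +
      0.3 * des@blocks[[2]][, sample(3, 1)] +
      0.2 * des@blocks[[3]][, sample(3, 1)]
    y <- sqrt(yc^2 + rnorm(length(yc), 0, 0.02)^2)
    est <- mfExhaustive(y, des)
    expect_equal(est@nSolves, 27)
    yn <- y / mean(y[bValues(sc) == 0])
    best <- Inf
    for (i in 1:3) for (j in 1:3) for (k in 1:3) {
      A <- cbind(des@blocks[[1]][, i], des@blocks[[2]][, j],
                 des@blocks[[3]][, k])
      g <- pracma::lsqnonneg(A, yn)
      best <- min(best, sqrt(sum((yn - A %*% g$x)^2)))
    }
    expect_lt(abs(est@residual - best), 1e-8)
  }
})

test_that("degenerate inputs are handled", {
  sc <- tinyScheme(nDir = 8)
  d <- tinyDict(sc, nFvf = 2, nDex = 1)
  des <- rotatedDesign(d, rbind(c(0, 0, 1), c(1, 0, 0)))
  expect_error(mfExhaustive(rep(0, nMeasurements(sc)), des), "all-zero")
})

test_that("residual ties break to the lowest combined index", {
  # duplicate atoms (nDex = 2 at fvf grid of 1 value gives distinct atoms;
  # build explicit duplicate blocks instead)
  sc <- tinyScheme(nDir = 10)
  d <- tinyDict(sc, nFvf = 2, nDex = 1)
  des <- rotatedDesign(d, rbind(c(0, 0, 1), c(0, 0, 1)))
  # identical orientations make blocks identical: (i, j) and (j, i) tie
  y <- des@blocks[[1]][, 1] + 0.5 * des@blocks[[1]][, 2]
  est1 <- mfExhaustive(y, des)
  est2 <- mfExhaustive(y, des)
  expect_identical(est1@fvf, est2@fvf)
  expect_identical(est1@nu, est2@nu)
})
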