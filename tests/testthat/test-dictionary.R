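# Parameter grid, analytic fingerprints and dictionary rotation.

test_that("default parameter grid reproduces the canonical 38 x 10 layout", {
  g <- buildParameterGrid()
  expect_equal(nrow(g), 380)
  expect_equal(diff(sort(unique(g$fvf)))[1], (0.8 - 0.06) / 37,
               tolerance = 1e-12)
  expect_equal(diff(sort(unique(g$dex)))[1], (2.4 - 0.6) / 9,
               tolerance = 1e-12)
  expect_equal(range(g$fvf), c(0.06, 0.8))
  expect_equal(range(g$dex), c(0.6, 2.4))
  # fvf-major ordering
  expect_equal(g$fvf[1:10], rep(0.06, 10))
})

test_that("grid row count is the product of the axis sizes", {
  for (nf in c(1, 3, 7)) for (nd in c(1, 4)) {
    expect_equal(nrow(buildParameterGrid(nFvf = nf, nDex = nd)), nf * nd)
  }
})

test_that("analytic fingerprint matches closed forms", {
  # parallel gradient: both compartments are free 1D diffusion
  sc <- makeScheme(rbind(c(0, 0, 1)), 1000, delta = 12.9, Delta = 21.8)
  f <- analyticFingerprint(substrateConfig(fvf = 0.5, dEx = 1.5), sc, c(0, 0, 1))
  expect_equal(f, 0.5 * exp(-2.2) + 0.5 * exp(-1.5), tolerance = 1e-12)
  # fvf -> 0: isotropic monoexponential at Dex
  sc2 <- makeScheme(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                    rep(2000, 3), delta = 12.9, Delta = 21.8)
  f2 <- analyticFingerprint(substrateConfig(fvf = 1e-9, dEx = 1.2), sc2,
                            c(0, 0, 1))
  expect_equal(f2, rep(exp(-2 * 1.2), 3), tolerance = 1e-6)
  # b = 0 entries are exactly 1
  sc3 <- tinyScheme()
  f3 <- analyticFingerprint(substrateConfig(), sc3, randomUnit())
  expect_equal(f3[bValues(sc3) == 0], 1)
  expect_true(all(f3 > 0 & f3 <= 1))
})

test_that("analytic fingerprint is antipodally symmetric in u", {
  sc <- tinyScheme()
  cfg <- substrateConfig(fvf = 0.4, dEx = 1.8)
  set.seed(1)
  for (i in 1:5) {
    u <- randomUnit()
    expect_equal(analyticFingerprint(cfg, sc, u),
                 analyticFingerprint(cfg, sc, -u), tolerance = 1e-12)
  }
})

test_that("restricted perpendicular signal exceeds the free-diffusion one", {
  # restriction inside cylinders attenuates less than free diffusion at D_in
  sc <- makeScheme(rbind(c(1, 0, 0)), 5000, delta = 12.9, Delta = 21.8)
  cfg <- substrateConfig(fvf = 0.89, dEx = 1.5)
  f <- analyticFingerprint(cfg, sc, c(0, 0, 1))
  free <- 0.89 * exp(-5 * 2.2) + 0.11 * exp(-5 * 1.5 * (1 - 0.89))
  expect_gt(f, free)
})

test_that("dictionary atoms are valid signals with aligned labels", {
  sc <- tinyScheme()
  d <- buildDictionary(buildParameterGrid(nFvf = 4, nDex = 3), sc)
  expect_equal(nAtoms(d), 12)
  expect_equal(dim(atoms(d)), c(12, nMeasurements(sc)))
  expect_true(all(atoms(d) > 0 & atoms(d) <= 1))
  expect_equal(atoms(d)[, bValues(sc) == 0], matrix(1, 12, 1),
               ignore_attr = TRUE)
  # atom rows follow the params table
  f <- analyticFingerprint(substrateConfig(fvf = d@params$fvf[5],
                                           dEx = d@params$dex[5]),
                           sc, c(0, 0, 1))
  expect_equal(atoms(d)[5, ], f, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("rotation at the canonical axis is the identity and matches the
          closed form at any axis", {
  sc <- tinyScheme()
  d <- tinyDict(sc)
  expect_equal(rotateDictionary(d, c(0, 0, 1)), t(atoms(d)),
               tolerance = 1e-12, ignore_attr = TRUE)
  set.seed(2)
  u <- randomUnit()
  R <- rotateDictionary(d, u)
  for (a in c(1, 4, 9)) {
    expect_equal(R[, a],
                 analyticFingerprint(substrateConfig(fvf = d@params$fvf[a],
                                                     dEx = d@params$dex[a]),
                                     sc, u),
                 tolerance = 1e-12)
  }
})

test_that("rotated design blocks stay in the valid signal range", {
  d <- tinyDict()
  set.seed(3)
  des <- rotatedDesign(d, rbind(randomUnit(), randomUnit()))
  for (B in des@blocks) expect_true(all(B > 0 & B <= 1 + 1e-9))
})
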