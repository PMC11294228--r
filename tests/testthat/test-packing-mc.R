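# Cylinder packings and the Monte Carlo walker.

test_that("gamma radius sampling matches the configured moments", {
  r <- sampleAxonRadii(1e4, seed = 71)
  expect_equal(mean(r), 0.5, tolerance = 0.01)
  expect_equal(sd(r), 0.3, tolerance = 0.02 * 0.3 / 0.3)
  expect_lt(abs(sd(r) - 0.3) / 0.3, 0.02)
})

test_that("packings reach the requested density without overlaps", {
  p <- packCylinders(substrateConfig(fvf = 0.3), nCyl = 50, seed = 72)
  expect_equal(p@achievedFvf, 0.3, tolerance = 0.01)
  n <- length(p@radii)
  L <- p@cellSize
  for (i in 1:(n - 1)) {
    dx <- abs(p@centers[(i + 1):n, 1] - p@centers[i, 1]); dx <- pmin(dx, L - dx)
    dy <- abs(p@centers[(i + 1):n, 2] - p@centers[i, 2]); dy <- pmin(dy, L - dy)
    expect_true(all(sqrt(dx^2 + dy^2) >= p@radii[(i + 1):n] + p@radii[i] - 1e-9))
  }
  expect_error(packCylinders(substrateConfig(fvf = 0.85), 10), "dense")
})

test_that("free diffusion reproduces the monoexponential decay", {
  # empty packing: all spins extra-axonal at D_ex, no obstacles
  sc <- makeScheme(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1)),
                   c(0, 2000, 2000), delta = 12.9, Delta = 21.8)
  pk <- new("CylinderPacking", centers = matrix(0, 0, 2), radii = numeric(0),
            cellSize = 10, achievedFvf = 0)
  cfg <- substrateConfig(fvf = 0.3, dEx = 1.5)
  s <- mcFingerprint(pk, cfg, sc, nSpins = 60000, dt = 0.05, seed = 73,
                     compartment = "extra")
  expect_equal(s[1], 1)
  # MC standard error of |mean phase| ~ 1/sqrt(2 n)
  se <- 3 / sqrt(2 * 60000)
  expect_equal(s[2], exp(-2 * 1.5), tolerance = se / exp(-2 * 1.5))
  expect_equal(s[3], exp(-2 * 1.5), tolerance = se / exp(-2 * 1.5))
})

test_that("restriction raises the perpendicular intra-axonal signal", {
  sc <- makeScheme(rbind(c(0, 0, 0), c(1, 0, 0)), c(0, 5000),
                   delta = 12.9, Delta = 21.8)
  cfg <- substrateConfig(fvf = 0.3, dEx = 1.5)
  pk <- packCylinders(cfg, nCyl = 30, seed = 74)
  s <- suppressWarnings(
    mcFingerprint(pk, cfg, sc, nSpins = 4000, dt = 5e-4, seed = 75,
                  compartment = "intra"))
  expect_gt(s[2], exp(-5 * 2.2) + 0.1)
  expect_equal(s[1], 1)
})

test_that("Monte Carlo scatter shrinks with the walker count", {
  sc <- makeScheme(rbind(c(0, 0, 0), c(1, 0, 0)), c(0, 1000),
                   delta = 12.9, Delta = 21.8)
  pk <- new("CylinderPacking", centers = matrix(0, 0, 2), radii = numeric(0),
            cellSize = 10, achievedFvf = 0)
  cfg <- substrateConfig(fvf = 0.3, dEx = 1.0)
  reps <- function(n) vapply(1:8, function(i)
    mcFingerprint(pk, cfg, sc, nSpins = n, dt = 0.1, seed = 80 + i,
                  compartment = "extra")[2], numeric(1))
  v1 <- var(reps(500))
  v2 <- var(reps(8000))
  expect_lt(v2, v1)     # 16x more walkers: variance clearly smaller
})

test_that("analytic and Monte Carlo fingerprints agree at low b", {
  # full two-compartment atom on the b = 1000 shell; the GPA cylinder model
  # and the tortuosity tensor should track the walker simulation closely in
  # this regime
  dirs <- sphereDirections(12, seed = 76)
  sc <- makeScheme(rbind(c(0, 0, 0), dirs), c(0, rep(1000, 12)),
                   delta = 12.9, Delta = 21.8)
  cfg <- substrateConfig(fvf = 0.25, dEx = 1.5)
  pk <- packCylinders(cfg, nCyl = 40, seed = 77)
  mc <- suppressWarnings(
    mcFingerprint(pk, cfg, sc, nSpins = 8000, dt = 1e-3, seed = 78))
  an <- analyticFingerprint(cfg, sc, c(0, 0, 1))
  expect_lt(sqrt(mean((mc - an)^2)), 0.02)
})

test_that("rotation of Monte Carlo atoms interpolates the axial profile", {
  dirs <- sphereDirections(24, seed = 79)
  sc <- makeScheme(rbind(c(0, 0, 0), dirs), c(0, rep(1000, 24)),
                   delta = 12.9, Delta = 21.8)
  grid <- buildParameterGrid(nFvf = 1, fvfLo = 0.3, nDex = 1, dexLo = 1.5)
  dmc <- suppressWarnings(
    buildDictionary(grid, sc, generator = "montecarlo", seed = 80,
                    nSpins = 4000, dt = 2e-3, nCylinders = 30))
  # identity rotation reproduces the canonical atom up to interpolation
  R0 <- rotateDictionary(dmc, c(0, 0, 1))
  expect_lt(max(abs(R0[, 1] - atoms(dmc)[1, ])), 0.02)
  # rotation to another axis stays close to the closed-form model
  # (Monte Carlo scatter + interpolation tolerance)
  Rx <- rotateDictionary(dmc, c(1, 0, 0))
  an <- analyticFingerprint(substrateConfig(fvf = 0.3, dEx = 1.5), sc,
                            c(1, 0, 0))
  expect_lt(sqrt(mean((Rx[, 1] - an)^2)), 0.03)
})
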