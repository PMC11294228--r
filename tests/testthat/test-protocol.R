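# Acquisition schemes: construction, shell structure, IO.

test_that("HCP-MGH scheme has the published volume counts", {
  sc <- hcpMghScheme(seed = 1)
  expect_equal(nMeasurements(sc), 552)
  expect_equal(sum(bValues(sc) > 0), 512)
  expect_equal(sum(bValues(sc) == 0), 40)
  expect_equal(as.numeric(table(bValues(sc)[bValues(sc) > 0])),
               c(64, 64, 128, 256))
  expect_equal(pulseDuration(sc), 12.9)
  expect_equal(diffusionTime(sc), 21.8)
  # published per-shell gradient strengths are stored verbatim
  g <- vapply(c(1000, 3000, 5000, 10000), function(b)
    unique(gradientStrengths(sc)[bValues(sc) == b]), numeric(1))
  expect_equal(g, c(69, 120, 155, 219))
})

test_that("clinical scheme has 260 measurements and omits high shells", {
  sc <- clinicalScheme(seed = 7)
  expect_equal(nMeasurements(sc), 260)
  expect_equal(sum(bValues(sc) == 0), 4)
  expect_false(any(bValues(sc) %in% c(3000, 10000)))
  expect_equal(sort(unique(bValues(sc)[bValues(sc) > 0])),
               c(1000, 2000, 5000))
})

test_that("scheme builders are deterministic and directions are unit norm", {
  a <- hcpMghScheme(seed = 3)
  b <- hcpMghScheme(seed = 3)
  expect_identical(directions(a), directions(b))
  dwi <- bValues(a) > 0
  expect_true(all(abs(sqrt(rowSums(directions(a)[dwi, ]^2)) - 1) < 1e-9))
  c1 <- clinicalScheme(seed = 1)
  c2 <- clinicalScheme(seed = 2)
  expect_false(identical(directions(c1), directions(c2)))
})

test_that("groupShells assigns ids by ascending b with b = 0 first", {
  expect_equal(groupShells(c(0, 1000, 1005, 3000), tol = 50),
               c(0L, 1L, 1L, 2L))
  expect_equal(groupShells(rep(0, 5)), rep(0L, 5))
  b <- c(0, 100, 300, 700)
  expect_equal(groupShells(b, tol = 50), 0:3)
  # idempotence: grouping the ids themselves with tol < 1 preserves structure
  ids <- groupShells(b, tol = 50)
  expect_equal(groupShells(as.numeric(ids), tol = 0.5), ids)
  # permutation equivariance
  p <- c(3, 1, 4, 2)
  expect_equal(groupShells(b[p], tol = 50), ids[p])
})

test_that("bval/bvec round trip preserves the scheme", {
  sc <- clinicalScheme(seed = 7)
  bval <- tempfile(fileext = ".bval")
  bvec <- tempfile(fileext = ".bvec")
  writeScheme(sc, bval, bvec)
  sc2 <- readScheme(bval, bvec, delta = 22.9, Delta = 35.7)
  expect_equal(bValues(sc2), bValues(sc), tolerance = 1e-6)
  expect_equal(directions(sc2), directions(sc), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(shellIds(sc2), shellIds(sc))
})

test_that("scheme IO validates inputs", {
  bval <- tempfile(); bvec <- tempfile()
  writeLines("0 1000 1000", bval)
  writeLines(c("0 1 0 0", "0 0 1 0", "1 0 0 1"), bvec)
  expect_error(readScheme(bval, bvec, delta = 10, Delta = 20), "mismatch")
  # b = 0 rows with zero vectors are accepted
  writeLines("0 1000 1000 2000", bval)
  sc <- readScheme(bval, bvec, delta = 10, Delta = 20)
  expect_equal(nMeasurements(sc), 4)
  # off-unit directions are renormalized with a warning
  writeLines(c("0 2 0", "0 0 2", "0 0 0"), bvec)
  writeLines("0 1000 1000", bval)
  expect_warning(sc <- readScheme(bval, bvec, delta = 10, Delta = 20),
                 "renormaliz")
  expect_equal(sqrt(rowSums(directions(sc)[2:3, ]^2)), c(1, 1),
               ignore_attr = TRUE)
})
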