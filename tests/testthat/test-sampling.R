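test_that("Sobol' sequence reproduces the reference low-discrepancy points", {
  # frozen from an independent reference generator of the Joe-Kuo sequence
  # (first 7 points after the all-zeros point, d = 3)
  expected <- matrix(c(
    0.500, 0.500, 0.500,
    0.750, 0.250, 0.250,
    0.250, 0.750, 0.750,
    0.375, 0.375, 0.625,
    0.875, 0.875, 0.125,
    0.625, 0.125, 0.875,
    0.125, 0.625, 0.375), ncol = 3, byrow = TRUE)
  expect_equal(sobolSequence(7, 3), expected, tolerance = 1e-12)
  # deterministic, no seed involved
  expect_identical(sobolSequence(64, 8), sobolSequence(64, 8))
  expect_error(sobolSequence(4, 99), "dimensions")
})

test_that("unit designs have the radial structure and stay in [0,1]", {
  for (scheme in c("uniform-sobol", "uniform-random", "latin-hypercube")) {
    d <- generateUnitDesign(k = 3, N = 32, scheme = scheme, seed = 7)
    expect_true(validObject(d))
    P <- designP(d); Q <- designQ(d)
    expect_true(all(P >= 0 & P <= 1) && all(Q >= 0 & Q <= 1))
    R <- designRadial(d)
    expect_length(R, 3)
    for (i in 1:3) {
      diffCols <- which(colSums(R[[i]] != P) > 0)
      expect_true(all(diffCols %in% i))     # differs from P only in column i
      expect_identical(R[[i]][, i], Q[, i])
    }
  }
  # k = 1: the single radial matrix is Q itself
  d1 <- generateUnitDesign(1, 16)
  expect_identical(designRadial(d1)[[1]], designQ(d1))
  # P = Q makes every radial matrix equal P
  P <- matrix(runif(10), 5)
  expect_true(all(vapply(radialMatrices(P, P),
                         function(R) identical(R, P), logical(1))))
  expect_error(radialMatrices(P, P[1:3, ]), "dimensions")
})

test_that("stochastic schemes are seed-deterministic", {
  a <- generateUnitDesign(2, 16, "uniform-random", seed = 42)
  b <- generateUnitDesign(2, 16, "uniform-random", seed = 42)
  expect_identical(designP(a), designP(b))
  expect_identical(designQ(a), designQ(b))
  c <- generateUnitDesign(2, 16, "uniform-random", seed = 43)
  expect_false(identical(designP(a), designP(c)))
  expect_error(generateUnitDesign(0, 16), "k must be")
  expect_error(generateUnitDesign(2, 1), "N must be")
  expect_error(generateUnitDesign(2, 16, scheme = "halton"))
})

test_that("radial substitution matches the defining example", {
  R <- radialMatrices(matrix(c(0.1, 0.2), 1), matrix(c(0.9, 0.8), 1))
  expect_equal(R[[1]], matrix(c(0.9, 0.2), 1))
  expect_equal(R[[2]], matrix(c(0.1, 0.8), 1))
})

test_that("the full radial scheme implies N(k+2) model evaluations", {
  d <- generateUnitDesign(k = 8, N = 2000)
  nRuns <- nrow(designP(d)) + nrow(designQ(d)) +
    sum(vapply(designRadial(d), nrow, integer(1)))
  expect_identical(nRuns, 20000L)
})

test_that("scaling maps [0,1] affinely onto physical bounds", {
  specs <- variableSpec(c("Cab", "SD"), min = c(0, 0.5),
                        max = c(80, 1500), unit = c("ug/cm2", "1/ha"))
  X <- scaleDesign(rbind(c(0.5, 1), c(0, 0), c(1, 0.25)), specs)
  expect_equal(unname(X[1, "Cab"]), 40)    # midpoint of [0, 80]
  expect_equal(unname(X[1, "SD"]), 1500)   # upper bound
  expect_equal(unname(X[2, ]), c(0, 0.5))
  expect_equal(unname(X[3, ]), c(80, 0.5 + 0.25 * 1499.5))
  # property: random unit designs land inside the bounds, columnwise
  U <- matrix(runif(300), ncol = 3)
  sp3 <- variableSpec(c("a", "b", "c"), c(-1, 0, 10), c(1, 5, 11))
  Xs <- scaleDesign(U, sp3)
  for (j in 1:3)
    expect_true(all(Xs[, j] >= sp3$min[j] & Xs[, j] <= sp3$max[j]))
  expect_error(scaleDesign(U, variableSpec("a", 0, 1)), "column count")
  expect_error(variableSpec("a", 2, 1), "min < max")
  expect_error(variableSpec(c("a", "a"), c(0, 0), c(1, 1)), "unique")
})

test_that("the default scheme is more uniform than pseudo-random sampling", {
  d <- generateUnitDesign(2, 512, "uniform-sobol")
  sob <- cbind(designP(d)[, 1], designQ(d)[, 1])  # any 2 of the 4 columns
  sob <- sobolSequence(512, 2)
  set.seed(99)
  rnd <- matrix(runif(512 * 2), ncol = 2)
  expect_lt(centeredL2Discrepancy(sob), centeredL2Discrepancy(rnd))
})

test_that("design matrices export to CSV", {
  d <- generateUnitDesign(2, 8)
  dir <- tempfile()
  paths <- writeDesignMatrices(d, dir)
  expect_true(all(file.exists(paths)))
  back <- as.matrix(read.csv(paths[1]))
  expect_equal(unname(back), unname(designP(d)), tolerance = 1e-12)
})
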