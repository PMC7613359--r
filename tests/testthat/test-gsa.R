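test_that("output moments follow the plug-in estimators", {
  m <- estimateOutputMoments(c(0, 1))
  expect_equal(m$f0Hat, 0.5)
  expect_equal(m$VHat, 0.25)
  m2 <- estimateOutputMoments(rep(3.7, 100))
  expect_equal(m2$VHat, 0)
  expect_error(estimateOutputMoments(c(1, NA)), "finite")
  expect_error(estimateOutputMoments(1), "at least two")
  # V of uniform(0,1) is 1/12; quasi-random sample converges well inside
  # three pseudo-random standard errors
  u <- sobolSequence(2^14, 1)
  se <- sqrt(var((u - mean(u))^2) / length(u))
  expect_lt(abs(estimateOutputMoments(u)$VHat - 1 / 12), 3 * se)
})

test_that("Saltelli estimators recover closed forms for a linear model", {
  b <- makeBenchmark("additive_linear", list(b = c(1, 2)))
  r <- saltelliEstimate(b$fun, b$k, 2^13)
  expect_equal(unname(firstOrder(r)), c(0.2, 0.8), tolerance = 0.02)
  expect_equal(unname(totalEffect(r)), c(0.2, 0.8), tolerance = 0.02)
  # additive model: STi = Si
  expect_lt(max(abs(totalEffect(r) - firstOrder(r))), 0.02)
  expect_lt(sum(firstOrder(r)), 1 + 0.02)
})

test_that("degenerate outputs are flagged and zeroed", {
  b <- makeBenchmark("constant")
  r <- saltelliEstimate(b$fun, b$k, 256)
  expect_true(r@degenerate)
  expect_equal(unname(firstOrder(r)), rep(0, 3))
  expect_equal(unname(totalEffect(r)), rep(0, 3))
  expect_error(normalizeTotalEffects(r), "degenerate")
})

test_that("invalid rows are excluded consistently across blocks", {
  b <- makeBenchmark("additive_linear", list(b = c(1, 2)))
  d <- generateUnitDesign(2, 4096)
  fP <- b$fun(designP(d)); fQ <- b$fun(designQ(d))
  fR <- lapply(designRadial(d), b$fun)
  bad <- c(5, 100, 2000)
  fP[bad[1]] <- NaN; fQ[bad[2]] <- NaN; fR[[2]][bad[3]] <- NaN
  r <- estimateSobolIndices(fP, fQ, fR)
  expect_identical(r@nExcluded, 3L)
  expect_identical(r@N, 4093L)
  expect_equal(unname(firstOrder(r)), c(0.2, 0.8), tolerance = 0.03)
  expect_error(estimateSobolIndices(fP[-1], fQ, fR), "same length")
})

test_that("total-effect normalization yields shares summing to one", {
  r <- new("GSAResult", variableNames = c("a", "b", "c"),
           Si = c(0.5, 0.1, 0.1), STi = c(0.6, 0.2, 0.2),
           SiRaw = c(0.5, 0.1, 0.1), STiRaw = c(0.6, 0.2, 0.2),
           f0Hat = 1, VHat = 1, N = 100L, nExcluded = 0L,
           degenerate = FALSE)
  sh <- normalizeTotalEffects(r)
  expect_equal(unname(sh), c(0.6, 0.2, 0.2))
  expect_equal(sum(sh), 1)
  df <- as.data.frame(r)
  expect_named(df, c("variable", "Si_raw", "Si", "STi_raw", "STi",
                     "STi_share", "N", "degenerate"))
})

test_that("an ignored input collects no sensitivity", {
  b <- makeBenchmark("dummy_variable")
  r <- saltelliEstimate(b$fun, b$k, 2^12)
  expect_lt(firstOrder(r)[["x3"]], 0.01)
  expect_lt(totalEffect(r)[["x3"]], 0.01)
})

test_that("total effects dominate first-order effects within noise", {
  for (nm in c("ishigami", "g_function", "additive_linear")) {
    b <- makeBenchmark(nm)
    r <- saltelliEstimate(b$fun, b$k, 2^12)
    expect_true(all(r@STiRaw - r@SiRaw > -0.03),
                label = paste(nm, "STi >= Si"))
  }
})

test_that("convergence scans tighten toward the large-N estimate", {
  b <- makeBenchmark("ishigami")
  sp <- variableSpec(paste0("x", 1:3), rep(0, 3), rep(1, 3))
  tab <- convergenceScan(function(X) b$fun(X), sp, c(64, 256, 1024, 4096))
  expect_identical(nrow(tab), 12L)
  ref <- tab$STi[tab$N == 4096]
  err <- vapply(c(64, 256, 1024), function(N)
    max(abs(tab$STi[tab$N == N] - ref)), numeric(1))
  expect_true(err[3] < err[1])
  expect_lt(max(abs(ref - b$STi)), 0.02)
  # degenerate and single-N edge cases
  cst <- convergenceScan(function(X) rep(2, nrow(X)), sp, c(16, 32))
  expect_true(all(cst$STi == 0))
  one <- convergenceScan(function(X) X[, 1], sp, 64)
  expect_identical(nrow(one), 3L)
  expect_error(convergenceScan(function(X) X[, 1], sp, c(64, 64)),
               "increasing")
})
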