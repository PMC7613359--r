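test_that("the expression grammar parses what it should and only that", {
  tr <- parseViExpression("(NIR-RED)/(NIR+RED)")
  syms <- viRequiredSymbols(new("VIDefinition", name = "x",
                                abbreviation = "x",
                                expression = "(NIR-RED)/(NIR+RED)",
                                targetVariable = "other",
                                applicableSensors = "grid", note = ""))
  expect_setequal(syms$roles, c("NIR", "RED"))
  w <- viRequiredSymbols(new("VIDefinition", name = "x", abbreviation = "x",
                             expression = "2*rho(1205)/(rho(1095)+rho(1275))",
                             targetVariable = "other",
                             applicableSensors = "grid", note = ""))
  expect_identical(w$wavelengths, c(1095, 1205, 1275))
  expect_error(parseViExpression("(NIR-"), "syntax error")
  expect_error(parseViExpression("NIR + FOO"), "unknown symbol")
  expect_error(parseViExpression("log(NIR)"), "not allowed")
  expect_error(parseViExpression("NIR <- 1"), "not allowed")
  expect_error(parseViExpression(""), "nonempty")
})

test_that("every shipped expression round-trips through the parser", {
  for (def in builtinRegistry()) {
    t1 <- parseViExpression(def@expression)
    t2 <- parseViExpression(serializeViExpression(t1))
    expect_identical(t1, t2, label = def@abbreviation)
  }
})

test_that("hand-computed index values are reproduced", {
  reg <- builtinRegistry()
  expect_equal(evaluateVi(reg[["NDVI"]], list(NIR = 0.5, RED = 0.1)),
               0.4 / 0.6)
  expect_equal(evaluateVi(reg[["NDVI"]], list(NIR = 0.3, RED = 0.3)), 0)
  rho <- function(l) c(`860` = 0.4, `1240` = 0.2)[[as.character(l)]]
  expect_equal(evaluateVi(reg[["NDWI"]], list(rho = rho)), 0.2 / 0.6)
  expect_equal(evaluateVi(reg[["EVI"]],
                          list(NIR = 0.4, RED = 0.1, BLUE = 0.05)),
               2.5 * 0.3 / ((0.4 + 0.6 - 0.375) + 1))
  # vectorised evaluation
  out <- evaluateVi(reg[["NDVI"]], list(NIR = c(0.5, 0.3),
                                        RED = c(0.1, 0.3)))
  expect_equal(out, c(2 / 3, 0))
})

test_that("degenerate denominators yield NaN rather than values", {
  ndvi <- builtinRegistry()[["NDVI"]]
  out <- evaluateVi(ndvi, list(NIR = c(0, 0.5), RED = c(0, 0.1)))
  expect_true(is.nan(out[1]))
  expect_equal(out[2], 2 / 3)
})

test_that("normalized-difference indices stay within [-1, 1]", {
  set.seed(5)
  n <- 500
  refl <- function() runif(n, 1e-4, 1)
  bands <- list(NIR = refl(), RED = refl(), GREEN = refl(), SWIR = refl())
  store <- new.env()
  rho <- function(l) {
    key <- as.character(l)
    if (is.null(store[[key]])) store[[key]] <- refl()
    store[[key]]
  }
  bands$rho <- rho
  for (abbr in c("NDVI", "GNDVI", "NDWI", "NDII", "SIWSI", "LWVI1",
                 "LWVI2")) {
    v <- evaluateVi(builtinRegistry()[[abbr]], bands)
    expect_true(all(v[!is.nan(v)] >= -1 & v[!is.nan(v)] <= 1),
                label = abbr)
  }
})

test_that("sensor applicability is enforced, not approximated", {
  l8 <- builtinRegistry("Landsat8")
  expect_false("CIrededge" %in% names(l8))   # no red-edge band
  expect_false("NDWI" %in% names(l8))        # no 1240 nm band
  expect_true("CIrededge" %in% names(builtinRegistry("Sentinel2")))
  expect_true("NDWI" %in% names(builtinRegistry("MODIS")))
  cir <- builtinRegistry()[["CIrededge"]]
  flat <- makeSpectrumSet(matrix(0.3, 1, 2101))
  b <- convolveToSensor(flat, "Landsat8")
  expect_error(evaluateViOnSpectra(cir, b, getSensor("Landsat8")),
               "not applicable")
})

test_that("the narrowband registry carries the full published sets", {
  en <- builtinRegistry("EnMAP")
  counts <- table(vapply(en, function(d) d@targetVariable, character(1)))
  expect_identical(as.integer(counts[c("LCC", "LWC", "LAI")]),
                   c(13L, 14L, 9L))
})

test_that("indices evaluate end-to-end on sensor band reflectances", {
  rt <- testLeaf()
  sp <- makeSpectrumSet(matrix(rt$reflectance, 1, byrow = TRUE))
  s2 <- getSensor("Sentinel2")
  b <- convolveToSensor(sp, s2)
  ndvi <- evaluateViOnSpectra(builtinRegistry()[["NDVI"]], b, s2)
  # healthy leaf: strong red absorption, high NIR
  expect_gt(ndvi, 0.5)
  expect_lt(ndvi, 1)
  # pure-rho index on the native grid needs no sensor
  wbi <- evaluateViOnSpectra(builtinRegistry()[["WBI"]], sp)
  expect_equal(wbi, rt$reflectance[970 - 399] / rt$reflectance[902 - 399])
  # role-based index without a sensor is rejected
  expect_error(evaluateViOnSpectra(builtinRegistry()[["NDVI"]], sp),
               "sensor is required")
})
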