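test_that("spectral response shapes honour their definitions", {
  grid <- 400:2500
  # boxcar: equal weights over the covered interval
  w <- bandSRF(700, 20, "boxcar", grid)
  on <- w > 0
  expect_identical(sum(on), 21L)
  expect_true(all(abs(w[on] - 1 / 21) < 1e-12))
  # gaussian: half the peak at center +/- fwhm/2 (before normalization the
  # ratio is preserved by the common normalization constant)
  g <- bandSRF(670, 20, "gaussian", grid)
  expect_equal(g[grid == 660] / g[grid == 670], 0.5, tolerance = 1e-9)
  expect_equal(sum(g), 1)
  expect_error(bandSRF(3000, 10, "gaussian", grid), "400-2500")
  expect_error(bandSRF(2400, 30, "gaussian", 400:1020), "intersect")
  expect_error(bandSRF(500, -1, "gaussian", grid), "positive")
})

test_that("convolution is a convex combination of the spectrum", {
  flat <- makeSpectrumSet(matrix(0.37, 1, 2101))
  b <- convolveToSensor(flat, "Landsat8")
  expect_true(all(abs(spectra(b) - 0.37) < 1e-12))
  # step spectrum with a boxcar band straddling the step
  step <- rep(0.2, 2101)
  step[(400:2500) >= 700] <- 0.4
  ss <- makeSpectrumSet(matrix(step, 1, byrow = TRUE))
  w <- bandSRF(700, 20, "boxcar", 400:2500)
  val <- drop(spectra(ss) %*% w)
  expect_equal(val, (10 * 0.2 + 11 * 0.4) / 21, tolerance = 1e-12)  # 0.3048
  # bounds preservation for an arbitrary spectrum
  set.seed(4)
  sp <- makeSpectrumSet(matrix(runif(2101, 0.1, 0.6), 1))
  bb <- convolveToSensor(sp, "Sentinel2")
  expect_true(all(spectra(bb) >= min(spectra(sp)) &
                    spectra(bb) <= max(spectra(sp))))
  # a 1-nm boxcar band reproduces the underlying sample
  w1 <- bandSRF(1205, 1, "boxcar", 400:2500)
  expect_equal(drop(spectra(sp) %*% w1), spectra(sp)[1, 1205 - 399])
})

test_that("nearest-sample lookup resolves wavelength terms", {
  sp <- makeSpectrumSet(matrix(seq(0, 1, length.out = 2101), 1))
  expect_identical(nearestBandValue(sp, 670.25),
                   spectra(sp)[, 670 - 399])
  expect_identical(nearestBandValue(sp, 900), spectra(sp)[, 900 - 399])
  expect_error(nearestBandValue(sp, 3000), "coverage")
  # ties break toward the lower wavelength
  two <- new("SpectrumSet", wavelengths = c(500, 600),
             values = matrix(c(0.1, 0.9), 1), gridId = "sensor-bands")
  expect_identical(nearestBandValue(two, 550), two@values[, 1])
})

test_that("bundled sensor definitions are consistent", {
  expect_setequal(listSensors(), c("Landsat8", "MODIS", "Sentinel2",
                                   "Sentinel3", "EnMAP"))
  for (nm in listSensors()) {
    s <- getSensor(nm)
    expect_true(validObject(s))
    b <- sensorBands(s)
    expect_false(anyDuplicated(b$band) > 0)
    expect_true(all(diff(b$center) > 0))
  }
  expect_identical(nrow(sensorBands(getSensor("EnMAP"))), 230L)
  expect_error(getSensor("ASTER"), "unknown sensor")
  # role override
  s <- getSensor("Sentinel2", roles = c(NIR = "B8a"))
  expect_identical(unname(sensorRoles(s)[["NIR"]]), "B8a")
})

test_that("every applicable index resolves all its symbols on its sensors", {
  for (nm in listSensors()) {
    sensor <- getSensor(nm)
    roles <- sensorRoles(sensor)
    grid <- sensorBands(sensor)$center
    for (def in builtinRegistry(sensor)) {
      need <- viRequiredSymbols(def)
      expect_true(all(need$roles %in% names(roles)),
                  label = sprintf("%s roles on %s", def@abbreviation, nm))
      if (length(need$wavelengths))
        expect_true(all(need$wavelengths >= min(grid) - max(diff(grid)) &
                          need$wavelengths <= max(grid) + max(diff(grid))),
                    label = sprintf("%s wavelengths on %s",
                                    def@abbreviation, nm))
    }
  }
})
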