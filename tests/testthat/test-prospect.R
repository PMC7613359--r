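test_that("leaf spectra respect length, bounds and energy conservation", {
  set.seed(1)
  for (i in 1:5) {
    leaf <- list(N_struct = runif(1, 1, 2.6), Cab = runif(1, 0, 80),
                 Cw = runif(1, 0.001, 0.08), Cm = runif(1, 0.001, 0.02))
    rt <- prospect4(leaf)
    expect_length(rt$reflectance, 2101)
    expect_length(rt$transmittance, 2101)
    expect_true(all(rt$reflectance >= 0 & rt$reflectance <= 1))
    expect_true(all(rt$transmittance >= 0 & rt$transmittance <= 1))
    expect_true(all(rt$reflectance + rt$transmittance <= 1 + 1e-9))
  }
  expect_error(prospect4(list(N_struct = 0.5, Cab = 10, Cw = 0.01,
                              Cm = 0.01)), "N_struct")
  expect_error(prospect4(list(N_struct = 1.5, Cab = 10, Cw = 0.01)),
               "must provide")
})

test_that("red reflectance decreases monotonically with chlorophyll", {
  i670 <- 671  # 400:2500 grid position of 670 nm
  r <- vapply(seq(0, 80, by = 10), function(cab) {
    prospect4(list(N_struct = 1.5, Cab = cab, Cw = 0.01,
                   Cm = 0.009))$reflectance[i670]
  }, numeric(1))
  expect_true(all(diff(r) <= 1e-12))
})

test_that("the Stokes stack matches iterative layer adding", {
  # independent oracle: combine identical layers one at a time with the
  # two-stream adding equations and compare to the closed form
  addLayers <- function(r, t, n) {
    R <- r; T <- t
    for (i in seq_len(n - 1)) {
      dn <- 1 - R * r
      T2 <- T * t / dn
      R <- r + t * R * t / dn
      ## note: adding layer BELOW the current stack:
      ## R_new = R_top + T_top^2 R_bot / (1 - R_top R_bot) with identical
      ## layers; recompute properly below
      T <- T2
    }
    list(R = R, T = T)
  }
  # correct adding recursion (stack of j layers + 1 layer)
  addLayers <- function(r, t, n) {
    R <- r; T <- t
    if (n == 1) return(list(R = R, T = T))
    for (i in seq_len(n - 1)) {
      dn <- 1 - R * r
      Rnew <- R + T^2 * r / dn
      Tnew <- T * t / dn
      R <- Rnew; T <- Tnew
    }
    list(R = R, T = T)
  }
  set.seed(2)
  for (i in 1:20) {
    r <- runif(1, 0.02, 0.45)
    t <- runif(1, 0.02, min(0.5, 0.95 - r))
    n <- sample(1:5, 1)
    oracle <- addLayers(r, t, n)
    closed <- vigsa:::.stokesStack(r, t, n)
    expect_equal(closed$R, oracle$R, tolerance = 1e-10)
    expect_equal(closed$T, oracle$T, tolerance = 1e-10)
  }
  # conservative limit r + t = 1
  cons <- vigsa:::.stokesStack(0.4, 0.6, 3)
  expect_equal(cons$R + cons$T, 1, tolerance = 1e-12)
  expect_equal(cons$T, 0.6 / (0.6 + 0.4 * 3), tolerance = 1e-12)
  # transparent stack
  z <- vigsa:::.stokesStack(0.3, 0.3, 0)
  expect_equal(z$R, 0)
  expect_equal(z$T, 1)
})

test_that("surface transmissivity matches a Monte Carlo Fresnel average", {
  set.seed(3)
  n <- 1.45
  for (alpha in c(40, 90)) {
    a <- alpha * pi / 180
    # sample incidence angles with the projected-solid-angle density
    u <- runif(2e5)
    theta <- asin(sqrt(u) * sin(a))
    stt <- sin(theta) / n
    ctt <- sqrt(1 - stt^2)
    rs <- ((cos(theta) - n * ctt) / (cos(theta) + n * ctt))^2
    rp <- ((n * cos(theta) - ctt) / (n * cos(theta) + ctt))^2
    mc <- mean(1 - (rs + rp) / 2)
    expect_equal(tavTransmissivity(alpha, n), mc, tolerance = 2e-3)
  }
  expect_true(all(diff(tavTransmissivity(90, c(1.3, 1.4, 1.5))) < 0))
})

test_that("the layer transmission integral behaves at its limits", {
  expect_equal(vigsa:::.layerTransmission(0), 1)
  k <- c(1e-6, 0.01, 0.1, 1, 5, 20)
  th <- vigsa:::.layerTransmission(k)
  expect_true(all(diff(th) < 0))          # more absorption, less transmission
  expect_true(all(th >= 0 & th <= 1))
  # independent check by numerical quadrature of the hemispheric integral
  # theta(k) = int_0^1 exp(-k/mu) 2 mu dmu
  quadTheta <- function(k)
    integrate(function(mu) 2 * mu * exp(-k / mu), 0, 1,
              rel.tol = 1e-10)$value
  for (kk in c(0.05, 0.5, 2))
    expect_equal(vigsa:::.layerTransmission(kk), quadTheta(kk),
                 tolerance = 1e-7)
})

test_that("coefficient tables load, validate and checksum", {
  co <- syntheticLeafCoefficients()
  expect_identical(co$wavelength_nm, 400:2500)
  expect_true(all(co$k_Cab >= 0) && all(co$k_Cw > 0) && all(co$k_Cm > 0))
  # pigment absorption confined to the visible
  expect_true(all(co$k_Cab[co$wavelength_nm > 800] < 1e-4))
  f <- tempfile(fileext = ".csv")
  write.csv(co[, 1:5], f, row.names = FALSE)
  back <- readLeafCoefficients(f)
  expect_equal(back$k_Cw, co$k_Cw, tolerance = 1e-9)
  md5 <- unname(tools::md5sum(f))
  expect_silent(readLeafCoefficients(f, checksum = md5))
  expect_error(readLeafCoefficients(f, checksum = "deadbeef"), "checksum")
  bad <- tempfile(fileext = ".csv")
  write.csv(co[1:100, 1:5], bad, row.names = FALSE)
  expect_error(readLeafCoefficients(bad), "400-2500")
})
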