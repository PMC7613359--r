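test_that("closed-form canopy operators match numerical ODE integration", {
  library(deSolve)
  lidf <- lidfEllipsoidal(48)
  cases <- list(
    list(rho = 0.45, tau = 0.42, lai = 2.7, tts = 35),   # NIR-like
    list(rho = 0.05, tau = 0.02, lai = 4.0, tts = 20),   # red-like
    list(rho = 0.25, tau = 0.20, lai = 0.6, tts = 55))   # sparse
  for (cs in cases) {
    s <- vigsa:::.foursail(cs$rho, cs$tau, cs$lai, lidf, cs$tts, 0, 0,
                           hotspot = 0.01, rsoil = 0)
    cf <- vigsa:::.suits(cs$tts, 0, 0, lidf)
    sigb <- cf$ddb * cs$rho + cf$ddf * cs$tau
    sigf <- cf$ddf * cs$rho + cf$ddb * cs$tau
    att <- 1 - sigf
    sb <- cf$sdb * cs$rho + cf$sdf * cs$tau
    sf <- cf$sdf * cs$rho + cf$sdb * cs$tau
    vb <- cf$dob * cs$rho + cf$dof * cs$tau
    vf <- cf$dof * cs$rho + cf$dob * cs$tau
    deriv <- function(x, y, p)
      list(c(-att * y[1] + sigb * y[2] + sf * y[3],
             att * y[2] - sigb * y[1] - sb * y[3],
             -cf$ks * y[3]))
    xs <- seq(0, cs$lai, length.out = 801)
    solveBVP <- function(Es0, Em0) {
      run <- function(Ep0)
        ode(c(Em0, Ep0, Es0), xs, deriv, NULL, atol = 1e-12, rtol = 1e-10)
      r0 <- run(0); r1 <- run(1)
      EpL <- function(r) r[length(xs), 3]
      run(-EpL(r0) / (EpL(r1) - EpL(r0)))
    }
    trap <- function(f) sum((f[-1] + f[-length(xs)]) / 2 * diff(xs))
    # diffuse incidence: rdd, tdd, rdo, tdo
    sol <- solveBVP(0, 1)
    expect_equal(s$rdd, as.numeric(sol[1, 3]), tolerance = 1e-5)
    expect_equal(s$tdd, as.numeric(sol[length(xs), 2]), tolerance = 1e-5)
    rdoN <- trap(exp(-cf$ko * xs) * (vb * sol[, 2] + vf * sol[, 3]))
    tdoN <- trap(exp(-cf$ko * (cs$lai - xs)) *
                   (vf * sol[, 2] + vb * sol[, 3]))
    expect_equal(s$rdo, rdoN, tolerance = 1e-4)
    expect_equal(s$tdo, tdoN, tolerance = 1e-4)
    # solar incidence: rsd, tsd and the multiple-scattering term of rso
    sol2 <- solveBVP(1, 0)
    expect_equal(s$rsd, as.numeric(sol2[1, 3]), tolerance = 1e-5)
    expect_equal(s$tsd, as.numeric(sol2[length(xs), 2]), tolerance = 1e-5)
    rsodN <- trap(exp(-cf$ko * xs) * (vb * sol2[, 2] + vf * sol2[, 3]))
    w <- cf$sob * cs$rho + cf$sof * cs$tau
    hs <- vigsa:::.hotspotIntegral(cf$ks, cf$ko, cs$lai, 0.01,
                                   tan(cs$tts * pi / 180), s$tss, s$too)
    expect_equal(s$rso - w * cs$lai * hs$sumint, rsodN, tolerance = 1e-4)
  }
})

test_that("canopy limits behave physically", {
  rt <- testLeaf()
  soil <- syntheticSoilSpectrum(rt$wavelengths, 0.8)
  # no canopy: the scene is the soil
  toc0 <- sailTOC(rt$reflectance, rt$transmittance,
                  list(LAI = 0, LAD = 50, SZA = 30), soil)
  expect_equal(toc0, soil)
  # dense canopy decouples from the soil in the visible
  tocA <- sailTOC(rt$reflectance, rt$transmittance,
                  list(LAI = 10, LAD = 50, SZA = 30), soil)
  tocB <- sailTOC(rt$reflectance, rt$transmittance,
                  list(LAI = 10, LAD = 50, SZA = 30), soil * 0.1)
  vis <- rt$wavelengths <= 700
  expect_lt(max(abs(tocA - tocB)[vis]), 0.01)
  # no scatterers anywhere: black scene
  z <- rep(0, 2101)
  expect_equal(sailTOC(z, z, list(LAI = 3, LAD = 50, SZA = 30), z), z)
  # bounds
  expect_true(all(tocA >= 0 & tocA <= 1))
  expect_error(sailTOC(rt$reflectance, rt$transmittance,
                       list(LAI = 3, LAD = 50, SZA = 95), soil),
               "geometry")
})

test_that("soil brightening never darkens a sparse canopy", {
  rt <- testLeaf()
  base <- syntheticSoilSpectrum(rt$wavelengths, 1)
  tocs <- vapply(c(0.2, 0.5, 0.8), function(cf) {
    sailTOC(rt$reflectance, rt$transmittance,
            list(LAI = 0.4, LAD = 45, SZA = 30), cf * base)
  }, numeric(2101))
  expect_true(all(diff(t(tocs)) >= -1e-9))
})

test_that("the leaf inclination distribution is a proper density", {
  for (ang in c(15, 35, 57, 75)) {
    l <- lidfEllipsoidal(ang)
    expect_equal(sum(l$freq), 1, tolerance = 1e-9)
    expect_true(all(l$freq >= 0))
    # the class-discretised mean tracks the requested mean
    expect_equal(sum(l$angles * l$freq), ang, tolerance = 3)
  }
  # planophile vs erectophile weight placement
  expect_gt(sum(lidfEllipsoidal(20)$freq[1:3]),
            sum(lidfEllipsoidal(70)$freq[1:3]))
})

test_that("hotspot handling brackets the gap probability", {
  lidf <- lidfEllipsoidal(50)
  s <- vigsa:::.foursail(0.4, 0.4, 3, lidf, 30, 0, 0, hotspot = 0.05,
                         rsoil = 0)
  expect_gte(s$tsstoo, s$tss * s$too - 1e-12)
  expect_lte(s$tsstoo, min(s$tss, s$too) + 1e-12)
  # observer in the solar direction: full correlation
  hot <- vigsa:::.foursail(0.4, 0.4, 3, lidf, 30, 30, 0, hotspot = 0.05,
                           rsoil = 0)
  expect_equal(hot$tsstoo, hot$tss, tolerance = 1e-12)
  # hotspot disabled reduces to independent gaps
  off <- vigsa:::.foursail(0.4, 0.4, 3, lidf, 30, 0, 0, hotspot = 0,
                           rsoil = 0)
  expect_equal(off$tsstoo, off$tss * off$too, tolerance = 1e-12)
})
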