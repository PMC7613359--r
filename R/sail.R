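## Four-stream turbid-medium canopy reflectance model.
##
## The canopy layer is described by the classical four-stream system (direct
## solar flux, downward and upward diffuse flux, flux-equivalent radiance in
## the viewing direction) with extinction/scattering coefficients obtained
## by integrating leaf-projection geometry over the leaf inclination
## distribution. The diffuse operators are closed-form solutions of the
## two-stream ODE system; the bidirectional single-scattering term carries
## the hotspot (gap-correlation) integral; canopy and soil are combined with
## the standard adding equations.

# --- Leaf inclination distribution (ellipsoidal, parameterised by mean
# --- inclination angle) -----------------------------------------------------

.litab <- c(5, 15, 25, 35, 45, 55, 65, 75, 81, 83, 85, 87, 89)
.litab_edges <- c(seq(0, 80, 10), seq(82, 90, 2))

# Unnormalised ellipsoidal leaf-angle density over inclination theta (rad),
# axis ratio chi (horizontal/vertical semi-axis).
.ellipsDensity <- function(thetaRad, chi) {
  chi^3 * sin(thetaRad) / (cos(thetaRad)^2 + chi^2 * sin(thetaRad)^2)^2
}

.lidfTables <- function() {
  if (!is.null(.vigsa_cache$lidf)) return(.vigsa_cache$lidf)
  fine <- seq(0.125, 89.875, by = 0.25)
  fineRad <- fine * pi / 180
  cls <- findInterval(fine, .litab_edges, rightmost.closed = TRUE)
  chiGrid <- exp(seq(log(0.005), log(500), length.out = 240))
  meanAngle <- vapply(chiGrid, function(chi) {
    g <- .ellipsDensity(fineRad, chi)
    sum(fine * g) / sum(g)
  }, numeric(1))
  # mean angle is strictly decreasing in chi: invert by spline
  inv <- splinefun(rev(meanAngle), rev(log(chiGrid)), method = "monoH.FC")
  out <- list(fine = fine, fineRad = fineRad, cls = cls, inv = inv,
              range = range(meanAngle))
  .vigsa_cache$lidf <- out
  out
}

#' Leaf inclination distribution from a mean leaf angle
#'
#' Converts a scalar mean leaf inclination angle (degrees from horizontal:
#' 0 = planophile, 90 = erectophile) into class frequencies of the
#' ellipsoidal leaf-angle distribution over the 13 standard inclination
#' classes (centres 5..75 by 10 degrees, then 81, 83, 85, 87, 89).
#'
#' @param meanAngle mean leaf inclination in degrees, within (0, 90).
#' @return list with `angles` (class centres, degrees) and `freq`
#'   (frequencies summing to 1).
#' @examples
#' l <- lidfEllipsoidal(57)  # near-spherical distribution
#' sum(l$freq)
#' @export
lidfEllipsoidal <- function(meanAngle) {
  tb <- .lidfTables()
  meanAngle <- min(max(meanAngle, tb$range[1]), tb$range[2])
  chi <- exp(tb$inv(meanAngle))
  g <- .ellipsDensity(tb$fineRad, chi)
  freq <- as.numeric(rowsum(g, tb$cls))
  list(angles = .litab, freq = freq / sum(freq))
}

# --- SUITS coefficients -----------------------------------------------------

# Geometric scattering factors for one leaf inclination (all angles in
# degrees): chi_s/chi_o are projection (extinction) cross-sections in the
# solar/viewing directions, frho/ftau the bidirectional scattering
# contributions of leaf reflectance and transmittance.
.volscatt <- function(tts, tto, psi, ttl) {
  rd <- pi / 180
  cts <- cos(rd * tts); cto <- cos(rd * tto)
  sts <- sin(rd * tts); sto <- sin(rd * tto)
  cospsi <- cos(rd * psi); psir <- rd * psi
  cttl <- cos(rd * ttl); sttl <- sin(rd * ttl)
  cs <- cttl * cts; co <- cttl * cto
  ss <- sttl * sts; so <- sttl * sto
  cosbts <- if (abs(ss) > 1e-6) -cs / ss else 5
  cosbto <- if (abs(so) > 1e-6) -co / so else 5
  if (abs(cosbts) < 1) {
    bts <- acos(cosbts); ds <- ss
  } else {
    bts <- pi; ds <- cs
  }
  chi_s <- 2 / pi * ((bts - pi / 2) * cs + sin(bts) * ss)
  if (abs(cosbto) < 1) {
    bto <- acos(cosbto); doo <- so
  } else if (tto < 90) {
    bto <- pi; doo <- co
  } else {
    bto <- 0; doo <- -co
  }
  chi_o <- 2 / pi * ((bto - pi / 2) * co + sin(bto) * so)
  btran1 <- abs(bts - bto)
  btran2 <- pi - abs(bts + bto - pi)
  if (psir <= btran1) {
    bt1 <- psir; bt2 <- btran1; bt3 <- btran2
  } else {
    bt1 <- btran1
    if (psir <= btran2) {
      bt2 <- psir; bt3 <- btran2
    } else {
      bt2 <- btran2; bt3 <- psir
    }
  }
  t1 <- 2 * cs * co + ss * so * cospsi
  t2 <- if (bt2 > 0)
    sin(bt2) * (2 * ds * doo + ss * so * cos(bt1) * cos(bt3)) else 0
  denom <- 2 * pi^2
  frho <- max(((pi - bt2) * t1 + t2) / denom, 0)
  ftau <- max((-bt2 * t1 + t2) / denom, 0)
  c(chi_s = chi_s, chi_o = chi_o, frho = frho, ftau = ftau)
}

# Canopy-level extinction and scattering coefficients for a given geometry
# and leaf inclination distribution.
.suits <- function(tts, tto, psi, lidf) {
  rd <- pi / 180
  cts <- cos(rd * tts); cto <- cos(rd * tto)
  ks <- 0; ko <- 0; bf <- 0; sob <- 0; sof <- 0
  for (i in seq_along(lidf$angles)) {
    ttl <- lidf$angles[i]
    f <- lidf$freq[i]
    v <- .volscatt(tts, tto, psi, ttl)
    ks <- ks + f * v[["chi_s"]] / cts
    ko <- ko + f * v[["chi_o"]] / cto
    bf <- bf + f * cos(rd * ttl)^2
    sob <- sob + f * v[["frho"]] * pi / (cts * cto)
    sof <- sof + f * v[["ftau"]] * pi / (cts * cto)
  }
  list(ks = ks, ko = ko,
       sdb = 0.5 * (ks + bf), sdf = 0.5 * (ks - bf),
       dob = 0.5 * (ko + bf), dof = 0.5 * (ko - bf),
       ddb = 0.5 * (1 + bf), ddf = 0.5 * (1 - bf),
       sob = sob, sof = sof)
}

# --- closed-form exponential integrals with small-denominator guards -------

# int_0^L exp(-d x) dx
.eint <- function(d, L) {
  small <- abs(d) < 1e-8
  out <- (1 - exp(-d * L)) / ifelse(small, 1, d)
  out[small] <- L * (1 - d[small] * L / 2)
  out
}

# (exp(-a L) - exp(-b L)) / (b - a)
.jfunc1 <- function(a, b, L) {
  d <- b - a
  small <- abs(d) < 1e-8
  out <- (exp(-a * L) - exp(-b * L)) / ifelse(small, 1, d)
  out[small] <- (L * exp(-a * L) * (1 - d * L / 2))[small]
  out
}

# --- the four-stream layer + soil solution ----------------------------------

# rho, tau, rsoil: vectors over wavelength; lai, hotspot scalars;
# geometry in degrees. Returns all layer operators and scene reflectances.
.foursail <- function(rho, tau, lai, lidf, tts, tto = 0, psi = 0,
                      hotspot = 0.01, rsoil) {
  nw <- length(rho)
  stopifnot(length(tau) == nw, length(rsoil) == nw)
  if (tts < 0 || tts >= 90 || tto < 0 || tto >= 90)
    stop("invalid geometry: zenith angles must lie in [0, 90)")
  if (lai <= 0) {
    one <- rep(1, nw); zero <- rep(0, nw)
    return(list(rsot = rsoil, rdot = rsoil, rddt = rsoil, rsdt = rsoil,
                rdd = zero, tdd = one, rsd = zero, tsd = zero,
                rdo = zero, tdo = zero, rso = zero,
                tss = 1, too = 1, tsstoo = 1, ks = NA_real_, ko = NA_real_))
  }

  cf <- .suits(tts, tto, psi, lidf)
  ks <- cf$ks; ko <- cf$ko

  sigb <- cf$ddb * rho + cf$ddf * tau
  sigf <- cf$ddf * rho + cf$ddb * tau
  att <- 1 - sigf
  m <- sqrt(pmax(att^2 - sigb^2, 1e-24))
  rinf <- sigb / (att + m)

  sb <- cf$sdb * rho + cf$sdf * tau
  sf <- cf$sdf * rho + cf$sdb * tau
  vb <- cf$dob * rho + cf$dof * tau
  vf <- cf$dof * rho + cf$dob * tau
  w <- cf$sob * rho + cf$sof * tau

  e1 <- exp(-m * lai)
  denom <- 1 - rinf^2 * e1^2
  tss <- exp(-ks * lai)
  too <- exp(-ko * lai)

  # diffuse-diffuse operators
  Ad <- 1 / denom
  Bd <- -Ad * rinf * e1^2
  rdd <- Ad * rinf * (1 - e1^2)
  tdd <- e1 * (1 - rinf^2) / denom

  # solar-excited diffuse fluxes: particular solution ~ exp(-ks x)
  D0 <- m^2 - ks^2
  bad <- abs(D0) < 1e-9
  D0[bad] <- ifelse(D0[bad] >= 0, 1e-9, -1e-9)
  Pm <- (sf * (att + ks) + sb * sigb) / D0
  Pp <- (sb * (att - ks) + sf * sigb) / D0
  As <- (rinf * e1 * tss * Pp - Pm) / denom
  Bs <- -e1 * (As * rinf * e1 + tss * Pp)
  rsd <- As * rinf + Bs + Pp
  tsd <- As * e1 + Bs * rinf / e1 + Pm * tss
  rsd <- pmax(rsd, 0); tsd <- pmax(tsd, 0)

  # directional operators (integrals of the diffuse fluxes along the view
  # path); E-(x) = A e^{-mx} + B rinf e^{mx} (+ particular), E+ symmetric.
  Ikm <- .eint(ko + m, lai)       # e^{-ko x} e^{-m x}
  Ikp <- .eint(ko - m, lai)       # e^{-ko x} e^{+m x}
  rdo <- (vb + vf * rinf) * Ad * Ikm + (vb * rinf + vf) * Bd * Ikp
  Jm <- .jfunc1(m, ko, lai)                        # bottom exit, e^{-mx} mode
  Jp <- (exp(m * lai) - too) / (ko + m)            # bottom exit, e^{+mx} mode
  tdo <- (vf + vb * rinf) * Ad * Jm + (vf * rinf + vb) * Bd * Jp
  Iks <- .eint(ko + ks, lai)
  rsod <- (vb + vf * rinf) * As * Ikm + (vb * rinf + vf) * Bs * Ikp +
    (vb * Pm + vf * Pp) * Iks
  rdo <- pmax(rdo, 0); tdo <- pmax(tdo, 0); rsod <- pmax(rsod, 0)

  # single scattering with hotspot (gap correlation along sun/view paths)
  rd <- pi / 180
  dso <- sqrt(tan(rd * tts)^2 + tan(rd * tto)^2 -
                2 * tan(rd * tts) * tan(rd * tto) * cos(rd * psi))
  hs <- .hotspotIntegral(ks, ko, lai, hotspot, dso, tss, too)
  rsos <- w * lai * hs$sumint
  rso <- rsos + rsod
  tsstoo <- hs$tsstoo

  # adding the soil below the layer
  dn <- 1 - rsoil * rdd
  rddt <- rdd + tdd * rsoil * tdd / dn
  rsdt <- rsd + (tss + tsd) * rsoil * tdd / dn
  rdot <- rdo + tdd * rsoil * (tdo + too) / dn
  rsost <- rso + tsstoo * rsoil
  rsodt <- ((tss + tsd) * tdo + (tsd + tss * rsoil * rdd) * too) * rsoil / dn
  rsot <- rsost + rsodt

  list(rsot = pmin(pmax(rsot, 0), 1), rdot = pmin(pmax(rdot, 0), 1),
       rddt = rddt, rsdt = rsdt,
       rdd = rdd, tdd = tdd, rsd = rsd, tsd = tsd,
       rdo = rdo, tdo = tdo, rso = rso,
       tss = tss, too = too, tsstoo = tsstoo, ks = ks, ko = ko)
}

# Kuusk-style hotspot integral: bidirectional gap probability and the
# single-scattering path integral, by the standard 20-step exponential
# quadrature.
.hotspotIntegral <- function(ks, ko, lai, hotspot, dso, tss, too) {
  if (hotspot <= 0) {
    return(list(tsstoo = tss * too,
                sumint = .eint(ks + ko, lai) / lai))
  }
  alf <- if (dso == 0) 0 else (dso / hotspot) * 2 / (ks + ko)
  alf <- min(alf, 200)
  if (alf == 0) {
    # exact hotspot direction: full path correlation
    return(list(tsstoo = tss, sumint = (1 - tss) / (ks * lai)))
  }
  fhot <- lai * sqrt(ks * ko)
  x1 <- 0; y1 <- 0; f1 <- 1
  fint <- (1 - exp(-alf)) * 0.05
  sumint <- 0
  for (i in 1:20) {
    x2 <- if (i < 20) -log(1 - i * fint) / alf else 1
    y2 <- -(ko + ks) * lai * x2 + fhot * (1 - exp(-alf * x2)) / alf
    f2 <- exp(y2)
    sumint <- sumint +
      if (abs(y2 - y1) > 1e-12) (f2 - f1) * (x2 - x1) / (y2 - y1)
      else f1 * (x2 - x1)
    x1 <- x2; y1 <- y2; f1 <- f2
  }
  list(tsstoo = f1, sumint = sumint)
}

#' Top-of-canopy reflectance of a homogeneous canopy
#'
#' Couples precomputed leaf reflectance/transmittance spectra to the
#' four-stream turbid-medium canopy solution over a soil background and
#' returns the bidirectional top-of-canopy reflectance factor for the given
#' sun-target-sensor geometry (optionally blended with the
#' hemispherical-directional factor by the diffuse irradiance fraction).
#'
#' @param leafRefl,leafTrans leaf reflectance and transmittance vectors on
#'   the working wavelength grid.
#' @param canopy named list: `LAI` (total leaf area index, m2/m2), `LAD`
#'   (mean leaf inclination angle, degrees), `SZA` (solar zenith, degrees),
#'   optional `OZA` (observer zenith, default 0 = nadir), `RAA` (relative
#'   azimuth, default 0), `hotspot` (hot-spot parameter, default 0.01) and
#'   `skyl` (diffuse irradiance fraction, default 0).
#' @param soilSpectrum soil reflectance vector on the same grid.
#' @return top-of-canopy reflectance vector in `[0, 1]`.
#' @examples
#' rt <- prospect4(list(N_struct = 1.5, Cab = 40, Cw = 0.01, Cm = 0.009))
#' soil <- syntheticSoilSpectrum(rt$wavelengths, 0.8)
#' toc <- sailTOC(rt$reflectance, rt$transmittance,
#'                list(LAI = 3, LAD = 50, SZA = 30), soil)
#' @export
sailTOC <- function(leafRefl, leafTrans, canopy, soilSpectrum) {
  canopy <- modifyList(list(OZA = 0, RAA = 0, hotspot = 0.01, skyl = 0),
                       as.list(canopy))
  for (f in c("LAI", "LAD", "SZA"))
    if (is.null(canopy[[f]])) stop("canopy must provide ", f)
  if (length(leafRefl) != length(soilSpectrum))
    stop("leaf and soil spectra must share one wavelength grid")
  lidf <- lidfEllipsoidal(canopy$LAD)
  s <- .foursail(leafRefl, leafTrans, canopy$LAI, lidf,
                 tts = canopy$SZA, tto = canopy$OZA, psi = canopy$RAA,
                 hotspot = canopy$hotspot, rsoil = soilSpectrum)
  (1 - canopy$skyl) * s$rsot + canopy$skyl * s$rdot
}
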