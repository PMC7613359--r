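## Spectral coefficient tables for the leaf model, and the background soil
## spectrum. The bundled tables are SYNTHETIC: they are built
## programmatically from parametric absorption features and published
## optical-constant anchor values, emulating the shape and magnitude of the
## published four-parameter leaf calibration, because the original
## calibration files are not redistributable here. All qualitative spectral
## behaviour (pigment absorption confined to the visible, liquid-water bands
## at 970/1200/1450/1940 nm, dry-matter SWIR features) is preserved.

.vigsa_cache <- new.env(parent = emptyenv())

# Liquid-water absorption coefficient anchors [1/cm], interpolated on a log
# scale. Approximate values from standard optical-constant compilations.
.water_anchors <- function() {
  data.frame(
    wl = c(400, 450, 500, 550, 600, 650, 700, 730, 750, 780, 800, 840,
           870, 900, 930, 950, 970, 990, 1000, 1030, 1070, 1100, 1130,
           1150, 1180, 1200, 1230, 1270, 1300, 1350, 1380, 1400, 1430,
           1450, 1470, 1500, 1550, 1600, 1650, 1700, 1750, 1800, 1850,
           1880, 1900, 1920, 1940, 1960, 2000, 2050, 2100, 2150, 2200,
           2250, 2300, 2350, 2400, 2450, 2500),
    k = c(6e-4, 3e-4, 2.5e-4, 4.5e-4, 2.3e-3, 3.4e-3, 6e-3, 1.6e-2,
          2.6e-2, 2.3e-2, 2.0e-2, 4.0e-2, 5.5e-2, 6.8e-2, 1.5e-1, 2.8e-1,
          4.5e-1, 4.2e-1, 3.6e-1, 1.9e-1, 1.3e-1, 1.8e-1, 5.5e-1, 8.0e-1,
          1.00, 1.04, 0.95, 0.86, 1.0, 2.6, 5.5, 12, 25, 29, 26, 21, 11,
          6.7, 4.8, 5.3, 6.7, 8.0, 13, 23, 55, 105, 125, 110, 69, 45, 26,
          19, 16.5, 18, 27, 39, 50, 59, 72)
  )
}

.gauss <- function(wl, center, width) exp(-((wl - center) / width)^2)

#' Synthetic leaf-model coefficient table
#'
#' Builds the wavelength-indexed coefficient table consumed by
#' [prospect4()]: refractive index `refractive_index` and specific
#' absorption coefficients `k_Cab` (cm^2/ug), `k_Cw` (1/cm) and `k_Cm`
#' (cm^2/g) on the 1-nm grid 400-2500 nm (2101 rows). The table is
#' synthetic (see the package vignette): pigment absorption is a sum of
#' Gaussian bands peaking near 425/465/662 nm and vanishing beyond the red
#' edge, water absorption interpolates published liquid-water
#' optical-constant anchors, and dry matter combines a SWIR-rising baseline
#' with cellulose/lignin-like features near 1730, 2100 and 2300 nm.
#'
#' The returned table is cached per session and carries the precomputed
#' surface-transmissivity columns used by the plate model.
#'
#' @return data.frame with columns `wavelength_nm`, `refractive_index`,
#'   `k_Cab`, `k_Cw`, `k_Cm` (plus precomputed `tav40`/`tav90` columns).
#' @examples
#' head(syntheticLeafCoefficients())
#' @export
syntheticLeafCoefficients <- function() {
  if (!is.null(.vigsa_cache$leafCoeffs)) return(.vigsa_cache$leafCoeffs)
  wl <- 400:2500
  nr <- 1.32 + 0.21 * exp(-(wl - 400) / 900)
  kab <- 0.062 * .gauss(wl, 425, 28) + 0.040 * .gauss(wl, 465, 30) +
    0.012 * .gauss(wl, 550, 70) + 0.018 * .gauss(wl, 642, 25) +
    0.048 * .gauss(wl, 662, 20) + 0.008 * .gauss(wl, 690, 15)
  wa <- .water_anchors()
  kw <- exp(splinefun(wa$wl, log(wa$k), method = "natural")(wl))
  km <- 2 + 28 / (1 + exp(-(wl - 1700) / 200)) +
    14 * .gauss(wl, 1730, 40) + 20 * .gauss(wl, 2100, 70) +
    22 * .gauss(wl, 2300, 90)
  out <- data.frame(wavelength_nm = wl, refractive_index = nr,
                    k_Cab = kab, k_Cw = kw, k_Cm = km)
  out <- prepareLeafCoefficients(out)
  .vigsa_cache$leafCoeffs <- out
  out
}

#' Read a leaf coefficient table from a plain-text file
#'
#' Reads a whitespace- or comma-separated table with columns
#' `wavelength_nm`, `refractive_index`, `k_Cab`, `k_Cw`, `k_Cm` covering
#' 400-2500 nm at 1 nm, optionally verifying an MD5 checksum of the file,
#' and precomputes the surface-transmissivity terms.
#'
#' @param path file path.
#' @param checksum optional expected MD5 hex digest of the file.
#' @return prepared coefficient data.frame (see
#'   [syntheticLeafCoefficients()]).
#' @export
readLeafCoefficients <- function(path, checksum = NULL) {
  if (!is.null(checksum)) {
    got <- unname(tools::md5sum(path))
    if (!identical(tolower(got), tolower(checksum)))
      stop(sprintf("coefficient file checksum mismatch: %s", got))
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
  df <- read.table(path, header = TRUE, sep = sep)
  need <- c("wavelength_nm", "refractive_index", "k_Cab", "k_Cw", "k_Cm")
  if (!all(need %in% names(df)))
    stop("coefficient table must have columns ",
         paste(need, collapse = ", "))
  if (!identical(as.integer(df$wavelength_nm), 400:2500))
    stop("coefficient table must cover 400-2500 nm at 1 nm resolution")
  prepareLeafCoefficients(df[, need])
}

#' Precompute surface transmissivities for a coefficient table
#'
#' Attaches the average dielectric surface transmissivity `tav` for the
#' oblique-incidence cone (40 degrees, top surface) and the full hemisphere
#' (90 degrees, internal diffuse flux) to a coefficient table, so that the
#' plate model does not recompute the Fresnel integrals per call.
#'
#' @param coeffs coefficient data.frame (see [readLeafCoefficients()]).
#' @return the same data.frame with `tav40` and `tav90` columns added.
#' @export
prepareLeafCoefficients <- function(coeffs) {
  if (is.null(coeffs$tav40)) coeffs$tav40 <- tavTransmissivity(40, coeffs$refractive_index)
  if (is.null(coeffs$tav90)) coeffs$tav90 <- tavTransmissivity(90, coeffs$refractive_index)
  coeffs
}

#' Average transmissivity of a plane dielectric surface
#'
#' Transmissivity of an air-to-medium interface averaged over an incidence
#' cone of half-angle `alpha`, computed by numerical integration of the
#' Fresnel equations weighted by the projected solid angle:
#' \deqn{t_{av}(\alpha, n) = \frac{\int_0^\alpha T(\theta, n) \sin\theta
#'   \cos\theta\, d\theta}{\int_0^\alpha \sin\theta \cos\theta\, d\theta}.}
#'
#' @param alpha cone half-angle in degrees (0 < alpha <= 90).
#' @param n refractive index (vectorised).
#' @return transmissivity in (0, 1), same length as `n`.
#' @export
tavTransmissivity <- function(alpha, n) {
  stopifnot(alpha > 0, alpha <= 90, all(n >= 1))
  a <- alpha * pi / 180
  nq <- 128L
  theta <- (seq_len(nq) - 0.5) / nq * a
  wgt <- sin(theta) * cos(theta)
  ct <- cos(theta)
  st <- sin(theta)
  num <- numeric(length(n))
  for (j in seq_len(nq)) {
    stt <- st[j] / n                       # Snell: sin(theta_t)
    ctt <- sqrt(pmax(1 - stt^2, 0))
    rs <- ((ct[j] - n * ctt) / (ct[j] + n * ctt))^2
    rp <- ((n * ct[j] - ctt) / (n * ct[j] + ctt))^2
    num <- num + (1 - (rs + rp) / 2) * wgt[j]
  }
  num / sum(wgt)
}

#' Synthetic background soil reflectance spectrum
#'
#' A parametric dry-soil reflectance curve on an arbitrary wavelength grid:
#' brightness rising from the visible into the SWIR with mineral-bound-water
#' dips near 1415, 1930 and 2210 nm. The scene soil spectrum is this curve
#' multiplied by the dimensionless soil brightness coefficient in `[0, 1]`.
#' The curve is synthetic (no field spectrum is bundled).
#'
#' @param wl wavelength grid in nm.
#' @param coefficient soil brightness coefficient in `[0, 1]`.
#' @return reflectance vector on `wl`, in `[0, 1]`.
#' @examples
#' soil <- syntheticSoilSpectrum(400:2500)
#' @export
syntheticSoilSpectrum <- function(wl = 400:2500, coefficient = 1) {
  stopifnot(coefficient >= 0, coefficient <= 1)
  base <- 0.10 + 0.32 * (1 - exp(-(wl - 400) / 1200))
  dips <- 0.045 * .gauss(wl, 1415, 45) + 0.060 * .gauss(wl, 1930, 70) +
    0.040 * .gauss(wl, 2210, 60)
  pmin(pmax(coefficient * (base - dips), 0), 1)
}
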