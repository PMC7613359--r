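## Sensor band settings and spectral-response convolution.
##
## Band centres and FWHMs for the five bundled sensors are nominal values
## of the solar-reflective bands (thermal bands fall outside the 400-2500 nm
## simulation range and are excluded). Spectral response functions are
## approximated from centre/FWHM (gaussian by default) since the true
## tabulated responses are not bundled; user-supplied tabulated SRFs are
## accepted by `bandSRF`-compatible weight vectors.

.sensorDefs <- function() {
  if (!is.null(.vigsa_cache$sensors)) return(.vigsa_cache$sensors)

  l8 <- data.frame(
    band = c("B1", "B2", "B3", "B4", "B5", "B9", "B6", "B7"),
    center = c(443, 482, 561.5, 654.5, 865, 1373.5, 1608.5, 2200.5),
    fwhm = c(16, 60, 57, 37, 28, 20, 85, 187))
  l8roles <- c(BLUE = "B2", GREEN = "B3", RED = "B4", NIR = "B5",
               SWIR = "B6")

  modis <- data.frame(
    band = c("B8", "B9", "B3", "B10", "B11", "B12", "B4", "B1", "B13",
             "B14", "B15", "B2", "B16", "B17", "B18", "B19", "B5", "B26",
             "B6", "B7"),
    center = c(411.5, 443, 469, 488, 531, 551, 555, 645, 667, 678, 748,
               858.5, 869.5, 905, 936, 940, 1240, 1375, 1640, 2130),
    fwhm = c(15, 10, 20, 10, 10, 10, 20, 50, 10, 10, 10, 35, 15, 30, 10,
             50, 20, 30, 24, 50))
  modisroles <- c(BLUE = "B3", GREEN = "B4", RED = "B1", NIR = "B2",
                  SWIR = "B6")

  s2 <- data.frame(
    band = c("B1", "B2", "B3", "B4", "B5", "B6", "B7", "B8", "B8a", "B9",
             "B10", "B11", "B12"),
    center = c(442.7, 492.4, 559.8, 664.6, 704.1, 740.5, 782.8, 832.8,
               864.7, 945.1, 1373.5, 1613.7, 2202.4),
    fwhm = c(21, 66, 36, 31, 15, 15, 20, 106, 21, 20, 31, 91, 175))
  s2roles <- c(BLUE = "B2", GREEN = "B3", RED = "B4", RedEdge = "B5",
               NIR = "B8", SWIR = "B11")

  # Sentinel-3 as one logical sensor: OLCI VNIR bands + SLSTR solar bands
  olci <- data.frame(
    band = paste0("Oa", 1:21),
    center = c(400, 412.5, 442.5, 490, 510, 560, 620, 665, 673.75, 681.25,
               708.75, 753.75, 761.25, 764.375, 767.5, 778.75, 865, 885,
               900, 940, 1020),
    fwhm = c(15, 10, 10, 10, 10, 10, 10, 10, 7.5, 7.5, 10, 7.5, 2.5, 3.75,
             2.5, 15, 20, 10, 10, 20, 40))
  slstr <- data.frame(
    band = paste0("S", 1:6),
    center = c(554.27, 659.47, 868, 1374.8, 1613.4, 2255.7),
    fwhm = c(19.26, 19.25, 20.6, 20.8, 60.68, 50.15))
  s3 <- rbind(olci, slstr)
  s3roles <- c(BLUE = "Oa4", GREEN = "Oa6", RED = "Oa8", RedEdge = "Oa11",
               NIR = "Oa17", SWIR = "S5")

  # EnMAP: 230 narrow bands (88 VNIR + 142 SWIR), nominal smooth band model
  envnir <- seq(423, 999, length.out = 88)
  enswir <- seq(1000, 2445, length.out = 142)
  enmap <- data.frame(
    band = sprintf("E%03d", 1:230),
    center = c(envnir, enswir),
    fwhm = c(rep(8.1, 88), rep(12, 142)))
  # role bands chosen as the bands closest to the published role wavelengths
  enroleWl <- c(BLUE = 449.25, GREEN = 527.25, RED = 670.25,
                RedEdge = 709.25, NIR = 1085, SWIR = 2195)
  enroles <- vapply(enroleWl, function(wl) {
    enmap$band[which.min(abs(enmap$center - wl))]
  }, character(1))

  mk <- function(name, bands, roles) {
    o <- order(bands$center)
    new("Sensor", name = name, bands = bands[o, , drop = FALSE],
        roles = roles)
  }
  out <- list(
    Landsat8 = mk("Landsat8", l8, l8roles),
    MODIS = mk("MODIS", modis, modisroles),
    Sentinel2 = mk("Sentinel2", s2, s2roles),
    Sentinel3 = mk("Sentinel3", s3, s3roles),
    EnMAP = mk("EnMAP", enmap, enroles)
  )
  .vigsa_cache$sensors <- out
  out
}

#' List bundled sensors
#'
#' @return character vector of sensor names.
#' @export
listSensors <- function() names(.sensorDefs())

#' Retrieve a bundled sensor definition
#'
#' @param name sensor name (see [listSensors()]).
#' @param roles optional named character vector overriding the default
#'   role-to-band mapping.
#' @return a [Sensor-class] object.
#' @examples
#' getSensor("Sentinel2")
#' @export
getSensor <- function(name, roles = NULL) {
  defs <- .sensorDefs()
  if (!name %in% names(defs))
    stop("unknown sensor '", name, "'; available: ",
         paste(names(defs), collapse = ", "))
  s <- defs[[name]]
  if (!is.null(roles)) {
    merged <- s@roles
    merged[names(roles)] <- roles
    s@roles <- merged
    validObject(s)
  }
  s
}

#' Spectral response weights of one band
#'
#' Builds a normalized spectral response weight vector on a wavelength grid
#' from a band centre and full width at half maximum. The gaussian shape
#' satisfies `weight(center +/- fwhm/2) = peak/2` before normalization; the
#' boxcar covers `[center - fwhm/2, center + fwhm/2]` with equal weights.
#'
#' @param center band centre in nm (within 400-2500).
#' @param fwhm full width at half maximum in nm (> 0).
#' @param shape `"gaussian"` (default) or `"boxcar"`.
#' @param grid wavelength grid in nm.
#' @return numeric weight vector (nonnegative, summing to 1) on `grid`.
#' @examples
#' w <- bandSRF(670, 20, "gaussian", 400:2500)
#' @export
bandSRF <- function(center, fwhm, shape = c("gaussian", "boxcar"), grid) {
  shape <- match.arg(shape)
  if (center < 400 || center > 2500)
    stop("band centre ", center, " nm outside the 400-2500 nm range")
  if (fwhm <= 0) stop("fwhm must be positive")
  if (shape == "gaussian") {
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    w <- exp(-0.5 * ((grid - center) / sigma)^2)
    w[abs(grid - center) > 3 * fwhm] <- 0
  } else {
    w <- as.numeric(abs(grid - center) <= fwhm / 2 + 1e-9)
  }
  if (sum(w) <= 0)
    stop("band support (", center, " +/- ", fwhm,
         " nm) does not intersect the wavelength grid")
  w / sum(w)
}

#' Convolve spectra to sensor band reflectances
#'
#' Applies each band's spectral response to every spectrum, producing one
#' band reflectance per (simulation, band) as the SRF-weighted mean of the
#' spectrum. The result is returned as a [SpectrumSet-class] on the
#' `"sensor-bands"` grid whose wavelengths are the band centres and whose
#' columns are named by band.
#'
#' @param spectra a [SpectrumSet-class] on a native wavelength grid.
#' @param sensor a [Sensor-class] or sensor name.
#' @param shape SRF shape passed to [bandSRF()].
#' @return a [SpectrumSet-class] of band reflectances.
#' @examples
#' s <- new("SpectrumSet", wavelengths = as.numeric(400:2500),
#'          values = matrix(0.25, 1, 2101), gridId = "1nm-2101")
#' b <- convolveToSensor(s, "Landsat8")
#' @export
convolveToSensor <- function(spectra, sensor, shape = "gaussian") {
  stopifnot(is(spectra, "SpectrumSet"))
  if (is.character(sensor)) sensor <- getSensor(sensor)
  grid <- wavelengths(spectra)
  b <- sensorBands(sensor)
  W <- vapply(seq_len(nrow(b)), function(i) {
    bandSRF(b$center[i], b$fwhm[i], shape, grid)
  }, numeric(length(grid)))
  vals <- spectra(spectra) %*% W
  colnames(vals) <- b$band
  new("SpectrumSet", wavelengths = b$center, values = vals,
      gridId = "sensor-bands")
}

#' Value of the band/grid sample nearest a wavelength
#'
#' Resolves an explicit-wavelength reflectance term to the nearest sample of
#' the active grid (native wavelengths or sensor band centres); ties break
#' toward the lower wavelength.
#'
#' @param spectra a [SpectrumSet-class].
#' @param wavelength requested wavelength in nm.
#' @return numeric vector, one value per simulation.
#' @examples
#' s <- new("SpectrumSet", wavelengths = as.numeric(400:2500),
#'          values = matrix(0.25, 1, 2101), gridId = "1nm-2101")
#' nearestBandValue(s, 670.25)
#' @export
nearestBandValue <- function(spectra, wavelength) {
  stopifnot(is(spectra, "SpectrumSet"))
  grid <- wavelengths(spectra)
  maxGap <- if (length(grid) > 1) max(diff(grid)) else 1
  if (wavelength < min(grid) - maxGap || wavelength > max(grid) + maxGap)
    stop("wavelength ", wavelength, " nm outside grid coverage (",
         min(grid), "-", max(grid), " nm)")
  i <- which.min(abs(grid - wavelength))  # first minimum = lower wavelength
  spectra(spectra)[, i]
}
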