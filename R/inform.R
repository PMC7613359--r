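## Hybrid geometric-optical / turbid-medium forest reflectance model.
##
## The forest scene combines a tree-crown layer and an understory layer:
## within crowns radiative transfer follows the four-stream turbid-medium
## solution, while scene-level aggregation follows the forest-light
## interaction scheme: the bidirectional reflectance is a mixture of the
## infinitely-deep crown reflectance and the understory reflectance,
## weighted by scene gap transmittances in the sun and view directions that
## combine Poisson crown cover (from stem density and crown diameter, with
## sun-direction shadows enlarged by tree height) with within-crown gap
## fractions.

#' Top-of-canopy reflectance of a forest canopy
#'
#' @param leafRefl,leafTrans leaf reflectance and transmittance vectors on
#'   the working wavelength grid (for forest runs typically the 5-nm grid).
#' @param forest named list: `LAIs` (single-tree leaf area index, per crown
#'   projected area), `LAIu` (understory leaf area index), `SD` (stem
#'   density, 1/ha), `H` (tree height, m), `CD` (crown diameter, m), `LAD`
#'   (mean leaf inclination, degrees), `SZA` (solar zenith, degrees),
#'   optional `OZA`, `RAA`, `hotspot`, `skyl` as in [sailTOC()].
#' @param soilSpectrum soil reflectance vector on the same grid.
#' @return list with `reflectance` (top-of-canopy bidirectional reflectance
#'   in `[0, 1]`), `crownCover` (view-direction crown cover fraction in
#'   `[0, 1]`) and `shadowCover` (sun-direction cover fraction).
#' @examples
#' wl <- seq(400, 2500, 5)
#' rt <- prospect4(list(N_struct = 1.5, Cab = 40, Cw = 0.01, Cm = 0.009))
#' lr <- resampleSpectrum(rt$reflectance, rt$wavelengths, wl)
#' lt <- resampleSpectrum(rt$transmittance, rt$wavelengths, wl)
#' soil <- syntheticSoilSpectrum(wl, 0.8)
#' f <- informTOC(lr, lt, list(LAIs = 4, LAIu = 1, SD = 600, H = 15,
#'                             CD = 4, LAD = 50, SZA = 30), soil)
#' @export
informTOC <- function(leafRefl, leafTrans, forest, soilSpectrum) {
  forest <- modifyList(list(OZA = 0, RAA = 0, hotspot = 0.01, skyl = 0),
                       as.list(forest))
  for (f in c("LAIs", "LAIu", "SD", "H", "CD", "LAD", "SZA"))
    if (is.null(forest[[f]])) stop("forest must provide ", f)
  if (forest$SD < 0 || forest$CD < 0 || forest$H < 0)
    stop("SD, H and CD must be nonnegative")
  nw <- length(leafRefl)
  if (length(soilSpectrum) != nw || length(leafTrans) != nw)
    stop("leaf and soil spectra must share one wavelength grid")
  lidf <- lidfEllipsoidal(forest$LAD)
  zero <- rep(0, nw)

  # understory scene (turbid layer of LAIu over the soil)
  su <- .foursail(leafRefl, leafTrans, forest$LAIu, lidf,
                  tts = forest$SZA, tto = forest$OZA, psi = forest$RAA,
                  hotspot = forest$hotspot, rsoil = soilSpectrum)
  rg <- (1 - forest$skyl) * su$rsot + forest$skyl * su$rdot

  # infinitely deep crown reflectance (background-free)
  sinf <- .foursail(leafRefl, leafTrans, 15, lidf,
                    tts = forest$SZA, tto = forest$OZA, psi = forest$RAA,
                    hotspot = forest$hotspot, rsoil = zero)
  rcInf <- (1 - forest$skyl) * sinf$rsot + forest$skyl * sinf$rdot

  # Crown-layer optical depth from the canopy leaf density, the product of
  # single-tree LAI, crown diameter, stem density and tree height (per-ha
  # scaling); crown transmittances are total directional transmission
  # (direct gap plus diffusely scattered) through that layer.
  laiCrown <- min(forest$LAIs * forest$CD * forest$SD * forest$H / 1e4, 30)
  if (laiCrown > 0) {
    sc <- .foursail(leafRefl, leafTrans, laiCrown, lidf,
                    tts = forest$SZA, tto = forest$OZA, psi = forest$RAA,
                    hotspot = forest$hotspot, rsoil = zero)
    ts <- pmin(sc$tss + sc$tsd, 1)
    to <- pmin(sc$too + sc$tdo, 1)
  } else {
    ts <- 1; to <- 1
  }

  # Poisson crown cover from stem density and crown area; the sun-direction
  # cover adds the cylinder shadow cast by crowns of height H.
  crownArea <- pi * (forest$CD / 2)^2
  lamView <- forest$SD * crownArea / 1e4
  shadowArea <- crownArea +
    forest$CD * forest$H * tan(forest$SZA * pi / 180)
  lamSun <- forest$SD * shadowArea / 1e4
  coCov <- 1 - exp(-lamView)
  csCov <- 1 - exp(-lamSun)

  Ts <- 1 - csCov * (1 - ts)
  To <- 1 - coCov * (1 - to)
  refl <- rcInf * (1 - Ts * To) + rg * Ts * To

  list(reflectance = pmin(pmax(refl, 0), 1),
       crownCover = coCov, shadowCover = csCov)
}

#' Block-average a spectrum onto a coarser wavelength grid
#'
#' Averages a finely sampled spectrum over symmetric windows around each
#' target wavelength (window width equals the target grid spacing), e.g. to
#' produce the 5-nm forest-model grid from the 1-nm leaf-model grid.
#'
#' @param values spectrum on the source grid.
#' @param from source wavelength grid (regular).
#' @param to target wavelength grid (regular, coarser).
#' @return vector of block means on `to`.
#' @export
resampleSpectrum <- function(values, from, to) {
  step <- if (length(to) > 1) to[2] - to[1] else from[2] - from[1]
  half <- step / 2
  vapply(to, function(c0) {
    sel <- from >= c0 - half & from <= c0 + half
    if (!any(sel)) stop("target wavelength outside source grid: ", c0)
    mean(values[sel])
  }, numeric(1))
}
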