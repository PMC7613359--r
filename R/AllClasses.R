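## S4 classes for the core data containers.

#' Saltelli design matrices on the unit hypercube
#'
#' Holds the two independent base sample matrices `P` and `Q` (both `N x k`,
#' entries in `[0, 1]`) and the `k` radial recombination matrices, where the
#' i-th radial matrix equals `P` with its i-th column replaced by the i-th
#' column of `Q`. Evaluating a model on `P`, `Q` and the radial blocks costs
#' exactly `N * (k + 2)` model runs and supports simultaneous estimation of
#' first-order and total-effect Sobol' indices.
#'
#' @slot P numeric matrix, `N x k`, entries in `[0, 1]`.
#' @slot Q numeric matrix, same shape as `P`.
#' @slot radial list of `k` matrices, each `N x k`.
#' @slot N integer, sample count.
#' @slot k integer, variable count.
#' @slot scheme character, the sampling scheme that generated the design.
#' @slot seed integer, seed used for stochastic schemes (`NA` when unused).
#'
#' @seealso [generateUnitDesign()], [radialMatrices()], [scaleDesign()]
#' @export
setClass("DesignMatrices",
  representation(
    P = "matrix", Q = "matrix", radial = "list",
    N = "integer", k = "integer", scheme = "character", seed = "integer"
  )
)

setValidity("DesignMatrices", function(object) {
  msg <- character()
  if (!identical(dim(object@P), dim(object@Q)))
    msg <- c(msg, "P and Q must have identical dimensions")
  if (nrow(object@P) != object@N || ncol(object@P) != object@k)
    msg <- c(msg, "P must be N x k")
  rng <- range(object@P, object@Q)
  if (rng[1] < 0 || rng[2] > 1)
    msg <- c(msg, "all design entries must lie in [0, 1]")
  if (length(object@radial) != object@k)
    msg <- c(msg, "radial list length must equal k")
  for (i in seq_along(object@radial)) {
    Ri <- object@radial[[i]]
    if (!identical(dim(Ri), dim(object@P))) {
      msg <- c(msg, sprintf("radial[[%d]] has wrong shape", i))
      next
    }
    expect <- object@P
    expect[, i] <- object@Q[, i]
    if (!isTRUE(all.equal(Ri, expect, check.attributes = FALSE)))
      msg <- c(msg, sprintf(
        "radial[[%d]] must equal P with column %d taken from Q", i, i))
  }
  if (length(msg)) msg else TRUE
})

#' Set of simulated reflectance spectra on a fixed wavelength grid
#'
#' A matrix of bidirectional top-of-canopy (or leaf-level) reflectance
#' spectra, one row per simulation, one column per wavelength. Recognised
#' grids are the 1-nm grid (400-2500 nm, 2101 samples), the 5-nm grid
#' (421 samples) and arbitrary sensor-band grids.
#'
#' @slot wavelengths numeric vector of wavelengths in nm (strictly
#'   increasing).
#' @slot values numeric matrix, simulations x wavelengths, finite, in
#'   `[0, 1]`.
#' @slot gridId character: `"1nm-2101"`, `"5nm-421"` or `"sensor-bands"`.
#'
#' @seealso [simulateDesignSpectra()], [convolveToSensor()]
#' @export
setClass("SpectrumSet",
  representation(wavelengths = "numeric", values = "matrix",
                 gridId = "character")
)

setValidity("SpectrumSet", function(object) {
  msg <- character()
  w <- object@wavelengths
  if (length(w) != ncol(object@values))
    msg <- c(msg, "length(wavelengths) must equal ncol(values)")
  if (length(w) > 1 && any(diff(w) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "all reflectance values must be finite")
  else if (min(object@values) < -1e-9 || max(object@values) > 1 + 1e-9)
    msg <- c(msg, "reflectance values must lie in [0, 1]")
  if (identical(object@gridId, "1nm-2101") && length(w) != 2101)
    msg <- c(msg, "grid '1nm-2101' must have 2101 samples")
  if (identical(object@gridId, "5nm-421") && length(w) != 421)
    msg <- c(msg, "grid '5nm-421' must have 421 samples")
  if (length(msg)) msg else TRUE
})

#' Result of a Sobol' sensitivity estimation
#'
#' Per-variable first-order (`Si`) and total-effect (`STi`) Sobol' indices
#' together with the estimated output mean and unconditional variance. Raw
#' (possibly slightly negative, finite-sample) estimates are retained next to
#' the reported values, which are clipped to `[0, Inf)`. When the output
#' variance is numerically zero the result is flagged degenerate and all
#' indices are reported as zero.
#'
#' @slot variableNames character vector, length `k`.
#' @slot Si,STi numeric, clipped (reported) indices.
#' @slot SiRaw,STiRaw numeric, raw estimator values.
#' @slot f0Hat numeric(1), estimated output mean.
#' @slot VHat numeric(1), estimated output variance (>= 0).
#' @slot N integer, rows per design block used by the estimator.
#' @slot nExcluded integer, design rows dropped because the output was
#'   invalid (NaN) in at least one block.
#' @slot degenerate logical(1), TRUE when `VHat` is numerically zero.
#'
#' @seealso [estimateSobolIndices()], [normalizeTotalEffects()]
#' @export
setClass("GSAResult",
  representation(
    variableNames = "character",
    Si = "numeric", STi = "numeric",
    SiRaw = "numeric", STiRaw = "numeric",
    f0Hat = "numeric", VHat = "numeric",
    N = "integer", nExcluded = "integer", degenerate = "logical"
  )
)

setValidity("GSAResult", function(object) {
  k <- length(object@variableNames)
  msg <- character()
  if (length(object@Si) != k || length(object@STi) != k ||
      length(object@SiRaw) != k || length(object@STiRaw) != k)
    msg <- c(msg, "index vectors must match the number of variables")
  if (object@VHat < 0) msg <- c(msg, "VHat must be >= 0")
  if (any(object@Si < 0) || any(object@STi < 0))
    msg <- c(msg, "reported Si and STi must be clipped to >= 0")
  if (length(msg)) msg else TRUE
})

#' Sensor band-setting definition
#'
#' An ordered table of spectral bands (centre and full width at half maximum
#' in nm, optionally a tabulated spectral response) plus a mapping from the
#' symbolic band roles used in vegetation-index formulas (BLUE, GREEN, RED,
#' RedEdge, NIR, SWIR) to physical band names.
#'
#' @slot name character, sensor identifier.
#' @slot bands data.frame with columns `band` (character, unique),
#'   `center` (nm) and `fwhm` (nm).
#' @slot roles named character vector mapping role symbols to band names.
#'
#' @seealso [getSensor()], [listSensors()], [convolveToSensor()]
#' @export
setClass("Sensor",
  representation(name = "character", bands = "data.frame",
                 roles = "character")
)

setValidity("Sensor", function(object) {
  b <- object@bands
  msg <- character()
  need <- c("band", "center", "fwhm")
  if (!all(need %in% names(b)))
    msg <- c(msg, "bands must have columns band, center, fwhm")
  else {
    if (anyDuplicated(b$band)) msg <- c(msg, "band names must be unique")
    if (any(b$center < 400 | b$center > 2500))
      msg <- c(msg, "band centres must lie within 400-2500 nm")
    if (any(b$fwhm <= 0)) msg <- c(msg, "fwhm must be positive")
    bad <- setdiff(object@roles, b$band)
    if (length(bad))
      msg <- c(msg, paste("role mapped to unknown band:",
                          paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Vegetation-index definition
#'
#' A named algebraic expression over band-role symbols (BLUE, GREEN, RED,
#' RedEdge, NIR, SWIR) and explicit wavelength terms `rho(lambda)`, tagged
#' with the vegetation variable it was designed to track and the sensors it
#' applies to.
#'
#' @slot name character, full index name.
#' @slot abbreviation character, short identifier used in outputs.
#' @slot expression character, the formula text (see
#'   [parseViExpression()] for the accepted grammar).
#' @slot targetVariable character: `"LCC"`, `"LWC"` or `"LAI"` (the tag is
#'   organisational, taken from the published grouping, not a validated
#'   claim).
#' @slot applicableSensors character vector of sensor names, or `"grid"`
#'   for indices evaluable on any native wavelength grid.
#' @slot note character, provenance/ambiguity notes for the canonical form.
#'
#' @seealso [builtinRegistry()], [evaluateVi()]
#' @export
setClass("VIDefinition",
  representation(
    name = "character", abbreviation = "character", expression = "character",
    targetVariable = "character", applicableSensors = "character",
    note = "character"
  )
)

setValidity("VIDefinition", function(object) {
  msg <- character()
  if (!nzchar(object@expression)) msg <- c(msg, "expression must be nonempty")
  if (!object@targetVariable %in% c("LCC", "LWC", "LAI", "other"))
    msg <- c(msg, "targetVariable must be LCC, LWC, LAI or other")
  tr <- tryCatch(parseViExpression(object@expression), error = identity)
  if (inherits(tr, "error"))
    msg <- c(msg, paste("expression does not parse:", conditionMessage(tr)))
  if (length(msg)) msg else TRUE
})
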