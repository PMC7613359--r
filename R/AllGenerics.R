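## Generics and accessors for the S4 containers.

#' @describeIn DesignMatrices-accessors base matrix P
#' @export
setGeneric("designP", function(x) standardGeneric("designP"))
#' @describeIn DesignMatrices-accessors auxiliary matrix Q
#' @export
setGeneric("designQ", function(x) standardGeneric("designQ"))
#' @describeIn DesignMatrices-accessors list of radial matrices
#' @export
setGeneric("designRadial", function(x) standardGeneric("designRadial"))
#' @rdname wavelengths
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))
#' @rdname spectra
#' @export
setGeneric("spectra", function(x) standardGeneric("spectra"))
#' @rdname firstOrder
#' @export
setGeneric("firstOrder", function(x, raw = FALSE) standardGeneric("firstOrder"))
#' @rdname totalEffect
#' @export
setGeneric("totalEffect", function(x, raw = FALSE) standardGeneric("totalEffect"))
#' @rdname sensorBands
#' @export
setGeneric("sensorBands", function(x) standardGeneric("sensorBands"))
#' @rdname sensorRoles
#' @export
setGeneric("sensorRoles", function(x) standardGeneric("sensorRoles"))

#' Accessors for DesignMatrices
#'
#' @param x a [DesignMatrices-class] object.
#' @return `designP` and `designQ` return the `N x k` base matrices;
#'   `designRadial` the list of `k` radial matrices.
#' @name DesignMatrices-accessors
#' @aliases designP,DesignMatrices-method designQ,DesignMatrices-method
#'   designRadial,DesignMatrices-method
NULL

setMethod("designP", "DesignMatrices", function(x) x@P)
setMethod("designQ", "DesignMatrices", function(x) x@Q)
setMethod("designRadial", "DesignMatrices", function(x) x@radial)

#' Wavelength grid of a spectrum set
#'
#' @param x a [SpectrumSet-class].
#' @return numeric vector of wavelengths in nm.
#' @name wavelengths
#' @aliases wavelengths,SpectrumSet-method
NULL
setMethod("wavelengths", "SpectrumSet", function(x) x@wavelengths)

#' Reflectance matrix of a spectrum set
#'
#' @param x a [SpectrumSet-class].
#' @return numeric matrix, simulations x wavelengths.
#' @name spectra
#' @aliases spectra,SpectrumSet-method
NULL
setMethod("spectra", "SpectrumSet", function(x) x@values)

#' First-order Sobol' indices of a result
#'
#' @param x a [GSAResult-class].
#' @param raw logical; return the unclipped estimator values?
#' @return named numeric vector of Si per variable.
#' @name firstOrder
#' @aliases firstOrder,GSAResult-method
NULL
setMethod("firstOrder", "GSAResult", function(x, raw = FALSE) {
  setNames(if (raw) x@SiRaw else x@Si, x@variableNames)
})

#' Total-effect Sobol' indices of a result
#'
#' @param x a [GSAResult-class].
#' @param raw logical; return the unclipped estimator values?
#' @return named numeric vector of STi per variable.
#' @name totalEffect
#' @aliases totalEffect,GSAResult-method
NULL
setMethod("totalEffect", "GSAResult", function(x, raw = FALSE) {
  setNames(if (raw) x@STiRaw else x@STi, x@variableNames)
})

#' Band table of a sensor
#'
#' @param x a [Sensor-class].
#' @return data.frame with columns `band`, `center`, `fwhm`.
#' @name sensorBands
#' @aliases sensorBands,Sensor-method
NULL
setMethod("sensorBands", "Sensor", function(x) x@bands)

#' Role mapping of a sensor
#'
#' @param x a [Sensor-class].
#' @return named character vector mapping role symbols to band names.
#' @name sensorRoles
#' @aliases sensorRoles,Sensor-method
NULL
setMethod("sensorRoles", "Sensor", function(x) x@roles)

setMethod("show", "DesignMatrices", function(object) {
  cat(sprintf(
    "DesignMatrices: N = %d, k = %d, scheme = %s (%d model runs for N(k+2))\n",
    object@N, object@k, object@scheme, object@N * (object@k + 2L)))
})

setMethod("show", "SpectrumSet", function(object) {
  cat(sprintf("SpectrumSet: %d spectra on grid '%s' (%d samples, %.0f-%.0f nm)\n",
              nrow(object@values), object@gridId, length(object@wavelengths),
              min(object@wavelengths), max(object@wavelengths)))
})

setMethod("show", "GSAResult", function(object) {
  cat(sprintf("GSAResult over %d variables (N = %d%s%s)\n",
              length(object@variableNames), object@N,
              if (object@nExcluded > 0)
                sprintf(", %d rows excluded", object@nExcluded) else "",
              if (object@degenerate) ", DEGENERATE output" else ""))
  df <- as.data.frame(object)
  print(df[, c("variable", "Si", "STi")], row.names = FALSE, digits = 3)
})

setMethod("show", "Sensor", function(object) {
  cat(sprintf("Sensor '%s': %d bands (%.0f-%.0f nm)\n", object@name,
              nrow(object@bands), min(object@bands$center),
              max(object@bands$center)))
  if (length(object@roles))
    cat("  roles:", paste(names(object@roles), object@roles,
                          sep = "=", collapse = ", "), "\n")
})

setMethod("show", "VIDefinition", function(object) {
  cat(sprintf("VI %s (%s, target %s): %s\n", object@abbreviation,
              object@name, object@targetVariable, object@expression))
})

#' Coerce a GSAResult to a data frame
#'
#' One row per variable, columns `variable`, `Si_raw`, `Si`, `STi_raw`,
#' `STi`, `STi_share`, `N`, `degenerate`. `STi_share` is `STi` normalized to
#' sum to one across variables (`NA` for degenerate results).
#'
#' @param x a [GSAResult-class].
#' @param row.names,optional,... ignored, present for generic consistency.
#' @return a data.frame.
#' @method as.data.frame GSAResult
#' @export
as.data.frame.GSAResult <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  shares <- if (x@degenerate || sum(x@STi) <= 0) rep(NA_real_, length(x@STi))
            else x@STi / sum(x@STi)
  data.frame(
    variable = x@variableNames,
    Si_raw = x@SiRaw, Si = x@Si,
    STi_raw = x@STiRaw, STi = x@STi,
    STi_share = shares,
    N = x@N, degenerate = x@degenerate,
    stringsAsFactors = FALSE
  )
}

setMethod("as.data.frame", "GSAResult", as.data.frame.GSAResult)
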