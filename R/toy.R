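## Closed-form toy canopy model: a self-contained spectral test model that
## requires no coefficient data and has analytically known sensitivity
## structure.

#' Closed-form toy spectral model
#'
#' Produces a deterministic spectrum from a flat baseline minus
#' parameter-scaled Gaussian absorption features at fixed centres spread
#' over the grid: at the centre of feature i the spectrum is (up to small
#' overlap terms) affine-linear in parameter i alone, so Sobol' indices of
#' band values have simple closed forms. Parameters live on `[0, 1]`;
#' entries beyond `nActive` are ignored (inert), which makes the model a
#' convenient dummy-variable test bed.
#'
#' @param params numeric vector (length >= 2) of parameters in `[0, 1]`.
#' @param wl wavelength grid in nm (default the 1-nm grid).
#' @param nActive number of leading parameters that influence the spectrum
#'   (default all).
#' @return reflectance-like spectrum on `wl`, values in `[0, 1]`.
#' @examples
#' s <- toyCanopy(c(0.2, 0.9))
#' range(s)
#' @export
toyCanopy <- function(params, wl = 400:2500, nActive = length(params)) {
  p <- length(params)
  if (p < 2) stop("toy model needs at least two parameters")
  if (any(params < 0 | params > 1)) stop("toy parameters must lie in [0, 1]")
  nActive <- min(nActive, p)
  centres <- seq(500, 2300, length.out = p)
  out <- rep(0.5, length(wl))
  for (i in seq_len(nActive)) {
    g <- exp(-((wl - centres[i]) / 60)^2)
    g[abs(wl - centres[i]) > 180] <- 0   # compact support: exactly flat far away
    out <- out - 0.35 * params[i] * g
  }
  pmin(pmax(out, 0), 1)
}

#' Feature centres of the toy model
#'
#' @param p number of parameters.
#' @return wavelengths (nm) at which each toy parameter has its absorption
#'   feature.
#' @export
toyFeatureCentres <- function(p) seq(500, 2300, length.out = p)
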