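## Four-parameter plate-model leaf reflectance/transmittance simulator.

#' Simulate leaf reflectance and transmittance (plate model)
#'
#' Generalised plate model of leaf optics with four parameters: leaf
#' structure `N_struct` (number of equivalent compact layers, >= 1),
#' chlorophyll a+b content `Cab` (ug/cm^2), equivalent water thickness `Cw`
#' (cm) and dry matter content `Cm` (g/cm^2). The per-layer absorption
#' coefficient is \eqn{k = (Cab\,k_{Cab} + Cw\,k_{Cw} + Cm\,k_{Cm}) / N},
#' the isotropic-flux layer transmission is
#' \eqn{\theta(k) = (1-k)e^{-k} + k^2 E_1(k)} (exponential integral), and
#' the stack of one oblique-illuminated surface layer above `N - 1`
#' diffuse layers is resolved with the Stokes closed-form expressions.
#'
#' @param leaf named list or vector with elements `N_struct`, `Cab`, `Cw`,
#'   `Cm`.
#' @param coeffs coefficient table (default the bundled synthetic
#'   calibration, see [syntheticLeafCoefficients()]).
#' @param alpha incidence cone half-angle of the upper surface in degrees
#'   (40 by convention: rough surface aggregate).
#' @return list with `wavelengths` (nm), `reflectance` and `transmittance`
#'   (each length 2101, in `[0, 1]`, summing to <= 1 everywhere).
#' @examples
#' rt <- prospect4(list(N_struct = 1.5, Cab = 40, Cw = 0.01, Cm = 0.009))
#' range(rt$reflectance + rt$transmittance)
#' @export
prospect4 <- function(leaf, coeffs = syntheticLeafCoefficients(),
                      alpha = 40) {
  leaf <- as.list(leaf)
  need <- c("N_struct", "Cab", "Cw", "Cm")
  if (!all(need %in% names(leaf)))
    stop("leaf must provide N_struct, Cab, Cw and Cm")
  Nst <- leaf$N_struct
  if (Nst < 1) stop("N_struct must be >= 1")
  if (leaf$Cab < 0 || leaf$Cw < 0 || leaf$Cm < 0)
    stop("contents must be nonnegative")
  coeffs <- prepareLeafCoefficients(coeffs)

  k <- (leaf$Cab * coeffs$k_Cab + leaf$Cw * coeffs$k_Cw +
          leaf$Cm * coeffs$k_Cm) / Nst
  theta <- .layerTransmission(k)

  nr <- coeffs$refractive_index
  talf <- if (alpha == 40) coeffs$tav40 else tavTransmissivity(alpha, nr)
  t12 <- coeffs$tav90
  ralf <- 1 - talf
  r12 <- 1 - t12
  t21 <- t12 / nr^2
  r21 <- 1 - t21

  # one compact layer, oblique top illumination vs diffuse illumination
  denom <- 1 - r21^2 * theta^2
  Ta <- talf * theta * t21 / denom
  Ra <- ralf + r21 * theta * Ta
  t <- t12 * theta * t21 / denom
  r <- r12 + r21 * theta * t

  # Stokes expressions for a stack of N-1 identical diffuse layers
  sub <- .stokesStack(r, t, Nst - 1)

  den2 <- 1 - sub$R * r
  tran <- Ta * sub$T / den2
  refl <- Ra + Ta * sub$R * t / den2

  list(wavelengths = coeffs$wavelength_nm,
       reflectance = pmin(pmax(refl, 0), 1),
       transmittance = pmin(pmax(tran, 0), 1))
}

# Isotropic-flux transmission through one absorbing layer:
# theta(k) = (1 - k) exp(-k) + k^2 E1(k); theta(0) = 1.
.layerTransmission <- function(k) {
  out <- rep(1, length(k))
  pos <- k > 0
  kp <- k[pos]
  out[pos] <- (1 - kp) * exp(-kp) + kp^2 * pracma::expint(kp)
  pmin(pmax(out, 0), 1)
}

# Reflectance/transmittance of n identical layers (n >= 0, possibly
# non-integer) stacked on each other, from the single-layer (r, t) pair,
# via the Stokes closed form. n = 0 returns a transparent stack.
.stokesStack <- function(r, t, n) {
  if (n <= 0) return(list(R = rep(0, length(r)), T = rep(1, length(r))))
  R <- numeric(length(r))
  T <- numeric(length(r))
  # non-conservative case (r + t < 1)
  nc <- (r + t) < 1 - 1e-12
  if (any(nc)) {
    rr <- r[nc]
    tt <- pmax(t[nc], 1e-200)  # keep b finite in saturated absorption bands
    D <- sqrt(pmax((1 + rr + tt) * (1 + rr - tt) *
                     (1 - rr + tt) * (1 - rr - tt), 0))
    a <- (1 + rr^2 - tt^2 + D) / (2 * rr)
    b <- (1 - rr^2 + tt^2 + D) / (2 * tt)
    bn <- b^n                  # b > 1, may be huge; forms below stay stable
    cinv <- 1 / bn^2           # -> 0 when bn overflows
    R[nc] <- a * (1 - cinv) / (a^2 - cinv)
    T[nc] <- (a^2 - 1) / (bn * (a^2 - cinv))
    T[nc][!is.finite(T[nc])] <- 0
  }
  # conservative scattering limit (r + t -> 1)
  if (any(!nc)) {
    tt <- t[!nc]
    T[!nc] <- tt / (tt + (1 - tt) * n)
    R[!nc] <- 1 - T[!nc]
  }
  list(R = R, T = T)
}
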