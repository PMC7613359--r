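# Shared helpers for the vigsa test suite.

# Wrap a plain matrix of spectra into a SpectrumSet on the 1-nm grid.
makeSpectrumSet <- function(values, wl = 400:2500,
                            gridId = if (length(wl) == 2101) "1nm-2101"
                                     else "sensor-bands") {
  new("SpectrumSet", wavelengths = as.numeric(wl),
      values = as.matrix(values), gridId = gridId)
}

# Saltelli estimation of a function on the unit hypercube.
saltelliEstimate <- function(fun, k, N, scheme = "uniform-sobol",
                             seed = 1L, names = paste0("x", seq_len(k))) {
  d <- generateUnitDesign(k, N, scheme, seed)
  estimateSobolIndices(fun(designP(d)), fun(designQ(d)),
                       lapply(designRadial(d), fun), names)
}

# Centered L2 discrepancy (Hickernell): lower = more uniform point set.
centeredL2Discrepancy <- function(U) {
  n <- nrow(U); d <- ncol(U)
  z <- abs(U - 0.5)
  t1 <- prod(rep(13 / 12, d))
  t2 <- mean(apply(1 + 0.5 * z - 0.5 * z^2, 1, prod))
  s3 <- 0
  for (i in seq_len(n)) {
    zi <- z[i, ]
    M <- 1 + 0.5 * sweep(z, 2, zi, function(a, b) a + b) -
      0.5 * abs(sweep(U, 2, U[i, ]))
    s3 <- s3 + sum(apply(M, 1, prod))
  }
  sqrt(t1 - 2 * t2 + s3 / n^2)
}

# Reference leaf/soil spectra reused across RTM tests.
testLeaf <- function() prospect4(list(N_struct = 1.5, Cab = 40,
                                      Cw = 0.01, Cm = 0.009))
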