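## Monte Carlo Sobol' index estimators (Saltelli radial scheme).

#' Estimate the output mean and unconditional variance
#'
#' Computes the Monte Carlo estimates of the model output mean `f0` and the
#' unconditional output variance `V(y)` from the outputs of the base sample
#' matrix: `f0 = mean(fP)` and `V = mean(fP^2) - f0^2`. A tiny negative
#' variance arising from floating-point cancellation is clamped to zero.
#'
#' @param fP numeric vector of model outputs on the base matrix P (length
#'   `N >= 2`, all finite).
#' @return list with elements `f0Hat` and `VHat`.
#' @examples
#' estimateOutputMoments(c(0, 1))  # f0 = 0.5, V = 0.25
#' @export
estimateOutputMoments <- function(fP) {
  if (length(fP) < 2) stop("need at least two model outputs")
  if (!all(is.finite(fP))) stop("model outputs must be finite")
  f0 <- mean(fP)
  V <- mean(fP^2) - f0^2
  list(f0Hat = f0, VHat = max(V, 0))
}

# Degenerate-variance guard shared by the estimators.
.isDegenerateVariance <- function(VHat, f0Hat) {
  VHat < 1e-12 * max(1, f0Hat^2)
}

#' Estimate first-order and total-effect Sobol' indices
#'
#' Saltelli-style estimators over the radial design: with `fP` and `fQ` the
#' outputs on the base matrices and `fR[[i]]` the outputs on the i-th radial
#' matrix (P with column i from Q),
#' \deqn{\hat S_i = \frac{1}{N \hat V} \sum_j f(Q)_j\,(f(P_Q^{(i)})_j -
#'   f(P)_j), \qquad
#'   \hat S_{Ti} = \frac{1}{2 N \hat V} \sum_j (f(P)_j - f(P_Q^{(i)})_j)^2.}
#'
#' Rows for which any block produced an invalid output (NaN, e.g. from a
#' guarded vegetation-index denominator) are excluded across all blocks so
#' that the pairings stay aligned; the exclusion count is recorded. Raw
#' estimates are retained; reported values are clipped to `[0, Inf)`. When
#' the output variance is numerically zero, all indices are reported zero
#' and the result is flagged degenerate.
#'
#' @param fP,fQ numeric vectors of length N (outputs on P and Q).
#' @param fR list of k numeric vectors of length N (outputs on the radial
#'   matrices, in variable order).
#' @param variableNames optional character vector of length k.
#' @return a [GSAResult-class] object.
#' @examples
#' d <- generateUnitDesign(2, 512)
#' f <- function(X) X[, 1] + 2 * X[, 2]
#' r <- estimateSobolIndices(f(designP(d)), f(designQ(d)),
#'                           lapply(designRadial(d), f))
#' firstOrder(r)  # close to (0.2, 0.8)
#' @export
estimateSobolIndices <- function(fP, fQ, fR,
                                 variableNames = paste0("x", seq_along(fR))) {
  k <- length(fR)
  if (k < 1) stop("need at least one radial output vector")
  N0 <- length(fP)
  if (length(fQ) != N0 || any(vapply(fR, length, 1L) != N0))
    stop("all output vectors must have the same length")
  if (length(variableNames) != k)
    stop("variableNames must have one entry per radial block")

  blocks <- cbind(fP, fQ, do.call(cbind, fR))
  ok <- rowSums(!is.finite(blocks)) == 0
  nExcluded <- sum(!ok)
  if (sum(ok) < 2)
    stop("fewer than two valid design rows remain after exclusion")
  fP <- fP[ok]; fQ <- fQ[ok]
  fR <- lapply(fR, function(v) v[ok])
  N <- length(fP)

  mom <- estimateOutputMoments(fP)
  degenerate <- .isDegenerateVariance(mom$VHat, mom$f0Hat)

  if (degenerate) {
    zero <- rep(0, k)
    SiRaw <- zero; STiRaw <- zero
  } else {
    SiRaw <- vapply(fR, function(fRi) {
      mean(fQ * (fRi - fP)) / mom$VHat
    }, numeric(1))
    STiRaw <- vapply(fR, function(fRi) {
      mean((fP - fRi)^2) / (2 * mom$VHat)
    }, numeric(1))
  }

  new("GSAResult",
      variableNames = as.character(variableNames),
      Si = pmax(SiRaw, 0), STi = pmax(STiRaw, 0),
      SiRaw = SiRaw, STiRaw = STiRaw,
      f0Hat = mom$f0Hat, VHat = mom$VHat,
      N = as.integer(N), nExcluded = as.integer(nExcluded),
      degenerate = degenerate)
}

# Vectorised estimator over a matrix-valued output (one column per output,
# e.g. per wavelength): returns list(Si, STi, VHat, f0Hat, degenerate), each
# a k x W matrix / length-W vector. Used by the spectral GSA path.
.sobolIndicesMatrix <- function(FP, FQ, FRlist) {
  k <- length(FRlist)
  f0 <- colMeans(FP)
  V <- pmax(colMeans(FP^2) - f0^2, 0)
  degen <- V < 1e-12 * pmax(1, f0^2)
  Vsafe <- ifelse(degen, 1, V)
  Si <- matrix(0, k, ncol(FP))
  STi <- matrix(0, k, ncol(FP))
  for (i in seq_len(k)) {
    D <- FRlist[[i]] - FP
    Si[i, ] <- colMeans(FQ * D) / Vsafe
    STi[i, ] <- colMeans(D^2) / (2 * Vsafe)
  }
  Si[, degen] <- 0
  STi[, degen] <- 0
  list(Si = Si, STi = STi, VHat = V, f0Hat = f0, degenerate = degen)
}

#' Normalize total-effect indices to shares
#'
#' Rescales the reported total-effect indices so that they sum to one,
#' giving the share of total-effect weight attributable to each variable
#' (total effects themselves need not sum to one because interactions are
#' counted once per participating variable).
#'
#' @param result a non-degenerate [GSAResult-class].
#' @return named numeric vector of shares summing to 1.
#' @examples
#' ## STi = (0.6, 0.2, 0.2) -> shares (0.6, 0.2, 0.2)
#' @export
normalizeTotalEffects <- function(result) {
  stopifnot(is(result, "GSAResult"))
  tot <- sum(result@STi)
  if (result@degenerate || tot <= 0)
    stop("degenerate result: all total-effect indices are zero")
  setNames(result@STi / tot, result@variableNames)
}

#' Scan total-effect estimates over increasing sample sizes
#'
#' Reruns the full Saltelli design and estimation for each sample size in
#' `N_grid` and tabulates the per-variable total-effect (and first-order)
#' indices, revealing at which sample size the estimates stabilize.
#'
#' @param model function taking a physical design matrix (rows = samples,
#'   columns = variables in spec order) and returning one numeric output per
#'   row.
#' @param specs variable specification table ([variableSpec()]).
#' @param N_grid strictly increasing integer vector of samples per variable
#'   scheme.
#' @param scheme,seed passed to [generateUnitDesign()].
#' @return data.frame with columns `N`, `variable`, `Si`, `STi`.
#' @examples
#' f <- function(X) X[, 1] + 2 * X[, 2]
#' sp <- variableSpec(c("a", "b"), c(0, 0), c(1, 1))
#' convergenceScan(f, sp, c(64, 256))
#' @export
convergenceScan <- function(model, specs, N_grid,
                            scheme = "uniform-sobol", seed = 1L) {
  N_grid <- as.integer(N_grid)
  if (length(N_grid) < 1 || any(diff(N_grid) <= 0))
    stop("N_grid must be strictly increasing")
  k <- nrow(specs)
  rows <- lapply(N_grid, function(N) {
    d <- generateUnitDesign(k, N, scheme, seed)
    evalBlock <- function(U) {
      out <- model(scaleDesign(U, specs))
      if (length(out) != nrow(U))
        stop("model must return one output per design row")
      out
    }
    fP <- evalBlock(designP(d))
    fQ <- evalBlock(designQ(d))
    fR <- lapply(designRadial(d), evalBlock)
    r <- estimateSobolIndices(fP, fQ, fR, specs$name)
    data.frame(N = N, variable = specs$name,
               Si = r@Si, STi = r@STi, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
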