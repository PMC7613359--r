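## Analytic benchmark functions with known Sobol' indices, and a
## brute-force double-loop estimator used as an independent cross-check.

#' Analytic sensitivity benchmarks
#'
#' Returns a benchmark test function defined on the unit hypercube together
#' with its closed-form Sobol' indices. Available benchmarks:
#'
#' * `additive_linear`: `f(u) = sum(b_i u_i)`; `Si = STi =
#'   b_i^2 / sum(b^2)` (uniform inputs have equal variance, so ranges
#'   cancel).
#' * `ishigami`: the Ishigami function on inputs rescaled to `[-pi, pi]^3`,
#'   `f = sin x1 + a sin^2 x2 + b x3^4 sin x1`, with the standard
#'   closed-form variance decomposition.
#' * `g_function`: Sobol's g-function with coefficients `a`;
#'   `V_i = 1/(3 (1 + a_i)^2)`, `V = prod(1 + V_i) - 1`.
#' * `constant`: constant output, all indices zero.
#' * `dummy_variable`: `f = u1 + 2 u2` embedded in `k = 3` inputs; the third
#'   input is inert (`Si = STi = 0`).
#'
#' @param name benchmark name (see above).
#' @param params optional list: `b` (coefficients, additive_linear),
#'   `a`, `b` (ishigami), `a` (g_function), `k` (constant).
#' @return list with elements `fun` (function of a matrix of unit-hypercube
#'   rows, returning one value per row), `k`, `Si`, `STi` (closed forms) and
#'   `name`.
#' @examples
#' b <- makeBenchmark("additive_linear", list(b = c(1, 2)))
#' b$Si  # 0.2 0.8
#' @export
makeBenchmark <- function(name, params = list()) {
  name <- match.arg(name, c("additive_linear", "ishigami", "g_function",
                            "constant", "dummy_variable"))
  switch(name,
    additive_linear = {
      b <- if (!is.null(params$b)) params$b else c(1, 2)
      S <- b^2 / sum(b^2)
      list(name = name, k = length(b),
           fun = function(U) drop(as.matrix(U) %*% b),
           Si = S, STi = S)
    },
    ishigami = {
      a <- if (!is.null(params$a)) params$a else 7
      b <- if (!is.null(params$b)) params$b else 0.1
      V1 <- 0.5 * (1 + b * pi^4 / 5)^2
      V2 <- a^2 / 8
      V13 <- 8 * b^2 * pi^8 / 225
      V <- V1 + V2 + V13
      list(name = name, k = 3L,
           fun = function(U) {
             X <- 2 * pi * as.matrix(U) - pi
             sin(X[, 1]) + a * sin(X[, 2])^2 + b * X[, 3]^4 * sin(X[, 1])
           },
           Si = c(V1, V2, 0) / V,
           STi = c(V1 + V13, V2, V13) / V)
    },
    g_function = {
      a <- if (!is.null(params$a)) params$a else c(0, 1, 4.5, 9)
      Vi <- 1 / (3 * (1 + a)^2)
      V <- prod(1 + Vi) - 1
      STi <- vapply(seq_along(a), function(i) {
        Vi[i] * prod(1 + Vi[-i]) / V
      }, numeric(1))
      list(name = name, k = length(a),
           fun = function(U) {
             U <- as.matrix(U)
             out <- rep(1, nrow(U))
             for (i in seq_along(a))
               out <- out * (abs(4 * U[, i] - 2) + a[i]) / (1 + a[i])
             out
           },
           Si = Vi / V, STi = STi)
    },
    constant = {
      k <- if (!is.null(params$k)) params$k else 3L
      list(name = name, k = as.integer(k),
           fun = function(U) rep(1, nrow(as.matrix(U))),
           Si = rep(0, k), STi = rep(0, k))
    },
    dummy_variable = {
      S <- c(1, 4, 0) / 5
      list(name = name, k = 3L,
           fun = function(U) {
             U <- as.matrix(U)
             U[, 1] + 2 * U[, 2]
           },
           Si = S, STi = S)
    }
  )
}

#' Brute-force double-loop Sobol' estimator
#'
#' Estimates first-order indices directly from their definition
#' `Si = V[E(y | x_i)] / V(y)`: for each variable, an outer loop fixes
#' `x_i` at `n_outer` jitter-stratified values while an inner loop of
#' `n_inner` plain pseudo-random complement draws estimates the conditional
#' mean (with an inner-noise bias correction). The pseudo-random inner
#' sampling keeps this estimator's error structure independent of the
#' quasi-random Saltelli path it cross-checks. Intended for small test
#' functions only; a runtime guard rejects large problems.
#'
#' @param fun function of a unit-hypercube matrix returning one value per
#'   row.
#' @param k number of inputs (<= 4).
#' @param n_outer,n_inner loop sizes.
#' @param seed RNG seed.
#' @return named list with `Si` (numeric vector) and `VHat`.
#' @examples
#' b <- makeBenchmark("additive_linear", list(b = c(1, 2)))
#' doubleLoopOracle(b$fun, b$k, 256, 256)$Si
#' @export
doubleLoopOracle <- function(fun, k, n_outer = 512, n_inner = 512,
                             seed = 1L) {
  if (k > 4) stop("double-loop oracle is restricted to k <= 4")
  if (as.double(n_outer) * n_inner * k > 5e7)
    stop("runtime guard exceeded: reduce n_outer or n_inner")
  .withLocalSeed(seed, {
    big <- matrix(runif(4096 * k), ncol = k)
    y <- fun(big)
    V <- var(y)
    if (V < 1e-12)
      return(list(Si = rep(0, k), VHat = V))
    Si <- vapply(seq_len(k), function(i) {
      # jittered stratification of the conditioning variable (variance
      # reduction on the outer loop; inner draws stay plain pseudo-random)
      xi <- (seq_len(n_outer) - runif(n_outer)) / n_outer
      condStats <- vapply(xi, function(x) {
        U <- matrix(runif(n_inner * k), ncol = k)
        U[, i] <- x
        yi <- fun(U)
        c(mean(yi), var(yi))
      }, numeric(2))
      # variance of conditional means, bias-corrected for inner-loop noise
      max(var(condStats[1, ]) - mean(condStats[2, ]) / n_inner, 0) / V
    }, numeric(1))
    list(Si = Si, VHat = V)
  })
}
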