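## Quasi-random sampling designs for Saltelli-style GSA.

# Primitive polynomials and initial direction numbers for the Sobol'
# sequence, dimensions 2..41 (dimension 1 uses m = 1 for all orders).
# These are the published Joe & Kuo (2008) "new-joe-kuo-6" constants; the
# polynomial is encoded with all coefficient bits (e.g. 7 = x^2 + x + 1).
.jk_poly <- c(
  3L, 7L, 11L, 13L, 19L, 25L, 37L, 41L, 47L, 55L, 59L, 61L, 67L, 91L, 97L,
  103L, 109L, 115L, 131L, 137L, 143L, 145L, 157L, 167L, 171L, 185L, 191L,
  193L, 203L, 211L, 213L, 229L, 239L, 241L, 247L, 253L, 285L, 299L, 301L
)
.jk_minit <- list(
  1L, c(1L, 3L), c(1L, 3L, 1L), c(1L, 1L, 1L), c(1L, 1L, 3L, 3L),
  c(1L, 3L, 5L, 13L), c(1L, 1L, 5L, 5L, 17L), c(1L, 1L, 5L, 5L, 5L),
  c(1L, 1L, 7L, 11L, 19L), c(1L, 1L, 5L, 1L, 1L), c(1L, 1L, 1L, 3L, 11L),
  c(1L, 3L, 5L, 5L, 31L), c(1L, 3L, 3L, 9L, 7L, 49L),
  c(1L, 1L, 1L, 15L, 21L, 21L), c(1L, 3L, 1L, 13L, 27L, 49L),
  c(1L, 1L, 1L, 15L, 7L, 5L), c(1L, 3L, 1L, 15L, 13L, 25L),
  c(1L, 1L, 5L, 5L, 19L, 61L), c(1L, 3L, 7L, 11L, 23L, 15L, 103L),
  c(1L, 3L, 7L, 13L, 13L, 15L, 69L), c(1L, 1L, 3L, 13L, 7L, 35L, 63L),
  c(1L, 3L, 5L, 9L, 1L, 25L, 53L), c(1L, 3L, 1L, 13L, 9L, 35L, 107L),
  c(1L, 3L, 1L, 5L, 27L, 61L, 31L), c(1L, 1L, 5L, 11L, 19L, 41L, 61L),
  c(1L, 3L, 5L, 3L, 3L, 13L, 69L), c(1L, 1L, 7L, 13L, 1L, 19L, 1L),
  c(1L, 3L, 7L, 5L, 13L, 19L, 59L), c(1L, 1L, 3L, 9L, 25L, 29L, 41L),
  c(1L, 3L, 5L, 13L, 23L, 1L, 55L), c(1L, 3L, 7L, 3L, 13L, 59L, 17L),
  c(1L, 3L, 1L, 3L, 5L, 53L, 69L), c(1L, 1L, 5L, 5L, 23L, 33L, 13L),
  c(1L, 1L, 7L, 7L, 1L, 61L, 123L), c(1L, 1L, 7L, 9L, 13L, 61L, 49L),
  c(1L, 3L, 3L, 5L, 3L, 55L, 33L), c(1L, 3L, 1L, 15L, 31L, 13L, 49L, 245L),
  c(1L, 3L, 5L, 15L, 31L, 59L, 63L, 97L),
  c(1L, 3L, 1L, 11L, 11L, 11L, 77L, 249L)
)

.sobol_bits <- 30L
.sobol_max_dim <- length(.jk_poly) + 1L

# Direction integers v_1..v_B (fixed point with .sobol_bits bits) for one
# dimension.
.sobolDirections <- function(dim, bits = .sobol_bits) {
  if (dim == 1L) {
    m <- rep(1L, bits)
  } else {
    p <- .jk_poly[dim - 1L]
    m0 <- .jk_minit[[dim - 1L]]
    s <- length(m0)
    # interior coefficient bits a_1..a_{s-1} of the primitive polynomial
    a <- integer(max(s - 1L, 0L))
    for (j in seq_len(s - 1L)) a[j] <- bitwAnd(bitwShiftR(p, s - j), 1L)
    m <- c(m0, integer(max(bits - s, 0L)))
    if (bits > s) {
      for (i in (s + 1L):bits) {
        newm <- bitwXor(bitwShiftL(m[i - s], s), m[i - s])
        for (j in seq_len(s - 1L)) {
          if (a[j] == 1L)
            newm <- bitwXor(newm, bitwShiftL(m[i - j], j))
        }
        m[i] <- newm
      }
    }
    m <- m[seq_len(bits)]
  }
  vapply(seq_len(bits), function(i) bitwShiftL(m[i], bits - i), integer(1))
}

#' Sobol' low-discrepancy sequence
#'
#' Generates the first `n` points (after skipping the initial all-zeros
#' point) of the unscrambled `d`-dimensional Sobol' sequence, using the
#' published Joe-Kuo direction numbers and Gray-code ordering. The sequence
#' is fully deterministic; no seed is involved.
#'
#' @param n number of points.
#' @param d dimension (1 to 41).
#' @param skip number of initial points to discard; the default 1 drops the
#'   all-zeros point so that every returned coordinate lies in (0, 1).
#' @return an `n x d` matrix with entries in `(0, 1)`.
#' @examples
#' sobolSequence(4, 2)
#' @export
sobolSequence <- function(n, d, skip = 1L) {
  stopifnot(n >= 1, d >= 1, skip >= 0)
  if (d > .sobol_max_dim)
    stop(sprintf("Sobol' sequence supports at most %d dimensions",
                 .sobol_max_dim))
  V <- vapply(seq_len(d), .sobolDirections, integer(.sobol_bits))  # B x d
  out <- matrix(0, n, d)
  cur <- integer(d)
  total <- n + skip - 1L
  keep <- 0L
  for (i in seq_len(total)) {
    # index of lowest set bit of i (Gray-code step)
    c <- 1L
    ii <- i
    while (bitwAnd(ii, 1L) == 0L) {
      ii <- bitwShiftR(ii, 1L)
      c <- c + 1L
    }
    cur <- bitwXor(cur, V[c, ])
    if (i >= skip) {
      keep <- keep + 1L
      out[keep, ] <- cur
    }
  }
  out / 2^.sobol_bits
}

.design_schemes <- c("uniform-sobol", "uniform-random", "latin-hypercube")

#' Build the radial recombination matrices
#'
#' For base matrices `P` and `Q` of equal shape `N x k`, returns the list of
#' `k` matrices in which the i-th matrix equals `P` with its i-th column
#' replaced by the i-th column of `Q` (the radial sampling scheme used to
#' estimate Si and STi simultaneously).
#'
#' @param P,Q numeric matrices of identical shape.
#' @return list of `k = ncol(P)` matrices.
#' @examples
#' radialMatrices(matrix(c(0.1, 0.2), 1), matrix(c(0.9, 0.8), 1))
#' @export
radialMatrices <- function(P, Q) {
  if (!identical(dim(P), dim(Q)))
    stop("P and Q must have identical dimensions")
  lapply(seq_len(ncol(P)), function(i) {
    R <- P
    R[, i] <- Q[, i]
    R
  })
}

#' Generate a unit-hypercube Saltelli design
#'
#' Draws an `N x 2k` sample on the unit hypercube with the requested scheme,
#' splits it into the two base matrices `P` (left `k` columns) and `Q`
#' (right `k` columns), and attaches the `k` radial matrices. Evaluating a
#' model on the full design costs exactly `N (k + 2)` runs.
#'
#' The default `"uniform-sobol"` scheme is a deterministic unscrambled
#' Sobol' sequence (the leading all-zeros point is skipped), so identical
#' `(k, N)` always reproduce the same design regardless of `seed`; the seed
#' only drives the stochastic `"uniform-random"` and `"latin-hypercube"`
#' schemes.
#'
#' @param k number of model input variables (>= 1).
#' @param N samples per matrix (>= 2).
#' @param scheme one of `"uniform-sobol"` (default), `"uniform-random"`,
#'   `"latin-hypercube"`.
#' @param seed integer seed for stochastic schemes.
#' @return a [DesignMatrices-class] object.
#' @examples
#' d <- generateUnitDesign(k = 3, N = 8)
#' designP(d)[1:2, ]
#' @export
generateUnitDesign <- function(k, N, scheme = "uniform-sobol", seed = 1L) {
  if (!(is.numeric(k) && length(k) == 1 && k >= 1))
    stop("k must be a positive scalar")
  if (!(is.numeric(N) && length(N) == 1 && N >= 2))
    stop("N must be at least 2")
  k <- as.integer(k)
  N <- as.integer(N)
  scheme <- match.arg(scheme, .design_schemes)
  U <- switch(scheme,
    "uniform-sobol" = sobolSequence(N, 2L * k),
    "uniform-random" = .withLocalSeed(seed, matrix(runif(N * 2L * k), N)),
    "latin-hypercube" = .withLocalSeed(seed, lhs::randomLHS(N, 2L * k))
  )
  P <- U[, seq_len(k), drop = FALSE]
  Q <- U[, k + seq_len(k), drop = FALSE]
  new("DesignMatrices",
      P = P, Q = Q, radial = radialMatrices(P, Q),
      N = N, k = k, scheme = scheme,
      seed = if (scheme == "uniform-sobol") NA_integer_ else as.integer(seed))
}

# Run expr under a local RNG seed without disturbing the caller's RNG state.
.withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Variable specification table
#'
#' Builds and validates the table of model input variables (name, physical
#' bounds, unit, marginal distribution) used to scale unit designs to
#' physical values.
#'
#' @param name character vector of unique variable names.
#' @param min,max numeric vectors of physical bounds (`min < max`).
#' @param unit character vector of unit strings.
#' @param distribution marginal distribution tag; currently all supported
#'   schemes use uniform marginals.
#' @return a data.frame with class `"variableSpec"` prepended.
#' @examples
#' variableSpec("Cab", 0, 80, "ug/cm2")
#' @export
variableSpec <- function(name, min, max, unit = "-",
                         distribution = "uniform") {
  df <- data.frame(name = as.character(name), min = as.numeric(min),
                   max = as.numeric(max), unit = unit,
                   distribution = distribution, stringsAsFactors = FALSE)
  if (anyDuplicated(df$name)) stop("variable names must be unique")
  if (any(df$min >= df$max)) stop("each variable needs min < max")
  class(df) <- c("variableSpec", class(df))
  df
}

#' Export design matrices as CSV files for audit
#'
#' Writes `P.csv`, `Q.csv` and `radial_<i>.csv` into a directory.
#'
#' @param design a [DesignMatrices-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the file paths written.
#' @export
writeDesignMatrices <- function(design, dir) {
  stopifnot(is(design, "DesignMatrices"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(file.path(dir, "P.csv"), file.path(dir, "Q.csv"),
             file.path(dir, sprintf("radial_%d.csv", seq_len(design@k))))
  write.csv(designP(design), paths[1], row.names = FALSE)
  write.csv(designQ(design), paths[2], row.names = FALSE)
  for (i in seq_len(design@k))
    write.csv(design@radial[[i]], paths[2 + i], row.names = FALSE)
  invisible(paths)
}

#' Scale a unit design to physical variable bounds
#'
#' Maps each column of a unit-hypercube matrix affinely from `[0, 1]` to the
#' `[min, max]` interval of the corresponding variable.
#'
#' @param unit numeric matrix with entries in `[0, 1]`, one column per
#'   variable.
#' @param specs a variable specification table (see [variableSpec()]).
#' @return numeric matrix of physical values with variable names as column
#'   names.
#' @examples
#' scaleDesign(matrix(0.5, 1, 1), variableSpec("Cab", 0, 80, "ug/cm2"))
#' @export
scaleDesign <- function(unit, specs) {
  unit <- as.matrix(unit)
  if (ncol(unit) != nrow(specs))
    stop("column count of the design must equal the number of variable specs")
  if (any(specs$min >= specs$max)) stop("each variable needs min < max")
  out <- sweep(unit, 2, specs$max - specs$min, "*")
  out <- sweep(out, 2, specs$min, "+")
  colnames(out) <- specs$name
  out
}
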