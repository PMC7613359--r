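## End-to-end orchestration: configuration, model evaluation over Saltelli
## designs, per-index and per-wavelength GSA, and result writers.

.models <- c("PROSAIL", "PROINFORM", "toy")

#' Default variable specifications per model
#'
#' The standard simulation bounds: four leaf variables (structure `N`,
#' chlorophyll `Cab`, water `Cw`, dry matter `Cm`), the shared canopy
#' variables (mean leaf angle `LAD`, solar zenith `SZA`, soil brightness
#' `soil_coeff`), plus `LAI` for the homogeneous canopy model or the five
#' forest-structure variables (`LAIs`, `LAIu`, `SD`, `H`, `CD`) for the
#' forest model. The observer stays at nadir; hot spot and diffuse fraction
#' are fixed at their defaults and are not sampled.
#'
#' @param model `"PROSAIL"` (8 variables), `"PROINFORM"` (12) or `"toy"`.
#' @param toyParams number of toy-model parameters (toy only).
#' @return a [variableSpec()] table.
#' @examples
#' defaultVariableSpecs("PROSAIL")
#' @export
defaultVariableSpecs <- function(model, toyParams = 4L) {
  model <- match.arg(model, .models)
  leaf <- variableSpec(
    c("N", "Cab", "Cw", "Cm"),
    min = c(1, 0, 0.001, 0.001),
    max = c(2.6, 80, 0.08, 0.02),
    unit = c("-", "ug/cm2", "cm", "g/cm2"))
  shared <- variableSpec(
    c("LAD", "SZA", "soil_coeff"),
    min = c(0, 0, 0), max = c(90, 60, 1),
    unit = c("deg", "deg", "-"))
  out <- switch(model,
    PROSAIL = rbind(leaf, shared,
                    variableSpec("LAI", 0, 10, "m2/m2")),
    PROINFORM = rbind(leaf, shared,
                      variableSpec(c("LAIs", "LAIu", "SD", "H", "CD"),
                                   min = c(0, 0, 0.5, 0.5, 0.1),
                                   max = c(10, 5, 1500, 30, 10),
                                   unit = c("m2/m2", "m2/m2", "1/ha", "m",
                                            "m"))),
    toy = variableSpec(paste0("x", seq_len(toyParams)),
                       rep(0, toyParams), rep(1, toyParams))
  )
  class(out) <- c("variableSpec", "data.frame")
  out
}

#' Assemble and validate a run configuration
#'
#' @param model RTM choice: `"PROSAIL"`, `"PROINFORM"` or `"toy"`.
#' @param N samples per variable scheme (the full design then costs
#'   `N (k + 2)` model evaluations).
#' @param scheme,seed sampling scheme and seed (see
#'   [generateUnitDesign()]).
#' @param sensor optional sensor name or [Sensor-class] for band-setting
#'   convolution.
#' @param vi character vector of registry abbreviations, a list of
#'   [VIDefinition-class] objects, or `NULL` for every applicable shipped
#'   index.
#' @param specs optional custom [variableSpec()] table replacing the model
#'   default.
#' @param srfShape SRF shape for sensor convolution.
#' @param hotspot,skyl fixed canopy parameters (hot-spot parameter and
#'   diffuse irradiance fraction).
#' @param toyParams,toyActive toy-model size and number of active
#'   parameters.
#' @return validated configuration list of class `"vigsaConfig"`.
#' @export
runConfig <- function(model = "PROSAIL", N = 2000, scheme = "uniform-sobol",
                      seed = 1L, sensor = NULL, vi = NULL, specs = NULL,
                      srfShape = "gaussian", hotspot = 0.01, skyl = 0,
                      toyParams = 4L, toyActive = NULL) {
  model <- match.arg(model, .models)
  if (N < 2) stop("N must be at least 2")
  scheme <- match.arg(scheme, .design_schemes)
  if (is.null(specs)) specs <- defaultVariableSpecs(model, toyParams)
  if (!is.null(sensor) && is.character(sensor)) sensor <- getSensor(sensor)
  cfg <- structure(list(
    model = model, N = as.integer(N), scheme = scheme,
    seed = as.integer(seed), sensor = sensor, vi = vi, specs = specs,
    srfShape = srfShape, hotspot = hotspot, skyl = skyl,
    toyParams = as.integer(toyParams),
    toyActive = if (is.null(toyActive)) NULL else as.integer(toyActive)
  ), class = "vigsaConfig")
  .resolveViDefs(cfg)   # fail early on unresolvable indices
  cfg
}

.resolveViDefs <- function(config) {
  if (is.list(config$vi) &&
      all(vapply(config$vi, is, logical(1), "VIDefinition")))
    return(config$vi)
  reg <- builtinRegistry(config$sensor)
  if (is.null(config$vi)) {
    if (is.null(config$sensor)) {
      # native grid: only indices without role symbols are evaluable
      reg <- builtinRegistry()
      keep <- vapply(reg, function(d)
        length(viRequiredSymbols(d)$roles) == 0, logical(1))
      return(reg[keep])
    }
    return(reg)
  }
  defs <- lapply(config$vi, function(a) {
    allreg <- builtinRegistry()
    if (!a %in% names(allreg)) stop("unknown index abbreviation: ", a)
    d <- allreg[[a]]
    if (!is.null(config$sensor) &&
        !config$sensor@name %in% d@applicableSensors)
      stop("index ", a, " is not applicable to sensor ",
           config$sensor@name)
    d
  })
  names(defs) <- config$vi
  defs
}

#' Read a run configuration from a YAML or JSON file
#'
#' Recognised top-level fields match the arguments of [runConfig()];
#' `specs` may be given as a list of records with `name`, `min`, `max`,
#' `unit`.
#'
#' @param path config file path (`.yaml`/`.yml` or `.json`).
#' @return a `"vigsaConfig"` object.
#' @export
readRunConfig <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  # YAML 1.1 parses a bare key `N` as boolean FALSE; restore it
  names(raw)[names(raw) %in% c("FALSE", "F")] <- "N"
  if (!is.null(raw$specs)) {
    sp <- as.data.frame(raw$specs)
    raw$specs <- variableSpec(sp$name, sp$min, sp$max,
                              if (is.null(sp$unit)) "-" else sp$unit)
  }
  do.call(runConfig, raw)
}

# --- model evaluation -------------------------------------------------------

# 1-nm -> 5-nm block-average index table, cached.
.avg1to5 <- function(v) {
  idx <- .vigsa_cache$idx5
  if (is.null(idx)) {
    centres <- seq(1, 2101, by = 5)
    idx <- outer(-2:2, centres, "+")
    idx[idx < 1] <- 1
    idx[idx > 2101] <- 2101
    .vigsa_cache$idx5 <- idx
  }
  colMeans(matrix(v[idx], nrow = 5))
}

#' Simulate spectra for every row of a physical design
#'
#' Evaluates the configured radiative transfer model once per design row
#' and stacks the resulting top-of-canopy reflectance spectra. The
#' homogeneous-canopy model works on the 1-nm grid (2101 bands), the forest
#' model on the 5-nm grid (421 bands, leaf optics block-averaged before the
#' canopy stage), the toy model on the 1-nm grid.
#'
#' @param config a `"vigsaConfig"` (its `model`, `hotspot`, `skyl` and toy
#'   settings are used).
#' @param X physical design matrix with columns in spec order.
#' @return a [SpectrumSet-class] with `nrow(X)` spectra.
#' @export
simulateDesignSpectra <- function(config, X) {
  model <- config$model
  n <- nrow(X)
  cn <- colnames(X)
  if (model == "toy") {
    wl <- 400:2500
    nAct <- if (is.null(config$toyActive)) ncol(X) else config$toyActive
    vals <- matrix(0, n, length(wl))
    for (i in seq_len(n))
      vals[i, ] <- toyCanopy(X[i, ], wl, nActive = nAct)
    return(new("SpectrumSet", wavelengths = as.numeric(wl), values = vals,
               gridId = "1nm-2101"))
  }
  coeffs <- syntheticLeafCoefficients()
  wl1 <- as.numeric(400:2500)
  soilBase1 <- syntheticSoilSpectrum(wl1, 1)
  leafCols <- c("N", "Cab", "Cw", "Cm")
  if (!all(c(leafCols, "LAD", "SZA", "soil_coeff") %in% cn))
    stop("design must provide columns ",
         paste(c(leafCols, "LAD", "SZA", "soil_coeff"), collapse = ", "))
  if (model == "PROSAIL") {
    stopifnot("LAI" %in% cn)
    vals <- matrix(0, n, 2101)
    for (i in seq_len(n)) {
      x <- X[i, ]
      rt <- prospect4(list(N_struct = x[["N"]], Cab = x[["Cab"]],
                           Cw = x[["Cw"]], Cm = x[["Cm"]]), coeffs)
      vals[i, ] <- sailTOC(rt$reflectance, rt$transmittance,
                           list(LAI = x[["LAI"]], LAD = x[["LAD"]],
                                SZA = x[["SZA"]], hotspot = config$hotspot,
                                skyl = config$skyl),
                           x[["soil_coeff"]] * soilBase1)
    }
    return(new("SpectrumSet", wavelengths = wl1, values = vals,
               gridId = "1nm-2101"))
  }
  # PROINFORM
  stopifnot(all(c("LAIs", "LAIu", "SD", "H", "CD") %in% cn))
  wl5 <- seq(400, 2500, by = 5)
  soilBase5 <- .avg1to5(soilBase1)
  vals <- matrix(0, n, 421)
  for (i in seq_len(n)) {
    x <- X[i, ]
    rt <- prospect4(list(N_struct = x[["N"]], Cab = x[["Cab"]],
                         Cw = x[["Cw"]], Cm = x[["Cm"]]), coeffs)
    lr <- .avg1to5(rt$reflectance)
    lt <- .avg1to5(rt$transmittance)
    f <- informTOC(lr, lt,
                   list(LAIs = x[["LAIs"]], LAIu = x[["LAIu"]],
                        SD = x[["SD"]], H = x[["H"]], CD = x[["CD"]],
                        LAD = x[["LAD"]], SZA = x[["SZA"]],
                        hotspot = config$hotspot, skyl = config$skyl),
                   x[["soil_coeff"]] * soilBase5)
    vals[i, ] <- f$reflectance
  }
  new("SpectrumSet", wavelengths = wl5, values = vals, gridId = "5nm-421")
}

# Evaluate spectra for the whole stacked design [P; R1..Rk; Q] and return
# the spectrum set plus the block index map.
.simulateFullDesign <- function(config, design) {
  specs <- config$specs
  k <- design@k
  N <- design@N
  Uall <- rbind(designP(design),
                do.call(rbind, designRadial(design)),
                designQ(design))
  X <- scaleDesign(Uall, specs)
  sset <- simulateDesignSpectra(config, X)
  idx <- list(P = seq_len(N),
              R = lapply(seq_len(k), function(i) N * i + seq_len(N)),
              Q = N * (k + 1) + seq_len(N))
  # bookkeeping from the rows actually simulated (equals N (k + 2))
  list(spectra = sset, idx = idx, evaluations = nrow(spectra(sset)))
}

# --- main entry points ------------------------------------------------------

#' Run the full vegetation-index GSA workflow
#'
#' Builds the Saltelli design, simulates one spectrum per design row
#' (spectra are simulated once and shared by all requested indices),
#' convolves to the sensor band setting when a sensor is configured,
#' evaluates every index, and estimates first-order and total-effect
#' Sobol' indices per index and model variable.
#'
#' @param config a `"vigsaConfig"` from [runConfig()] /
#'   [readRunConfig()].
#' @return object of class `"ViGsaRun"`: list with `results` (named list
#'   of [GSAResult-class], one per index), `table` (long data.frame with
#'   one row per index x variable) and `meta` (run metadata, including the
#'   exact model evaluation count `N (k + 2)`).
#' @examples
#' cfg <- runConfig(model = "toy", N = 128, sensor = "Landsat8",
#'                  vi = c("NDVI", "GNDVI"))
#' run <- runViGsa(cfg)
#' run$meta$evaluations  # 128 * (4 + 2)
#' @export
runViGsa <- function(config) {
  stopifnot(inherits(config, "vigsaConfig"))
  defs <- .resolveViDefs(config)
  if (!length(defs)) stop("no evaluable index for this configuration")
  specs <- config$specs
  design <- generateUnitDesign(nrow(specs), config$N, config$scheme,
                               config$seed)
  sim <- .simulateFullDesign(config, design)
  bandSet <- if (!is.null(config$sensor))
    convolveToSensor(sim$spectra, config$sensor, config$srfShape)
  else sim$spectra

  results <- lapply(defs, function(d) {
    v <- evaluateViOnSpectra(d, bandSet, config$sensor)
    estimateSobolIndices(v[sim$idx$P], v[sim$idx$Q],
                         lapply(sim$idx$R, function(ii) v[ii]),
                         specs$name)
  })
  tab <- do.call(rbind, lapply(names(results), function(nm) {
    df <- as.data.frame(results[[nm]])
    cbind(output_name = nm, df, stringsAsFactors = FALSE)
  }))
  structure(list(
    results = results, table = tab,
    meta = list(model = config$model,
                sensor = if (is.null(config$sensor)) NA_character_
                         else config$sensor@name,
                N = config$N, k = nrow(specs), scheme = config$scheme,
                seed = config$seed, evaluations = sim$evaluations,
                srfShape = config$srfShape,
                excludedRows = vapply(results, function(r) r@nExcluded,
                                      integer(1)),
                bounds = specs)
  ), class = "ViGsaRun")
}

#' @export
print.ViGsaRun <- function(x, ...) {
  cat(sprintf("Vegetation-index GSA run: %s%s, N = %d, k = %d (%d model runs)\n",
              x$meta$model,
              if (is.na(x$meta$sensor)) "" else paste0(" / ", x$meta$sensor),
              x$meta$N, x$meta$k, x$meta$evaluations))
  sti <- sapply(x$results, function(r) r@STi)
  rownames(sti) <- x$results[[1]]@variableNames
  cat("Total-effect indices (STi):\n")
  print(round(t(sti), 3))
  invisible(x)
}

#' Per-wavelength spectral GSA
#'
#' Runs the GSA with every wavelength of the native model grid as a
#' separate output, yielding a matrix of total-effect (and first-order)
#' indices of shape grid-length x variables. No sensor is involved.
#'
#' @param config a `"vigsaConfig"` (its `sensor`/`vi` fields are ignored).
#' @return object of class `"SpectralGsaResult"`: list with `wavelengths`,
#'   `STi` and `Si` (matrices, wavelengths x variables), `degenerate`
#'   (logical per wavelength) and `meta`.
#' @export
runSpectralGsa <- function(config) {
  stopifnot(inherits(config, "vigsaConfig"))
  specs <- config$specs
  design <- generateUnitDesign(nrow(specs), config$N, config$scheme,
                               config$seed)
  sim <- .simulateFullDesign(config, design)
  V <- spectra(sim$spectra)
  est <- .sobolIndicesMatrix(V[sim$idx$P, , drop = FALSE],
                             V[sim$idx$Q, , drop = FALSE],
                             lapply(sim$idx$R, function(ii)
                               V[ii, , drop = FALSE]))
  STi <- t(est$STi); Si <- t(est$Si)
  colnames(STi) <- specs$name
  colnames(Si) <- specs$name
  structure(list(
    wavelengths = wavelengths(sim$spectra),
    STi = pmax(STi, 0), Si = pmax(Si, 0),
    STiRaw = STi, SiRaw = Si,
    degenerate = est$degenerate,
    meta = list(model = config$model, N = config$N, k = nrow(specs),
                scheme = config$scheme, seed = config$seed,
                evaluations = sim$evaluations)
  ), class = "SpectralGsaResult")
}

#' @export
print.SpectralGsaResult <- function(x, ...) {
  cat(sprintf("Spectral GSA: %s, %d wavelengths x %d variables (N = %d)\n",
              x$meta$model, nrow(x$STi), ncol(x$STi), x$meta$N))
  invisible(x)
}

# --- writers ----------------------------------------------------------------

#' Write GSA results and a run manifest to disk
#'
#' Writes `results.csv` (long table: output_name, variable, Si_raw, Si,
#' STi_raw, STi, STi_share, N, degenerate) and `manifest.json` (scheme,
#' seed, bounds, evaluation counts, per-index excluded-row counts, config
#' hash).
#'
#' @param run a `"ViGsaRun"`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
writeGsaResults <- function(run, dir) {
  stopifnot(inherits(run, "ViGsaRun"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "results.csv")
  write.csv(run$table, csv, row.names = FALSE)
  meta <- run$meta
  meta$bounds <- as.data.frame(meta$bounds)
  meta$configHash <- .hashObject(meta[c("model", "sensor", "N", "k",
                                        "scheme", "seed", "srfShape")])
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(meta, manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv, manifest))
}

#' Write spectral GSA results to disk
#'
#' One CSV row per wavelength with the per-variable total-effect indices.
#'
#' @param res a `"SpectralGsaResult"`.
#' @param dir output directory.
#' @return invisibly, the path written.
#' @export
writeSpectralResults <- function(res, dir) {
  stopifnot(inherits(res, "SpectralGsaResult"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "spectral_sti.csv")
  df <- data.frame(wavelength_nm = res$wavelengths, res$STi,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.hashObject <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}
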