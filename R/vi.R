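## Vegetation-index expression engine and the registry of published
## indices.

.vi_roles <- c("BLUE", "GREEN", "RED", "RedEdge", "NIR", "SWIR")
.vi_functions <- c("+", "-", "*", "/", "^", "(", "sqrt", "abs", "rho")

#' Parse a vegetation-index expression
#'
#' Parses an index formula over the band-role symbols BLUE, GREEN, RED,
#' RedEdge, NIR, SWIR, explicit-wavelength terms `rho(lambda)`, numeric
#' literals and the operators `+ - * / ^` plus `sqrt()` and `abs()`.
#' Anything else (assignment, other functions, unknown symbols) is
#' rejected.
#'
#' @param text the formula text.
#' @return the validated expression tree (an R language object).
#' @examples
#' parseViExpression("(NIR-RED)/(NIR+RED)")
#' @export
parseViExpression <- function(text) {
  if (!is.character(text) || length(text) != 1 || !nzchar(trimws(text)))
    stop("VI expression must be a single nonempty string")
  exprs <- tryCatch(parse(text = text, keep.source = FALSE),
                    error = function(e)
                      stop("syntax error in VI expression: ",
                           conditionMessage(e), call. = FALSE))
  if (length(exprs) != 1)
    stop("VI expression must be a single formula")
  tree <- exprs[[1]]
  .validateViTree(tree)
  tree
}

.validateViTree <- function(node) {
  if (is.numeric(node)) return(invisible(TRUE))
  if (is.symbol(node)) {
    s <- as.character(node)
    if (!s %in% .vi_roles)
      stop("unknown symbol '", s, "' in VI expression (allowed roles: ",
           paste(.vi_roles, collapse = ", "), ")")
    return(invisible(TRUE))
  }
  if (is.call(node)) {
    fn <- as.character(node[[1]])
    if (!fn %in% .vi_functions)
      stop("function '", fn, "' not allowed in VI expressions")
    if (fn == "rho") {
      if (length(node) != 2 || !is.numeric(node[[2]]))
        stop("rho() takes a single numeric wavelength")
      return(invisible(TRUE))
    }
    for (i in seq_along(node)[-1]) .validateViTree(node[[i]])
    return(invisible(TRUE))
  }
  stop("unsupported element in VI expression: ", deparse(node))
}

#' Serialize a parsed VI expression back to text
#'
#' @param tree expression tree from [parseViExpression()].
#' @return single string; reparsing it yields an identical tree.
#' @export
serializeViExpression <- function(tree) {
  paste(deparse(tree, width.cutoff = 500L), collapse = "")
}

#' Symbols required by a VI definition
#'
#' @param def a [VIDefinition-class].
#' @return list with `roles` (character) and `wavelengths` (numeric) used
#'   by the expression.
#' @export
viRequiredSymbols <- function(def) {
  roles <- character()
  wls <- numeric()
  walk <- function(node) {
    if (is.symbol(node)) {
      roles <<- union(roles, as.character(node))
    } else if (is.call(node)) {
      if (identical(as.character(node[[1]]), "rho"))
        wls <<- union(wls, as.numeric(node[[2]]))
      else for (i in seq_along(node)[-1]) walk(node[[i]])
    }
  }
  walk(parseViExpression(def@expression))
  list(roles = intersect(roles, .vi_roles), wavelengths = sort(wls))
}

# Guarded recursive evaluator over vectors. `bands` is a named list of
# per-simulation reflectance vectors for role symbols plus an element
# `rho`: function(lambda) -> vector.
.evalViNode <- function(node, bands) {
  if (is.numeric(node)) return(node)
  if (is.symbol(node)) {
    s <- as.character(node)
    v <- bands[[s]]
    if (is.null(v)) stop("missing band for role '", s, "'")
    return(v)
  }
  fn <- as.character(node[[1]])
  if (fn == "(") return(.evalViNode(node[[2]], bands))
  if (fn == "rho") return(bands$rho(as.numeric(node[[2]])))
  if (fn %in% c("+", "-") && length(node) == 2) {
    v <- .evalViNode(node[[2]], bands)
    return(if (fn == "-") -v else v)
  }
  a <- .evalViNode(node[[2]], bands)
  b <- if (length(node) >= 3) .evalViNode(node[[3]], bands) else NULL
  switch(fn,
    "+" = a + b,
    "-" = a - b,
    "*" = a * b,
    "/" = {
      out <- a / b
      out[abs(b) < 1e-9] <- NaN   # guarded denominator: flag, don't clamp
      out
    },
    "^" = suppressWarnings(a^b),
    "sqrt" = suppressWarnings(sqrt(a)),
    "abs" = abs(a),
    stop("function '", fn, "' not allowed")
  )
}

#' Evaluate a vegetation index on band reflectances
#'
#' Evaluates the index expression on a record of band reflectances. Role
#' symbols resolve through the `bands` list; `rho(lambda)` terms resolve
#' through its `rho` element. Divisions by (near-)zero denominators yield
#' `NaN`, signalling an invalid simulation to the GSA row-exclusion path
#' rather than fabricating a value.
#'
#' @param def a [VIDefinition-class] (or a bare expression string).
#' @param bands named list: one numeric vector per role symbol used, plus
#'   optionally `rho = function(lambda)` for wavelength terms.
#' @return numeric vector of index values (`NaN` where invalid).
#' @examples
#' ndvi <- builtinRegistry()[["NDVI"]]
#' evaluateVi(ndvi, list(NIR = 0.5, RED = 0.1))
#' @export
evaluateVi <- function(def, bands) {
  expr <- if (is(def, "VIDefinition")) def@expression else def
  tree <- parseViExpression(expr)
  if (is.null(bands$rho))
    bands$rho <- function(lambda)
      stop("expression uses rho(", lambda,
           ") but no wavelength resolver was provided")
  out <- .evalViNode(tree, bands)
  out[!is.finite(out)] <- NaN
  out
}

#' Evaluate a vegetation index on a spectrum set
#'
#' Resolves role symbols via a sensor's role-to-band mapping (the spectra
#' must then be sensor-band reflectances from [convolveToSensor()]) and
#' `rho(lambda)` terms via [nearestBandValue()] on the active grid, then
#' evaluates the index for every simulation.
#'
#' @param def a [VIDefinition-class].
#' @param spectra a [SpectrumSet-class] (native grid or sensor bands).
#' @param sensor optional [Sensor-class] providing the role mapping;
#'   without it only pure-`rho` expressions can be evaluated.
#' @return numeric vector, one index value per simulation.
#' @export
evaluateViOnSpectra <- function(def, spectra, sensor = NULL) {
  stopifnot(is(def, "VIDefinition"), is(spectra, "SpectrumSet"))
  if (!is.null(sensor) && is.character(sensor)) sensor <- getSensor(sensor)
  if (!is.null(sensor) &&
      !def@abbreviation %in% c("", "custom") &&
      !"grid" %in% def@applicableSensors &&
      !sensor@name %in% def@applicableSensors)
    stop("index ", def@abbreviation, " is not applicable to sensor ",
         sensor@name)
  vals <- spectra(spectra)
  bands <- list(rho = function(lambda) nearestBandValue(spectra, lambda))
  need <- viRequiredSymbols(def)
  if (length(need$roles)) {
    if (is.null(sensor))
      stop("expression uses band roles; a sensor is required")
    roles <- sensorRoles(sensor)
    for (r in need$roles) {
      if (!r %in% names(roles))
        stop("sensor ", sensor@name, " has no band for role ", r)
      bandName <- roles[[r]]
      j <- match(bandName, colnames(vals))
      if (is.na(j))
        stop("band ", bandName, " not present in the spectrum set")
      bands[[r]] <- vals[, j]
    }
  }
  evaluateVi(def, bands)
}

# --- the shipped registry ---------------------------------------------------

.mkVi <- function(abbrev, name, expr, target, sensors, note = "") {
  new("VIDefinition", name = name, abbreviation = abbrev,
      expression = expr, targetVariable = target,
      applicableSensors = sensors, note = note)
}

.builtinViList <- function() {
  if (!is.null(.vigsa_cache$viRegistry)) return(.vigsa_cache$viRegistry)
  bb4 <- c("Landsat8", "MODIS", "Sentinel2", "Sentinel3")
  all5 <- c(bb4, "EnMAP")
  ndvi <- "(NIR-RED)/(NIR+RED)"
  ctvi <- sprintf("((%s+0.5)/abs(%s+0.5))*sqrt(abs(%s+0.5))",
                  ndvi, ndvi, ndvi)
  defs <- list(
    ## --- chlorophyll (LCC) ---
    .mkVi("CVI", "Chlorophyll vegetation index",
          "NIR*RED/GREEN^2", "LCC", all5),
    .mkVi("CIgreen", "Chlorophyll index green",
          "NIR/GREEN-1", "LCC", all5),
    .mkVi("GLI", "Green leaf index",
          "(2*GREEN-RED-BLUE)/(2*GREEN+RED+BLUE)", "LCC", all5),
    .mkVi("GNDVI", "Green NDVI",
          "(NIR-GREEN)/(NIR+GREEN)", "LCC", all5),
    .mkVi("GRVI", "Green ratio vegetation index",
          "NIR/GREEN", "LCC", all5),
    .mkVi("SR:550/800", "Simple ratio 550/800",
          "rho(550)/rho(800)", "LCC", all5,
          "table form rho550/rho800 kept as printed"),
    .mkVi("CIrededge", "Chlorophyll index red-edge",
          "NIR/RedEdge-1", "LCC", c("Sentinel2", "Sentinel3", "EnMAP")),
    .mkVi("Chlrededge", "Chlorophyll red-edge",
          "RedEdge/RED-1", "LCC", "EnMAP",
          "printed reading (RedEdge/Red)-1"),
    .mkVi("DD", "Double difference index",
          "(rho(749)-rho(720))-(rho(701)-rho(672))", "LCC", "EnMAP"),
    .mkVi("DPI", "Double peak index",
          "(rho(698)*rho(710))/rho(697)^2", "LCC", "EnMAP",
          "canonical product form; source prints a '+' between the bands"),
    .mkVi("GRVIhyper", "Green ratio vegetation index (narrowband)",
          "rho(560)/rho(658)", "LCC", "EnMAP"),
    .mkVi("TCARI", "Transformed chlorophyll absorption ratio",
          "3*((rho(700)-rho(670))-0.2*(rho(700)-rho(550))*(rho(700)/rho(670)))",
          "LCC", "EnMAP"),
    .mkVi("TCI", "Triangular chlorophyll index",
          "1.2*(rho(700)-rho(550))-1.5*(rho(670)-rho(550))*sqrt(rho(700)/rho(670))",
          "LCC", "EnMAP",
          "canonical form with sqrt of the red-edge ratio"),
    ## --- water (LWC) ---
    .mkVi("MNDWI", "Modified normalized difference water index",
          "(GREEN-rho(1600))/(GREEN+rho(1600))", "LWC", all5,
          "SWIR term fixed at 1600 nm within the printed 1500-1700 window"),
    .mkVi("MSI", "Moisture stress index",
          "rho(1600)/rho(820)", "LWC", all5),
    .mkVi("SIWSI", "Shortwave infrared water stress index",
          "(rho(800)-rho(1640))/(rho(800)+rho(1640))", "LWC", all5),
    .mkVi("NDWI", "Normalized difference water index",
          "(rho(860)-rho(1240))/(rho(860)+rho(1240))", "LWC",
          c("MODIS", "Sentinel2", "Sentinel3", "EnMAP")),
    .mkVi("LWVI2", "Leaf water vegetation index 2",
          "(rho(1094)-rho(1205))/(rho(1094)+rho(1205))", "LWC",
          c("Sentinel3", "EnMAP")),
    .mkVi("LWVI2-SLSTR", "Leaf water vegetation index 2 (SWIR reading)",
          "(NIR-SWIR)/(NIR+SWIR)", "LWC", "Sentinel3",
          "role-based SWIR variant matching the SLSTR band usage"),
    .mkVi("DSWI", "Disease water stress index",
          "(rho(802)+rho(547))/(rho(1657)+rho(682))", "LWC", "EnMAP"),
    .mkVi("DSWI-1", "Disease water stress index 1",
          "rho(800)/rho(1660)", "LWC", "EnMAP"),
    .mkVi("LWVI1", "Leaf water vegetation index 1",
          "(rho(1094)-rho(983))/(rho(1094)+rho(983))", "LWC", "EnMAP"),
    .mkVi("NDII", "Normalized difference infrared index",
          "(rho(819)-rho(1649))/(rho(819)+rho(1649))", "LWC", "EnMAP"),
    .mkVi("WBI", "Water band index",
          "rho(970)/rho(902)", "LWC", "EnMAP"),
    .mkVi("WBI4", "Water band index 4",
          "rho(895)/rho(972)", "LWC", "EnMAP"),
    .mkVi("WC", "Water content index",
          "rho(1193)/rho(1126)", "LWC", "EnMAP"),
    .mkVi("WI", "Water index",
          "rho(900)/rho(970)", "LWC", "EnMAP"),
    .mkVi("Ratio1200", "Three-band ratio 1200",
          "2*rho(1205)/(rho(1095)+rho(1275))", "LWC", "EnMAP",
          "printed rho12755 read as rho1275"),
    ## --- leaf area (LAI) ---
    .mkVi("CTVI", "Corrected transformed vegetation index",
          ctvi, "LAI", all5,
          "sign(NDVI+0.5)*sqrt(|NDVI+0.5|) canonical reading"),
    .mkVi("DVI", "Difference vegetation index",
          "NIR-RED", "LAI", all5,
          "difference form; the source stacks NIR over RED"),
    .mkVi("EVI", "Enhanced vegetation index",
          "2.5*(NIR-RED)/((NIR+6*RED-7.5*BLUE)+1)", "LAI", all5),
    .mkVi("MSR", "Modified simple ratio",
          "(rho(800)-rho(445))/(rho(680)-rho(445))", "LAI", all5),
    .mkVi("NDVI", "Normalized difference vegetation index",
          ndvi, "LAI", all5),
    .mkVi("SLAVI", "Specific leaf area vegetation index",
          "NIR/(RED+SWIR)", "LAI", all5),
    .mkVi("WDRVI", "Wide dynamic range vegetation index",
          "(0.1*NIR-RED)/(0.1*NIR+RED)", "LAI", all5),
    .mkVi("DLAI", "Difference 1725/970 LAI index",
          "rho(1725)-rho(970)", "LAI", "EnMAP"),
    .mkVi("LAIDI", "LAI determining index (1250/1050)",
          "rho(1250)/rho(1050)", "LAI", "EnMAP")
  )
  names(defs) <- vapply(defs, function(d) d@abbreviation, character(1))
  .vigsa_cache$viRegistry <- defs
  defs
}

#' Registry of shipped vegetation indices
#'
#' Returns the built-in index definitions, optionally restricted to those
#' applicable to one sensor's band setting.
#'
#' @param sensor optional [Sensor-class] or sensor name.
#' @return named list of [VIDefinition-class] objects.
#' @examples
#' names(builtinRegistry("Landsat8"))
#' @export
builtinRegistry <- function(sensor = NULL) {
  defs <- .builtinViList()
  if (is.null(sensor)) return(defs)
  if (is.character(sensor)) sensor <- getSensor(sensor)
  Filter(function(d) sensor@name %in% d@applicableSensors, defs)
}

#' Tabulate available indices
#'
#' @param sensor optional sensor restriction (see [builtinRegistry()]).
#' @param target optional target-variable restriction ("LCC", "LWC",
#'   "LAI").
#' @return data.frame with columns `abbreviation`, `name`, `target`,
#'   `expression`, `sensors`.
#' @export
listIndices <- function(sensor = NULL, target = NULL) {
  defs <- builtinRegistry(sensor)
  if (!is.null(target))
    defs <- Filter(function(d) d@targetVariable == target, defs)
  data.frame(
    abbreviation = vapply(defs, function(d) d@abbreviation, character(1)),
    name = vapply(defs, function(d) d@name, character(1)),
    target = vapply(defs, function(d) d@targetVariable, character(1)),
    expression = vapply(defs, function(d) d@expression, character(1)),
    sensors = vapply(defs, function(d)
      paste(d@applicableSensors, collapse = ";"), character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
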