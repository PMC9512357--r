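#' Load a beam model from a configuration file
#'
#' Reads the structured-text beam-model format (key/value pairs plus
#' `[sources]`, `[fluence_profile]`, `[spectrum]` and `[scatter_factors]`
#' tables) and returns a validated [BeamModel-class].  The two packaged
#' models, `versahd_6mv.cfg` (flattened) and `versahd_6fff.cfg` (FFF), carry
#' the published dual-source parameter sets for a Versa HD-type 6 MV head.
#'
#' @param path path to a beam-model config file, or `NULL` to load the
#'   packaged model for `quality`.
#' @param quality `"flattened"` or `"FFF"`.  When `path` is given the file's
#'   own quality tag must match (if `quality` is supplied).
#' @return a [BeamModel-class] object.
#' @examples
#' bm <- loadBeamModel(quality = "flattened")
#' bm@sources
#' interpProfile(bm@fluenceProfile, 60)
#' @export
loadBeamModel <- function(path = NULL, quality = c("flattened", "FFF")) {
  if (is.null(path)) {
    quality <- match.arg(quality)
    fname <- if (quality == "flattened") "versahd_6mv.cfg" else "versahd_6fff.cfg"
    path <- system.file("extdata", fname, package = "vsmDose", mustWork = TRUE)
  }
  if (!file.exists(path)) stop("beam model file not found: ", path)
  cfg <- .parseConfig(path)

  qual <- cfg$scalars[["quality"]]
  if (is.null(qual)) stop("beam model config lacks a 'quality' entry")
  if (!qual %in% c("flattened", "FFF"))
    stop("unknown beam quality '", qual, "' (expected 'flattened' or 'FFF')")
  if (!missing(quality) && !is.null(quality)) {
    quality <- match.arg(quality)
    if (qual != quality)
      stop("requested quality '", quality, "' but file declares '", qual, "'")
  }

  geo <- .geometryFromConfig(cfg$sections[["geometry"]])

  src <- .sectionTable(cfg, "sources", c("position", "weight", "sigma_x", "sigma_y"))
  fp  <- .sectionTable(cfg, "fluence_profile", c("r", "phi"))
  sp  <- .sectionTable(cfg, "spectrum", c("energy", "intensity"))
  sf  <- .sectionTable(cfg, "scatter_factors", c("width", "factor"))

  bm <- new("BeamModel",
    quality = qual, geometry = geo, sources = src,
    fluenceProfile = fp, spectrum = sp, scatterFactors = sf,
    calibration = .scalarNum(cfg, "calibration"),
    mlcTransmission = .scalarNum(cfg, "mlc_transmission"))
  ok <- validObject(bm, test = TRUE)
  if (!isTRUE(ok)) stop("invalid beam model in '", path, "': ", paste(ok, collapse = "; "))
  bm
}

#' Write a beam model to a configuration file
#'
#' Serializes a [BeamModel-class] in the same structured-text dialect read by
#' [loadBeamModel()]; a write/read round trip preserves all parameter values.
#'
#' @param model a [BeamModel-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeBeamModel <- function(model, path) {
  stopifnot(is(model, "BeamModel"))
  g <- model@geometry
  lines <- c(
    "# vsmDose beam model",
    paste("quality", model@quality),
    paste("calibration", format(model@calibration, digits = 17)),
    paste("mlc_transmission", format(model@mlcTransmission, digits = 17)),
    "",
    "[geometry]",
    paste("source_to_isocenter_mm", format(g@sourceToIsocenter, digits = 17)),
    paste("phase_plane_mm", format(g@phasePlane, digits = 17)),
    paste("collimator_mm", format(g@collimator, digits = 17)),
    paste("grid_size_x", g@gridSize[1]),
    paste("grid_size_y", g@gridSize[2]),
    paste("grid_resolution_mm_x", format(g@gridResolution[1], digits = 17)),
    paste("grid_resolution_mm_y", format(g@gridResolution[2], digits = 17)),
    paste("grid_edge_mm_x", format(g@gridEdge[1], digits = 17)),
    paste("grid_edge_mm_y", format(g@gridEdge[2], digits = 17)),
    paste("fixed_x_jaw_mm", format(g@fixedXJaw, digits = 17)),
    paste("mlc_leaf_count", g@mlcLeafCount),
    paste("mlc_leaf_width_mm", format(g@mlcLeafWidth, digits = 17)),
    "",
    "[sources]",
    .tableLines(model@sources),
    "",
    "[fluence_profile]",
    .tableLines(model@fluenceProfile),
    "",
    "[spectrum]",
    .tableLines(model@spectrum),
    "",
    "[scatter_factors]",
    .tableLines(model@scatterFactors))
  writeLines(lines, path)
  invisible(path)
}

#' Piecewise-linear table lookup
#'
#' Linear interpolation of a two-column lookup table (fluence profile or
#' collimator scatter factor table) at arbitrary non-negative abscissae.
#' Beyond the last tabulated point the last value is returned (0 for fluence
#' profiles, which end at 0 by construction); below the first point the first
#' value is returned.
#'
#' @param table a data.frame whose first column is the abscissa (mm) and
#'   second column the value, as stored in a [BeamModel-class].
#' @param x query positions (mm), all >= 0.
#' @return interpolated values, same length as `x`.
#' @export
interpProfile <- function(table, x) {
  if (any(x < 0)) stop("interpProfile: query positions must be >= 0")
  if (length(x) == 0) return(numeric())
  approx(table[[1]], table[[2]], xout = x, rule = 2, ties = "ordered")$y
}

#' Collimator scatter factor for an aperture of open area A
#'
#' Looks up F at the equivalent square width sqrt(A) in the model's scatter
#' factor table (A in mm^2 at the isocenter plane).
#'
#' @param model a [BeamModel-class].
#' @param area open aperture area (mm^2).
#' @return scatter factor(s).
#' @export
scatterFactor <- function(model, area) {
  if (any(area < 0)) stop("aperture area must be >= 0")
  interpProfile(model@scatterFactors, sqrt(area))
}

## ---- config parsing internals -------------------------------------------

.parseConfig <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- sub("#.*$", "", raw)
  raw <- trimws(raw)
  raw <- raw[nzchar(raw)]
  scalars <- list(); sections <- list(); current <- NULL
  for (ln in raw) {
    if (grepl("^\\[.+\\]$", ln)) {
      current <- sub("^\\[(.+)\\]$", "\\1", ln)
      sections[[current]] <- character()
    } else if (is.null(current)) {
      kv <- strsplit(ln, "[[:space:]]+")[[1]]
      if (length(kv) != 2) stop("malformed config line: '", ln, "'")
      scalars[[kv[1]]] <- kv[2]
    } else {
      sections[[current]] <- c(sections[[current]], ln)
    }
  }
  list(scalars = scalars, sections = sections)
}

.scalarNum <- function(cfg, key) {
  v <- cfg$scalars[[key]]
  if (is.null(v)) stop("beam model config lacks required entry '", key, "'")
  out <- suppressWarnings(as.numeric(v))
  if (is.na(out)) stop("entry '", key, "' is not numeric: '", v, "'")
  out
}

.sectionTable <- function(cfg, name, colnames) {
  lines <- cfg$sections[[name]]
  if (is.null(lines) || !length(lines))
    stop("beam model config lacks table [", name, "]")
  rows <- lapply(lines, function(ln) {
    v <- suppressWarnings(as.numeric(strsplit(ln, "[[:space:]]+")[[1]]))
    if (length(v) != length(colnames) || anyNA(v))
      stop("malformed row in [", name, "]: '", ln, "'")
    v
  })
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- colnames
  df
}

.geometryFromConfig <- function(lines) {
  if (is.null(lines)) stop("beam model config lacks [geometry] section")
  kv <- list()
  for (ln in lines) {
    p <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(p) != 2) stop("malformed geometry line: '", ln, "'")
    kv[[p[1]]] <- as.numeric(p[2])
  }
  need <- function(key) {
    v <- kv[[key]]
    if (is.null(v) || is.na(v)) stop("geometry entry missing or non-numeric: ", key)
    v
  }
  new("MachineGeometry",
    sourceToIsocenter = need("source_to_isocenter_mm"),
    phasePlane        = need("phase_plane_mm"),
    collimator        = need("collimator_mm"),
    gridSize          = as.integer(c(need("grid_size_x"), need("grid_size_y"))),
    gridResolution    = c(need("grid_resolution_mm_x"), need("grid_resolution_mm_y")),
    gridEdge          = c(need("grid_edge_mm_x"), need("grid_edge_mm_y")),
    fixedXJaw         = need("fixed_x_jaw_mm"),
    mlcLeafCount      = as.integer(need("mlc_leaf_count")),
    mlcLeafWidth      = need("mlc_leaf_width_mm"))
}

.tableLines <- function(df) {
  apply(df, 1, function(row) paste(format(row, digits = 17, trim = TRUE), collapse = "  "))
}

#' Default machine geometry
#'
#' The packaged Versa HD-type geometry: 800 x 800 grid at 0.5 mm, edge at
#' -200 mm, phase-space plane at 548 mm, collimator at 401.8 mm, isocenter at
#' 1000 mm, fixed x-jaws at +/-200 mm, 160 leaves of 5 mm pitch.
#'
#' @return a [MachineGeometry-class].
#' @export
defaultGeometry <- function() {
  new("MachineGeometry",
    sourceToIsocenter = 1000, phasePlane = 548, collimator = 401.8,
    gridSize = c(800L, 800L), gridResolution = c(0.5, 0.5),
    gridEdge = c(-200, -200), fixedXJaw = 200,
    mlcLeafCount = 160L, mlcLeafWidth = 5)
}

#' @describeIn BeamModel-class beam quality tag accessor
#' @param object,x a `BeamModel`
#' @export
beamQuality <- function(x) {
  stopifnot(is(x, "BeamModel"))
  x@quality
}

setMethod("show", "BeamModel", function(object) {
  g <- object@geometry
  cat("BeamModel (", object@quality, ")\n", sep = "")
  cat("  sources:", nrow(object@sources), "on-axis Gaussian source(s)\n")
  for (i in seq_len(nrow(object@sources)))
    cat(sprintf("    #%d: z = %.1f mm, weight %.3f, sigma (%.2f, %.2f) mm\n",
                i, object@sources$position[i], object@sources$weight[i],
                object@sources$sigma_x[i], object@sources$sigma_y[i]))
  cat(sprintf("  grid: %d x %d at %.2f mm, plane at %.1f mm, collimator %.1f mm\n",
              g@gridSize[1], g@gridSize[2], g@gridResolution[1],
              g@phasePlane, g@collimator))
  cat(sprintf("  calibration C = %.3g, MLC transmission %.3g\n",
              object@calibration, object@mlcTransmission))
})

setMethod("show", "MachineGeometry", function(object) {
  cat(sprintf("MachineGeometry: d = %.1f, p = %.1f, c = %.1f mm; grid %d x %d @ %.2f mm\n",
              object@sourceToIsocenter, object@phasePlane, object@collimator,
              object@gridSize[1], object@gridSize[2], object@gridResolution[1]))
})
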