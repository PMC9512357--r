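#' Read a treatment plan from the structured-text plan format
#'
#' The plan dialect is line-oriented: scalar headers (`name`, `quality`,
#' `prescription`, `isocenter`), then one `beam` block per beam with a
#' `gantry` line and one `segment` block per segment carrying `mu`, `yjaws`
#' and the two per-leaf bank arrays (mm at the isocenter plane, IEC61217
#' axes).  See [writePlan()] for the writer; a write/read round trip
#' preserves the plan.
#'
#' @param path plan file path.
#' @param geometry a [MachineGeometry-class] fixing the expected leaf count.
#' @return a [Plan-class].
#' @export
readPlan <- function(path, geometry = defaultGeometry()) {
  if (!file.exists(path)) stop("plan file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  raw <- sub("#.*$", "", raw); raw <- trimws(raw); raw <- raw[nzchar(raw)]
  nPairs <- geometry@mlcLeafCount %/% 2L

  name <- "unnamed"; quality <- "flattened"; prescription <- 0
  iso <- c(0, 0, 0)
  beams <- list()
  curGantry <- NULL; curSegs <- list()
  seg <- NULL

  flushSeg <- function() {
    if (is.null(seg)) return()
    for (key in c("mu", "yjaws", "bankA", "bankB"))
      if (is.null(seg[[key]])) stop("segment lacks '", key, "' entry")
    if (length(seg$bankA) != nPairs || length(seg$bankB) != nPairs)
      stop("leaf-count mismatch: expected ", nPairs, " leaves per bank, got ",
           length(seg$bankA), " / ", length(seg$bankB))
    if (seg$yjaws[1] >= seg$yjaws[2])
      stop("crossed y-jaws: y1 must be < y2 (got ", seg$yjaws[1], " >= ", seg$yjaws[2], ")")
    ap <- tryCatch(
      aperture(seg$yjaws, seg$bankA, seg$bankB, seg$transmission %||% 0, geometry),
      error = function(e) stop("invalid segment aperture: ", conditionMessage(e)))
    curSegs[[length(curSegs) + 1L]] <<-
      segment(ap, seg$mu, gantryAngle = curGantry %||% 0)
    seg <<- NULL
  }
  flushBeam <- function() {
    flushSeg()
    if (is.null(curGantry) && !length(curSegs)) return()
    if (!length(curSegs)) stop("beam with no segments")
    beams[[length(beams) + 1L]] <<-
      new("Beam", gantryAngle = curGantry %||% 0, segments = curSegs)
    curSegs <<- list(); curGantry <<- NULL
  }

  for (ln in raw) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    key <- tok[1]; val <- tok[-1]
    num <- suppressWarnings(as.numeric(val))
    switch(key,
      name         = { name <- paste(val, collapse = " ") },
      quality      = { quality <- val[1] },
      prescription = { prescription <- num[1] },
      isocenter    = { iso <- num },
      beam         = { flushBeam() },
      gantry       = { curGantry <- num[1] },
      segment      = { flushSeg(); seg <- list() },
      mu           = { seg$mu <- num[1] },
      yjaws        = { seg$yjaws <- num },
      bankA        = { seg$bankA <- num },
      bankB        = { seg$bankB <- num },
      transmission = { seg$transmission <- num[1] },
      stop("unrecognized plan entry '", key, "'"))
    if (any(is.na(num)) && key %in% c("prescription", "isocenter", "gantry",
                                      "mu", "yjaws", "bankA", "bankB", "transmission"))
      stop("non-numeric value in plan entry '", key, "'")
  }
  flushBeam()
  if (!length(beams)) stop("plan contains no beams")
  pl <- new("Plan", name = name, quality = quality,
            prescriptionDose = prescription, isocenter = iso, beams = beams)
  validObject(pl)
  pl
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname readPlan
#' @param plan a [Plan-class].
#' @export
writePlan <- function(plan, path) {
  stopifnot(is(plan, "Plan"))
  fmt <- function(x) paste(format(x, digits = 17, trim = TRUE), collapse = " ")
  lines <- c("# vsmDose plan",
             paste("name", plan@name),
             paste("quality", plan@quality),
             paste("prescription", fmt(plan@prescriptionDose)),
             paste("isocenter", fmt(plan@isocenter)))
  for (b in plan@beams) {
    lines <- c(lines, "beam", paste("gantry", fmt(b@gantryAngle)))
    for (s in b@segments) {
      ap <- s@aperture
      lines <- c(lines, "segment",
                 paste("mu", fmt(s@mu)),
                 paste("yjaws", fmt(ap@yJaws)),
                 paste("bankA", fmt(ap@bankA)),
                 paste("bankB", fmt(ap@bankB)),
                 paste("transmission", fmt(ap@transmission)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Generate a benchmark fixture (plan + phantom)
#'
#' Deterministic synthetic test cases covering the benchmarking protocol:
#' \describe{
#'   \item{`square_field`}{one centered (or offset) square field on the
#'     300 mm water cube with the isocenter at 100 mm depth; parameters
#'     `width`, `offsetX`, `offsetY`, `mu`.}
#'   \item{`offset_field`}{alias of `square_field` (offsets required).}
#'   \item{`toy_prostate_imrt`}{7 equally spaced coplanar beams, 28
#'     step-and-shoot segments around a central target in a water cube.
#'     Segment shapes are synthetic: they match the beam/segment counts and
#'     MU scale of a prostate SABR plan, not any patient's apertures.}
#'   \item{`toy_lung_imrt`}{15 equally spaced coplanar beams, 30 segments,
#'     on a phantom with a low-density (0.26 g/cm^3) lung block surrounding
#'     a unit-density 20 mm target.  Synthetic in the same sense.}
#' }
#'
#' @param kind fixture kind (see above).
#' @param parameters named list of kind-specific parameters.
#' @param seed integer seed; fixtures are deterministic functions of
#'   (kind, parameters, seed).
#' @param geometry a [MachineGeometry-class].
#' @return list with elements `plan` ([Plan-class]) and `phantom`
#'   ([Phantom-class]).
#' @examples
#' fx <- generateFixture("toy_prostate_imrt", seed = 1)
#' fx$plan
#' @export
generateFixture <- function(kind, parameters = list(), seed = 1,
                            geometry = defaultGeometry()) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  p <- parameters
  switch(kind,
    square_field = ,
    offset_field = {
      width <- p$width %||% 100
      ox <- p$offsetX %||% 0; oy <- p$offsetY %||% 0
      mu <- p$mu %||% 100
      ap <- makeSquareField(width, ox, oy, geometry = geometry)
      plan <- new("Plan", name = sprintf("%s_w%g_x%g_y%g", kind, width, ox, oy),
                  quality = p$quality %||% "flattened",
                  prescriptionDose = 100, isocenter = c(0, 0, 0),
                  beams = list(new("Beam", gantryAngle = 0,
                                   segments = list(segment(ap, mu)))))
      list(plan = plan, phantom = waterPhantom())
    },
    toy_prostate_imrt = {
      nBeams <- 7; segsPer <- 4
      plan <- .toyImrtPlan("toy_prostate_imrt", p$quality %||% "flattened",
                           nBeams, segsPer, baseWidth = 60,
                           prescription = p$prescription %||% 3625,
                           geometry = geometry)
      list(plan = plan, phantom = waterPhantom(isocenterDepth = 150))
    },
    toy_lung_imrt = {
      nBeams <- 15; segsPer <- 2
      plan <- .toyImrtPlan("toy_lung_imrt", p$quality %||% "flattened",
                           nBeams, segsPer, baseWidth = 30,
                           prescription = p$prescription %||% 5400,
                           geometry = geometry)
      list(plan = plan, phantom = .lungPhantom())
    },
    stop("unknown fixture kind '", kind, "'"))
}

# step-and-shoot toy plan: per beam, a conformal base aperture plus smaller
# modulation segments with jittered leaf tips (deterministic via the caller's
# set.seed)
.toyImrtPlan <- function(name, quality, nBeams, segsPer, baseWidth,
                         prescription, geometry) {
  beams <- vector("list", nBeams)
  gantries <- (seq_len(nBeams) - 1) * 360 / nBeams
  for (b in seq_len(nBeams)) {
    segs <- vector("list", segsPer)
    for (s in seq_len(segsPer)) {
      w <- baseWidth * (1 - 0.15 * (s - 1) / max(1, segsPer - 1))
      ap0 <- makeSquareField(w, geometry = geometry)
      jit <- runif(length(ap0@bankA), 0, 0.2 * w)
      open <- ap0@bankB > ap0@bankA
      bankA <- ap0@bankA; bankB <- ap0@bankB
      bankA[open] <- pmin(bankA[open] + jit[open], bankB[open])  # leaf modulation
      ap <- aperture(ap0@yJaws, bankA, bankB, ap0@transmission, geometry)
      mu <- round(runif(1, 15, 40), 1)
      segs[[s]] <- segment(ap, mu, gantryAngle = gantries[b])
    }
    beams[[b]] <- new("Beam", gantryAngle = gantries[b], segments = segs)
  }
  new("Plan", name = name, quality = quality,
      prescriptionDose = prescription, isocenter = c(0, 0, 0), beams = beams)
}

# 300 mm cube: unit-density body, 120 mm low-density (0.26) lung block
# surrounding a 20 mm unit-density spherical target at the isocenter
.lungPhantom <- function(sideMM = 300, spacing = 2) {
  n <- as.integer(round(sideMM / spacing))
  ctr <- (seq_len(n) - 0.5) * spacing - sideMM / 2
  dens <- array(1, dim = c(n, n, n))
  inLung <- abs(ctr) <= 60
  dens[inLung, inLung, inLung] <- 0.26
  r2 <- outer(outer(ctr^2, ctr^2, "+"), ctr^2, "+")
  dens[r2 <= 10^2] <- 1.0
  phantomFromDensity(dens, spacing, origin = rep(-sideMM / 2, 3))
}

#' Write / read a dose grid as a plain-text container
#'
#' Documented text format: header lines (`dims`, `spacing`, `origin`,
#' `histories`, `units`) followed by the dose values and the uncertainty
#' values in x-fastest order, `%.17g` formatted so a write/read round trip
#' is bit-identical.
#'
#' @param dose a [DoseGrid-class].
#' @param path output file.
#' @return `path` invisibly (`writeDose`); a [DoseGrid-class] (`readDose`).
#' @export
writeDose <- function(dose, path) {
  stopifnot(is(dose, "DoseGrid"))
  con <- file(path, "w")
  on.exit(close(con))
  d <- dim(dose@dose)
  writeLines(c("# vsmDose dose grid",
               paste("dims", paste(d, collapse = " ")),
               paste("spacing", paste(sprintf("%.17g", dose@spacing), collapse = " ")),
               paste("origin", paste(sprintf("%.17g", dose@origin), collapse = " ")),
               paste("histories", sprintf("%.17g", dose@histories)),
               paste("units", dose@units),
               "dose"), con)
  writeLines(sprintf("%.17g", as.numeric(dose@dose)), con)
  writeLines("uncertainty", con)
  writeLines(sprintf("%.17g", as.numeric(dose@uncertainty)), con)
  invisible(path)
}

#' @rdname writeDose
#' @export
readDose <- function(path) {
  if (!file.exists(path)) stop("dose file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[!grepl("^#", raw)]
  getv <- function(key) {
    ln <- raw[grepl(paste0("^", key, " "), raw)][1]
    strsplit(ln, "[[:space:]]+")[[1]][-1]
  }
  dims <- as.integer(getv("dims"))
  spacing <- as.numeric(getv("spacing"))
  origin <- as.numeric(getv("origin"))
  histories <- as.numeric(getv("histories"))
  units <- getv("units")[1]
  iDose <- which(raw == "dose")[1]; iUnc <- which(raw == "uncertainty")[1]
  nv <- prod(dims)
  doseV <- as.numeric(raw[(iDose + 1):(iDose + nv)])
  uncV <- as.numeric(raw[(iUnc + 1):(iUnc + nv)])
  new("DoseGrid", dose = array(doseV, dims), uncertainty = array(uncV, dims),
      spacing = spacing, origin = origin, histories = histories, units = units)
}
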