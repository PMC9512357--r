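#' Convert Hounsfield numbers to density and material
#'
#' Stoichiometric-style CT conversion: Hounsfield number to relative electron
#' density by piecewise-linear interpolation of a calibration table, relative
#' electron density to physical density through the empirical linear formula
#' stated in the calibration file, and material assignment by physical
#' density range.  Values below the table minimum clamp to air.
#'
#' @param hu vector of Hounsfield numbers.
#' @param calibration path to a calibration config (default: the packaged
#'   synthetic curve `hu_calibration.cfg`), or a parsed calibration list.
#' @return data.frame with columns `density` (g/cm^3), `material` (index:
#'   1 water, 2 air, 3 lung, 4 bone) and `materialName`.
#' @export
huToDensity <- function(hu, calibration = NULL) {
  cal <- .loadHuCalibration(calibration)
  if (any(diff(cal$table$hu) <= 0)) stop("HU calibration table must be monotone in HU")
  red <- approx(cal$table$hu, cal$table$red, xout = hu, rule = 2)$y
  rho <- pmax(0, cal$a * red + cal$b)
  mat <- .materialFromDensity(rho, cal$ranges)
  data.frame(density = rho, material = mat,
             materialName = .MATERIALS[mat])
}

.loadHuCalibration <- function(calibration = NULL) {
  if (is.list(calibration)) return(calibration)
  path <- if (is.null(calibration))
    system.file("extdata", "hu_calibration.cfg", package = "vsmDose", mustWork = TRUE)
  else calibration
  cfg <- .parseConfig(path)
  tab <- .sectionTable(cfg, "hu_to_red", c("hu", "red"))
  rng <- cfg$sections[["material_ranges"]]
  parts <- lapply(rng, function(ln) strsplit(ln, "[[:space:]]+")[[1]])
  ranges <- data.frame(
    material = vapply(parts, `[`, "", 1),
    lo = as.numeric(vapply(parts, `[`, "", 2)),
    hi = as.numeric(vapply(parts, `[`, "", 3)))
  list(a = .scalarNum(cfg, "density_a"), b = .scalarNum(cfg, "density_b"),
       table = tab, ranges = ranges)
}

.materialFromDensity <- function(rho, ranges = NULL) {
  if (is.null(ranges))
    ranges <- data.frame(material = c("air", "lung", "water", "bone"),
                         lo = c(0, 0.05, 0.70, 1.25), hi = c(0.05, 0.70, 1.25, 99))
  out <- integer(length(rho))
  for (k in seq_len(nrow(ranges))) {
    idx <- match(ranges$material[k], .MATERIALS)
    sel <- rho >= ranges$lo[k] & rho < ranges$hi[k]
    out[sel] <- idx
  }
  out[out == 0L] <- match("water", .MATERIALS)
  out
}

#' Homogeneous water-cube phantom
#'
#' The standard benchmarking phantom: a 300 mm water cube at unit density,
#' 2 mm isotropic voxels, positioned in the room frame with the beam entry
#' face at z = -100 mm so that the isocenter (origin) lies at 100 mm depth
#' for a gantry-zero beam.
#'
#' @param sideMM cube side (mm).
#' @param spacing voxel size (mm, isotropic).
#' @param isocenterDepth depth of the isocenter below the entry face (mm).
#' @return a [Phantom-class].
#' @export
waterPhantom <- function(sideMM = 300, spacing = 2, isocenterDepth = 100) {
  n <- as.integer(round(sideMM / spacing))
  dens <- array(1, dim = c(n, n, n))
  mat <- array(match("water", .MATERIALS), dim = c(n, n, n))
  new("Phantom", density = dens, material = mat,
      spacing = rep(spacing, 3),
      origin = c(-sideMM / 2, -sideMM / 2, -isocenterDepth))
}

#' Build a phantom from a density grid
#'
#' Materials are assigned from the density via the packaged density ranges.
#'
#' @param density 3-D array of physical density (g/cm^3).
#' @param spacing voxel size (mm), length 1 or 3.
#' @param origin room-frame corner position (mm).
#' @return a [Phantom-class].
#' @export
phantomFromDensity <- function(density, spacing, origin) {
  mat <- array(.materialFromDensity(as.vector(density)), dim = dim(density))
  new("Phantom", density = density, material = mat,
      spacing = rep(spacing, length.out = 3), origin = origin)
}

#' Transform beam-frame particles into the room frame
#'
#' The beam frame has its origin at the nominal source with +z along the
#' beam axis toward the patient.  The room frame has its origin at the
#' isocenter; at gantry zero the two frames differ only by the shift d along
#' z.  The gantry rotates the beam about the room y-axis.
#'
#' @param particles data.frame from [sampleParticles()].
#' @param gantryAngle gantry angle (degrees).
#' @param isocenter isocenter position in the room frame (mm).
#' @param d source-to-isocenter distance (mm).
#' @return the particle data.frame with room-frame positions/directions.
#' @export
transformParticles <- function(particles, gantryAngle = 0,
                               isocenter = c(0, 0, 0), d = 1000) {
  g <- gantryAngle * pi / 180
  cg <- cos(g); sg <- sin(g)
  x <- particles$x; y <- particles$y; z <- particles$z - d
  particles$x <- cg * x + sg * z + isocenter[1]
  particles$y <- y + isocenter[2]
  particles$z <- -sg * x + cg * z + isocenter[3]
  u <- particles$u; w <- particles$w
  particles$u <- cg * u + sg * w
  particles$w <- -sg * u + cg * w
  particles
}

#' Monte Carlo dose simulation
#'
#' Transports a photon particle stream through a voxel phantom with the
#' simplified engine (Woodcock tracking; Compton, photoelectric and pair
#' interactions; straight-line continuous-slowing-down electrons with
#' Gaussian angular diffusion) and scores energy deposited per voxel.
#' Histories are run in batches; the per-voxel relative statistical
#' uncertainty is estimated from the batch-to-batch variance.  The run stops
#' when the mean relative uncertainty over voxels above 50% of the current
#' maximum dose reaches `targetUncertainty`, or when `maxHistories` have been
#' transported.
#'
#' The returned dose is the accumulated dose over all histories in
#' per-history (unnormalized) units; apply [scaleDose()] with the beam's
#' integral fluence to obtain absolute dose.
#'
#' @param particles either a data.frame of particle records (beam frame; see
#'   [sampleParticles()]) or a generator `function(n, seed)` returning such a
#'   data.frame.
#' @param phantom a [Phantom-class].
#' @param targetUncertainty target mean relative uncertainty (e.g. 0.015),
#'   or `NULL` to run exactly `maxHistories`.
#' @param maxHistories history cap (required when `particles` is a
#'   generator).
#' @param batchSize histories per batch (and per uncertainty sample).
#' @param seed integer seed (also used to derive per-batch generator seeds).
#' @param gantryAngle,isocenter beam orientation used to transform particles
#'   into the room frame.
#' @param d source-to-isocenter distance (mm).
#' @param eCutPhoton,eCutElectron transport cutoffs (MeV); below them energy
#'   is deposited locally.
#' @param eStep electron step length (mm).
#' @return a [DoseGrid-class] in per-history units with `histories` set.
#' @export
simulateDose <- function(particles, phantom,
                         targetUncertainty = NULL, maxHistories = NULL,
                         batchSize = 250000, seed = 1,
                         gantryAngle = 0, isocenter = c(0, 0, 0), d = 1000,
                         eCutPhoton = 0.05, eCutElectron = 0.2, eStep = 1.0) {
  stopifnot(is(phantom, "Phantom"))
  if (!is.null(targetUncertainty) && targetUncertainty <= 0)
    stop("target uncertainty must be positive")
  isGen <- is.function(particles)
  if (!isGen) {
    if (!NROW(particles)) stop("empty particle stream")
    maxHistories <- nrow(particles)
  } else if (is.null(maxHistories)) {
    stop("maxHistories is required with a particle generator")
  }

  ph <- .getPhysics()
  dims <- dim(phantom@density)
  nvox <- prod(dims)
  voxMassG <- phantom@density * prod(phantom@spacing) / 1000  # g (rho * cm^3)

  total <- numeric(nvox)
  total2 <- numeric(nvox)
  nBatch <- 0L
  H <- 0
  repeat {
    nTake <- min(batchSize, maxHistories - H)
    if (nTake <= 0) break
    batchSeed <- (seed + 7919 * (nBatch + 1L)) %% 2147483647
    if (isGen) {
      part <- particles(nTake, batchSeed)
    } else {
      part <- particles[(H + 1):(H + nTake), , drop = FALSE]
    }
    part <- transformParticles(part, gantryAngle, isocenter, d)
    pm <- as.matrix(part[, c("x", "y", "z", "u", "v", "w", "energy")])
    res <- .cppTransport(pm, as.numeric(phantom@density),
                         as.integer(phantom@material),
                         as.integer(dims), phantom@spacing,
                         phantom@origin,
                         ph$energy, ph$muTot, ph$fPE, ph$fPair,
                         ph$stopPow, ph$X0, batchSeed,
                         eCutPhoton, eCutElectron, eStep, FALSE)
    bdose <- res$edep / pmax(as.vector(voxMassG), 1e-30)  # MeV/g
    total <- total + bdose
    total2 <- total2 + bdose^2
    nBatch <- nBatch + 1L
    H <- H + nTake
    if (!is.null(targetUncertainty) && nBatch >= 3) {
      unc <- .batchUncertainty(total, total2, nBatch)
      hot <- total >= 0.5 * max(total)
      if (mean(unc[hot], na.rm = TRUE) <= targetUncertainty) break
    }
    if (H >= maxHistories) break
  }

  unc <- .batchUncertainty(total, total2, nBatch)
  new("DoseGrid",
      dose = array(total, dims),
      uncertainty = array(unc, dims),
      spacing = phantom@spacing, origin = phantom@origin,
      histories = H, units = "per-history")
}

# relative standard error of a voxel total from per-batch sums
.batchUncertainty <- function(total, total2, nBatch) {
  if (nBatch < 2) return(rep(NA_real_, length(total)))
  meanB <- total / nBatch
  varB <- pmax(0, total2 / nBatch - meanB^2) / (nBatch - 1)
  out <- rep(NA_real_, length(total))
  pos <- total > 0
  out[pos] <- sqrt(varB[pos]) * nBatch / (total[pos] * sqrt(nBatch))
  out
}

#' Scale a simulated dose to absolute units
#'
#' Multiplies every voxel by `integralFluence / histories`: the division by
#' the number of transported histories converts the accumulated dose to dose
#' per particle, and the integral fluence rescales it to the particle count
#' implied by the monitor units and calibration of the beam.
#'
#' @param dose a per-history [DoseGrid-class] from [simulateDose()].
#' @param integralFluence the beam's masked integral fluence
#'   ([integralFluence()] of its phase-space map).
#' @param histories number of transported histories (default: from `dose`).
#' @return an absolute-dose [DoseGrid-class].
#' @export
scaleDose <- function(dose, integralFluence, histories = dose@histories) {
  stopifnot(is(dose, "DoseGrid"))
  if (is.null(histories) || histories == 0) stop("histories must be > 0")
  dose@dose <- dose@dose * (integralFluence / histories)
  dose@units <- "cGy"
  dose
}

#' Median-window filter of a dose grid
#'
#' Replaces each voxel by the median over the cubic neighborhood of the
#' given radius (clipped at the grid boundary), the paper-style statistical
#' noise filter: radius 3 for standard fields, radius 1 for very small
#' fields, radius 0 is the identity.  The uncertainty grid is passed through
#' unchanged.
#'
#' @param dose a [DoseGrid-class].
#' @param radius neighborhood radius in voxels (non-negative integer).
#' @return the filtered [DoseGrid-class].
#' @export
medianFilterDose <- function(dose, radius = 3) {
  stopifnot(is(dose, "DoseGrid"))
  if (radius < 0 || radius != round(radius)) stop("radius must be a non-negative integer")
  dims <- dim(dose@dose)
  filt <- .cppMedianFilter(as.numeric(dose@dose), as.integer(dims), as.integer(radius))
  dose@dose <- array(filt, dims)
  dose
}

#' Full dose pipeline for one beam
#'
#' Convenience wrapper running phase-space composition, particle sampling,
#' Monte Carlo transport and absolute dose scaling for a single beam.
#'
#' @param model a [BeamModel-class].
#' @param beam a [Beam-class], [Segment-class] or list of segments.
#' @param phantom a [Phantom-class].
#' @param histories number of histories (or cap when `targetUncertainty`
#'   is given).
#' @param seed integer seed.
#' @param targetUncertainty optional mean relative uncertainty target.
#' @param filterRadius median filter radius applied to the scaled dose
#'   (`NULL` to skip filtering).
#' @param isocenter room-frame isocenter (mm).
#' @param ... further arguments to [simulateDose()].
#' @return an absolute-dose [DoseGrid-class].
#' @export
computeBeamDose <- function(model, beam, phantom, histories, seed = 1,
                            targetUncertainty = NULL, filterRadius = NULL,
                            isocenter = c(0, 0, 0), ...) {
  ps <- computePhaseSpace(model, beam)
  gantry <- if (is(beam, "Beam")) beam@gantryAngle
            else if (is(beam, "Segment")) beam@gantryAngle
            else beam[[1]]@gantryAngle
  gen <- function(n, s) sampleParticles(ps, model, n, s)
  dg <- simulateDose(gen, phantom, targetUncertainty = targetUncertainty,
                     maxHistories = histories, seed = seed,
                     gantryAngle = gantry, isocenter = isocenter,
                     d = model@geometry@sourceToIsocenter, ...)
  dg <- scaleDose(dg, ps@integralFluence)
  if (!is.null(filterRadius)) dg <- medianFilterDose(dg, filterRadius)
  dg
}

#' Full dose pipeline for a plan
#'
#' Runs [computeBeamDose()] for every beam of a plan (histories allocated
#' proportionally to each beam's integral fluence) and sums the scaled dose
#' grids; per-voxel uncertainties combine in quadrature weighted by each
#' beam's dose.
#'
#' @param model a [BeamModel-class].
#' @param plan a [Plan-class].
#' @param phantom a [Phantom-class].
#' @param histories total histories over all beams.
#' @param seed integer seed.
#' @param filterRadius median filter radius applied to the summed dose.
#' @param ... further arguments to [simulateDose()].
#' @return an absolute-dose [DoseGrid-class].
#' @export
computePlanDose <- function(model, plan, phantom, histories, seed = 1,
                            filterRadius = 3, ...) {
  stopifnot(is(plan, "Plan"))
  ints <- vapply(plan@beams, function(b)
    computePhaseSpace(model, b)@integralFluence, 0)
  hAlloc <- pmax(1000, round(histories * ints / sum(ints)))
  doseSum <- NULL; varSum <- NULL
  for (k in seq_along(plan@beams)) {
    dg <- computeBeamDose(model, plan@beams[[k]], phantom,
                          histories = hAlloc[k], seed = seed + k,
                          isocenter = plan@isocenter, ...)
    dd <- dg@dose
    vv <- ifelse(is.na(dg@uncertainty), 0, (dg@uncertainty * dd)^2)
    if (is.null(doseSum)) { doseSum <- dd; varSum <- vv }
    else { doseSum <- doseSum + dd; varSum <- varSum + vv }
  }
  unc <- array(NA_real_, dim(doseSum))
  pos <- doseSum > 0
  unc[pos] <- sqrt(varSum[pos]) / doseSum[pos]
  out <- new("DoseGrid", dose = doseSum, uncertainty = unc,
             spacing = phantom@spacing, origin = phantom@origin,
             histories = sum(hAlloc), units = "cGy")
  if (!is.null(filterRadius)) out <- medianFilterDose(out, filterRadius)
  out
}

#' @rdname DoseGrid-class
#' @param x a `DoseGrid`
#' @export
doseArray <- function(x) { stopifnot(is(x, "DoseGrid")); x@dose }

#' @rdname DoseGrid-class
#' @export
uncertaintyArray <- function(x) { stopifnot(is(x, "DoseGrid")); x@uncertainty }

setMethod("show", "Phantom", function(object) {
  d <- dim(object@density)
  cat(sprintf("Phantom: %d x %d x %d voxels at (%.1f, %.1f, %.1f) mm, density %.3g-%.3g g/cm^3\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2], object@spacing[3],
              min(object@density), max(object@density)))
})

setMethod("show", "DoseGrid", function(object) {
  d <- dim(object@dose)
  cat(sprintf("DoseGrid (%s): %d x %d x %d voxels, max %.4g, %g histories\n",
              object@units, d[1], d[2], d[3], max(object@dose), object@histories))
})
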