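#' @import methods
#' @importFrom stats fft mvfft approx rnorm runif median quantile sd setNames
#' @importFrom utils read.table write.table packageVersion
#' @useDynLib vsmDose, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Machine geometry of the accelerator head
#'
#' Source-independent geometry of the head model: distances of the isocenter,
#' phase-space plane and collimator from the nominal source, the fluence grid
#' definition at the isocenter plane, and the MLC/jaw layout.  All distances
#' are in mm, measured along +z from the nominal source toward the patient.
#'
#' @slot sourceToIsocenter distance d from nominal source to isocenter (mm).
#' @slot phasePlane distance p of the phase-space plane from the source (mm).
#' @slot collimator distance c of the collimator (bottom of MLC leaves) from
#'   the source (mm).
#' @slot gridSize integer vector (I, J): grid points in x and y.
#' @slot gridResolution (dx, dy) grid spacing at the isocenter plane (mm).
#' @slot gridEdge (gx, gy) coordinate of grid point (0, 0) at isocenter (mm).
#' @slot fixedXJaw half-width of the fixed x-jaws at isocenter (mm).
#' @slot mlcLeafCount total number of leaves (two opposed banks).
#' @slot mlcLeafWidth leaf width (pitch) projected to isocenter (mm).
#' @export
setClass("MachineGeometry", representation(
  sourceToIsocenter = "numeric",
  phasePlane        = "numeric",
  collimator        = "numeric",
  gridSize          = "integer",
  gridResolution    = "numeric",
  gridEdge          = "numeric",
  fixedXJaw         = "numeric",
  mlcLeafCount      = "integer",
  mlcLeafWidth      = "numeric"
))

setValidity("MachineGeometry", function(object) {
  msg <- character()
  d <- object@sourceToIsocenter; p <- object@phasePlane; cc <- object@collimator
  if (!(length(d) == 1 && length(p) == 1 && length(cc) == 1))
    msg <- c(msg, "d, p, c must be scalars")
  else if (!(0 < cc && cc < p && p < d))
    msg <- c(msg, "geometry must satisfy 0 < collimator < phase plane < isocenter distance")
  if (any(object@gridSize <= 0L)) msg <- c(msg, "grid size must be positive")
  if (any(object@gridResolution <= 0)) msg <- c(msg, "grid resolution must be positive")
  if (object@mlcLeafCount <= 0L || object@mlcLeafCount %% 2L != 0L)
    msg <- c(msg, "mlcLeafCount must be a positive even number")
  if (object@mlcLeafWidth <= 0) msg <- c(msg, "mlcLeafWidth must be positive")
  if (length(msg)) msg else TRUE
})

#' Beam model for one beam quality
#'
#' Container for every head-model parameter of one beam quality: the virtual
#' sources on the beam axis, the primary fluence profile, the energy spectrum,
#' the collimator scatter factor table, the absolute calibration factor and
#' the MLC transmission.  Use [loadBeamModel()] to construct one from a
#' configuration file; packaged models reproduce the published flattened and
#' FFF parameter sets.
#'
#' @slot quality `"flattened"` or `"FFF"`.
#' @slot geometry a [MachineGeometry-class].
#' @slot sources data.frame with columns `position` (mm from nominal source),
#'   `weight` (relative), `sigma_x`, `sigma_y` (mm, source Gaussian widths).
#' @slot fluenceProfile data.frame `r` (off-axis mm at isocenter), `phi`.
#' @slot spectrum data.frame `energy` (MeV), `intensity` (relative).
#' @slot scatterFactors data.frame `width` (square field width mm), `factor`.
#' @slot calibration absolute calibration factor C (particles per MU mm^2).
#' @slot mlcTransmission MLC transmission in [0, 1).
#' @export
setClass("BeamModel", representation(
  quality         = "character",
  geometry        = "MachineGeometry",
  sources         = "data.frame",
  fluenceProfile  = "data.frame",
  spectrum        = "data.frame",
  scatterFactors  = "data.frame",
  calibration     = "numeric",
  mlcTransmission = "numeric"
))

setValidity("BeamModel", function(object) {
  msg <- character()
  if (!object@quality %in% c("flattened", "FFF"))
    msg <- c(msg, "quality must be 'flattened' or 'FFF'")
  s <- object@sources
  if (!all(c("position", "weight", "sigma_x", "sigma_y") %in% names(s)))
    msg <- c(msg, "sources must have columns position, weight, sigma_x, sigma_y")
  else {
    if (any(s$position < 0) || any(s$position >= object@geometry@collimator))
      msg <- c(msg, "source positions must lie in [0, collimator)")
    if (any(s$weight <= 0)) msg <- c(msg, "source weights must be positive")
    if (any(s$sigma_x <= 0) || any(s$sigma_y <= 0))
      msg <- c(msg, "source widths must be positive")
  }
  fp <- object@fluenceProfile
  if (nrow(fp) < 2 || fp$r[1] != 0 || any(diff(fp$r) <= 0))
    msg <- c(msg, "fluence_profile off-axis positions must be strictly increasing from 0")
  else {
    if (any(fp$phi < 0)) msg <- c(msg, "fluence_profile intensities must be >= 0")
    if (fp$phi[nrow(fp)] != 0)
      msg <- c(msg, "fluence_profile must fall to 0 at its last off-axis position")
  }
  sp <- object@spectrum
  if (nrow(sp) < 1 || any(diff(sp$energy) <= 0))
    msg <- c(msg, "spectrum energies must be strictly increasing")
  else if (any(sp$intensity <= 0))
    msg <- c(msg, "spectrum intensities must be positive")
  sf <- object@scatterFactors
  if (nrow(sf) < 2 || any(diff(sf$width) <= 0))
    msg <- c(msg, "scatter_factors field widths must be strictly increasing")
  else {
    f100 <- sf$factor[match(100, sf$width)]
    if (is.na(f100) || abs(f100 - 1) > 1e-9)
      msg <- c(msg, "scatter_factors must contain F(100 mm) = 1.000 (normalization rule)")
    if (any(sf$factor <= 0)) msg <- c(msg, "scatter factors must be positive")
  }
  if (length(object@calibration) != 1 || object@calibration <= 0)
    msg <- c(msg, "calibration C must be a positive scalar")
  if (object@mlcTransmission < 0 || object@mlcTransmission >= 1)
    msg <- c(msg, "mlcTransmission must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Beam aperture at the isocenter plane
#'
#' One segment's collimation: y-jaw positions and per-leaf tip positions of
#' the two opposed MLC banks, all expressed in mm at the isocenter plane
#' (IEC61217 x/y axes).  Leaves travel in x; leaf pair `l` (1-based) covers
#' the y-band `[-200 + 5 (l - 1), -200 + 5 l)` for the default 80-pair,
#' 5 mm-pitch MLC.  Intervals are half-open `[low, high)` so every point
#' belongs to exactly one leaf pair.
#'
#' @slot yJaws numeric(2), (y1, y2) with y1 < y2 (mm at isocenter).
#' @slot bankA per-leaf tip positions of bank A (lower x side) (mm).
#' @slot bankB per-leaf tip positions of bank B (upper x side) (mm).
#' @slot transmission fluence weight outside the opening (MLC transmission).
#' @export
setClass("Aperture", representation(
  yJaws        = "numeric",
  bankA        = "numeric",
  bankB        = "numeric",
  transmission = "numeric"
))

setValidity("Aperture", function(object) {
  msg <- character()
  if (length(object@yJaws) != 2 || object@yJaws[1] >= object@yJaws[2])
    msg <- c(msg, "y-jaws must satisfy y1 < y2")
  if (length(object@bankA) != length(object@bankB))
    msg <- c(msg, "leaf banks must have equal length")
  else if (any(object@bankA > object@bankB))
    msg <- c(msg, "bank A tip must not exceed bank B tip for any leaf pair")
  lim <- 200 + 1e-9
  if (any(abs(c(object@yJaws, object@bankA, object@bankB)) > lim))
    msg <- c(msg, "jaw and leaf positions must lie within +/-200 mm")
  if (object@transmission < 0 || object@transmission >= 1)
    msg <- c(msg, "transmission must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Treatment beam segment
#'
#' An [Aperture-class] plus the monitor units delivered through it and the
#' machine angles at which it is delivered.
#'
#' @slot aperture the collimation.
#' @slot mu monitor units M (> 0).
#' @slot gantryAngle gantry angle (degrees).
#' @slot collimatorAngle collimator angle (degrees, default 0; only 0 is
#'   modeled by the transport pipeline).
#' @export
setClass("Segment", representation(
  aperture        = "Aperture",
  mu              = "numeric",
  gantryAngle     = "numeric",
  collimatorAngle = "numeric"
))

setValidity("Segment", function(object) {
  if (length(object@mu) != 1 || object@mu <= 0) "monitor units must be > 0" else TRUE
})

#' Treatment beam: segments sharing one gantry angle
#' @slot gantryAngle gantry angle (degrees), shared by all segments.
#' @slot segments list of [Segment-class].
#' @export
setClass("Beam", representation(
  gantryAngle = "numeric",
  segments    = "list"
))

setValidity("Beam", function(object) {
  if (length(object@segments) < 1) return("beam must contain at least one segment")
  if (!all(vapply(object@segments, is, TRUE, class2 = "Segment")))
    return("segments must be Segment objects")
  g <- vapply(object@segments, function(s) s@gantryAngle, 0)
  if (any(abs(g - object@gantryAngle) > 1e-9))
    return("all segments of a beam must share its gantry angle")
  TRUE
})

#' Treatment plan
#' @slot name plan name.
#' @slot quality beam quality tag ("flattened" or "FFF").
#' @slot prescriptionDose prescription dose (cGy; used as gamma normalization).
#' @slot isocenter isocenter position (mm, room frame).
#' @slot beams list of [Beam-class].
#' @export
setClass("Plan", representation(
  name             = "character",
  quality          = "character",
  prescriptionDose = "numeric",
  isocenter        = "numeric",
  beams            = "list"
))

setValidity("Plan", function(object) {
  if (length(object@beams) < 1) return("plan must contain at least one beam")
  if (!all(vapply(object@beams, is, TRUE, class2 = "Beam")))
    return("beams must be Beam objects")
  mu <- sum(vapply(object@beams, function(b)
    sum(vapply(b@segments, function(s) s@mu, 0)), 0))
  if (mu <= 0) return("total MU must be > 0")
  if (length(object@isocenter) != 3) return("isocenter must be length 3")
  TRUE
})

#' Per-source fluence maps at the phase-space plane
#'
#' Calibrated fluence grids for one beam (summed over its segments), one grid
#' per virtual source, together with the 1%-of-maximum inclusion mask, the
#' per-source plane spacing and the integral fluence used for absolute dose
#' scaling.  Built by [computePhaseSpace()]; consumed by [sampleParticles()].
#'
#' @slot fluence list of I x J matrices, one per source (particle content per
#'   grid cell).
#' @slot mask list of logical matrices: cells retained by the 1% cutoff.
#' @slot sources source table of the generating beam model.
#' @slot geometry the [MachineGeometry-class].
#' @slot planeSpacing n x 2 matrix of (dx, dy) cell spacing at the
#'   phase-space plane for each source (mm).
#' @slot sourceIntegrals masked integral per source.
#' @slot integralFluence total masked integral (sum over sources).
#' @slot maskThreshold absolute threshold used for the mask.
#' @slot quality beam quality tag.
#' @export
setClass("PhaseSpaceMap", representation(
  fluence         = "list",
  mask            = "list",
  sources         = "data.frame",
  geometry        = "MachineGeometry",
  planeSpacing    = "matrix",
  sourceIntegrals = "numeric",
  integralFluence = "numeric",
  maskThreshold   = "numeric",
  quality         = "character"
))

setValidity("PhaseSpaceMap", function(object) {
  msg <- character()
  if (length(object@fluence) != nrow(object@sources))
    msg <- c(msg, "one fluence grid per source required")
  if (any(vapply(object@fluence, function(m) any(m < 0), TRUE)))
    msg <- c(msg, "fluence must be non-negative everywhere")
  if (length(object@mask) != length(object@fluence))
    msg <- c(msg, "one mask per fluence grid required")
  if (length(msg)) msg else TRUE
})

#' Voxel phantom
#'
#' Axis-aligned voxel grid of physical density and material index in the room
#' frame (isocenter at the origin; +z along the gantry-zero beam direction).
#' Materials are coded 1 = water, 2 = air, 3 = lung, 4 = bone.
#'
#' @slot density 3-D array of physical density (g/cm^3).
#' @slot material 3-D integer array of material indices (same dim).
#' @slot spacing voxel size (mm), length 3.
#' @slot origin room-frame position of the corner of voxel (1,1,1) (mm).
#' @export
setClass("Phantom", representation(
  density  = "array",
  material = "array",
  spacing  = "numeric",
  origin   = "numeric"
))

setValidity("Phantom", function(object) {
  msg <- character()
  if (length(dim(object@density)) != 3) msg <- c(msg, "density must be a 3-D array")
  if (any(object@density < 0)) msg <- c(msg, "densities must be >= 0")
  if (!identical(dim(object@density), dim(object@material)))
    msg <- c(msg, "material array must match density dimensions")
  if (length(object@spacing) != 3 || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive values")
  if (length(object@origin) != 3) msg <- c(msg, "origin must be length 3")
  if (length(msg)) msg else TRUE
})

#' Voxel dose grid
#'
#' Absorbed dose on the phantom voxel grid plus a per-voxel relative
#' statistical uncertainty estimated from history batches.  Dose is in
#' per-history units straight out of [simulateDose()] and in absolute units
#' (cGy scale) after [scaleDose()].
#'
#' @slot dose 3-D dose array.
#' @slot uncertainty 3-D array of relative standard errors (NA where dose 0).
#' @slot spacing voxel size (mm).
#' @slot origin room-frame corner position (mm).
#' @slot histories number of particle histories transported.
#' @slot units `"per-history"` or `"cGy"`.
#' @export
setClass("DoseGrid", representation(
  dose        = "array",
  uncertainty = "array",
  spacing     = "numeric",
  origin      = "numeric",
  histories   = "numeric",
  units       = "character"
))

setValidity("DoseGrid", function(object) {
  msg <- character()
  if (length(dim(object@dose)) != 3) msg <- c(msg, "dose must be a 3-D array")
  if (any(object@dose < 0)) msg <- c(msg, "dose must be >= 0")
  if (!identical(dim(object@dose), dim(object@uncertainty)))
    msg <- c(msg, "uncertainty array must match dose dimensions")
  if (length(msg)) msg else TRUE
})

#' Output factor result
#' @slot factor dose ratio test/reference at the measurement point.
#' @slot testDose,refDose point doses entering the ratio.
#' @slot uncertainty relative statistical uncertainty of the ratio
#'   (quadrature of the two point uncertainties).
#' @slot point measurement point (mm, room frame).
#' @slot description free-text field descriptor.
#' @export
setClass("OutputFactorResult", representation(
  factor      = "numeric",
  testDose    = "numeric",
  refDose     = "numeric",
  uncertainty = "numeric",
  point       = "numeric",
  description = "character"
))

#' Gamma comparison result
#' @slot passRate percentage of evaluated voxels with gamma < 1.
#' @slot gamma per-voxel gamma array (NA outside the evaluated region).
#' @slot doseCriterion absolute dose-difference criterion (same units as dose).
#' @slot dta distance-to-agreement criterion (mm).
#' @slot threshold low-dose threshold (fraction of reference maximum).
#' @slot nEvaluated number of voxels entering the pass rate.
#' @export
setClass("GammaResult", representation(
  passRate      = "numeric",
  gamma         = "array",
  doseCriterion = "numeric",
  dta           = "numeric",
  threshold     = "numeric",
  nEvaluated    = "numeric"
))
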