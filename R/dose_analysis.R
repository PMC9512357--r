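#' Point dose with local averaging
#'
#' Dose at a room-frame point read as the mean over the 3 x 3 x 3 voxel
#' neighborhood centered on the containing voxel (Monte Carlo noise
#' control), together with the corresponding statistical uncertainty.
#'
#' @param dose a [DoseGrid-class].
#' @param point room-frame position (mm), length 3.
#' @param halfWidth neighborhood half-width in voxels (default 1 -> 3x3x3).
#' @return list with `dose` and relative `uncertainty`.
#' @export
pointDose <- function(dose, point, halfWidth = 1) {
  stopifnot(is(dose, "DoseGrid"), length(point) == 3)
  dims <- dim(dose@dose)
  idx <- floor((point - dose@origin) / dose@spacing) + 1
  if (any(idx < 1) || any(idx > dims)) stop("point lies outside the dose grid")
  rng <- lapply(1:3, function(a)
    max(1, idx[a] - halfWidth):min(dims[a], idx[a] + halfWidth))
  block <- dose@dose[rng[[1]], rng[[2]], rng[[3]]]
  ub <- dose@uncertainty[rng[[1]], rng[[2]], rng[[3]]]
  m <- mean(block)
  # voxels are correlated after filtering; quote the mean voxel uncertainty
  u <- if (all(is.na(ub))) NA_real_ else mean(ub, na.rm = TRUE)
  list(dose = m, uncertainty = u)
}

#' Output factor
#'
#' Ratio of the dose of a test field to that of the reference field at a
#' measurement point (the field center at 100 mm depth in the standard
#' protocol), with point doses read by 3 x 3 x 3 neighborhood averaging and
#' the ratio uncertainty propagated in quadrature from both runs.
#'
#' @param testDose,refDose [DoseGrid-class] objects on the same grid.
#' @param point measurement point (mm, room frame); for offset fields the
#'   offset field center at measurement depth.
#' @param refPoint point at which the reference dose is read (default: the
#'   reference field center on the beam axis at the same depth as `point`).
#' @param description optional field descriptor.
#' @return an [OutputFactorResult-class].
#' @examples
#' \dontrun{
#' of <- outputFactor(testDose, refDose, point = c(0, 0, 0))
#' of@factor
#' }
#' @export
outputFactor <- function(testDose, refDose, point = c(0, 0, 0),
                         refPoint = c(0, 0, point[3]),
                         description = "") {
  if (!identical(dim(testDose@dose), dim(refDose@dose)) ||
      any(abs(testDose@spacing - refDose@spacing) > 1e-9))
    stop("test and reference dose grids must share geometry")
  pt <- pointDose(testDose, point)
  pr <- pointDose(refDose, refPoint)
  if (pr$dose == 0) stop("reference dose is zero at the measurement point")
  unc <- sqrt(sum(c(pt$uncertainty, pr$uncertainty)^2, na.rm = TRUE))
  new("OutputFactorResult",
      factor = pt$dose / pr$dose, testDose = pt$dose, refDose = pr$dose,
      uncertainty = unc, point = as.numeric(point), description = description)
}

#' Gamma index pass rate
#'
#' Global gamma analysis of an evaluated dose grid against a reference:
#' for each reference voxel above the low-dose threshold,
#' `gamma = min over r' of sqrt((D_eval(r') - D_ref(r))^2 / dD^2 +
#' |r' - r|^2 / dta^2)`, with `dD = doseCritPct/100 * normDose` and the
#' search taken over a sphere of radius `searchFactor * dta` with sub-voxel
#' trilinear interpolation of the evaluated grid on a `searchStep` lattice.
#' The pass rate is the percentage of evaluated voxels with gamma < 1.
#' The comparison is one-directional (reference vs evaluated).
#'
#' @param evalDose,refDose [DoseGrid-class] objects on the same grid.
#' @param doseCritPct dose-difference criterion as % of `normDose`.
#' @param normDose normalization dose (e.g. 100 cGy for simple beams, the
#'   prescription dose for plans).
#' @param dtaMM distance-to-agreement criterion (mm).
#' @param thresholdPct low-dose threshold as % of the reference maximum.
#' @param searchStep search lattice step (mm).
#' @param searchFactor search radius in units of `dtaMM`.
#' @return a [GammaResult-class].
#' @export
gammaPassRate <- function(evalDose, refDose, doseCritPct = 2, normDose = 100,
                          dtaMM = 2, thresholdPct = 10,
                          searchStep = 0.2, searchFactor = 3) {
  if (!identical(dim(evalDose@dose), dim(refDose@dose)) ||
      any(abs(evalDose@spacing - refDose@spacing) > 1e-9) ||
      any(abs(evalDose@origin - refDose@origin) > 1e-9))
    stop("evaluated and reference dose grids must be co-registered")
  if (doseCritPct <= 0 || dtaMM <= 0) stop("gamma criteria must be positive")
  dims <- dim(refDose@dose)
  doseCrit <- doseCritPct / 100 * normDose
  thrAbs <- thresholdPct / 100 * max(refDose@dose)
  res <- .cppGamma(as.numeric(refDose@dose), as.numeric(evalDose@dose),
                   as.integer(dims), refDose@spacing,
                   doseCrit, dtaMM, thrAbs, searchStep, searchFactor)
  new("GammaResult",
      passRate = res$passRate, gamma = array(res$gamma, dims),
      doseCriterion = doseCrit, dta = dtaMM, threshold = thresholdPct / 100,
      nEvaluated = res$nEvaluated)
}

#' Extract a 1-D dose profile
#'
#' Nearest-voxel line extraction along a grid axis through a given room-frame
#' position, returning voxel-center coordinates and doses.
#'
#' @param dose a [DoseGrid-class].
#' @param axis `"x"`, `"y"` or `"z"` (z = depth at gantry zero).
#' @param position room-frame point the line passes through (mm); the two
#'   coordinates orthogonal to `axis` select the line.
#' @return data.frame with columns `position` (mm) and `dose`.
#' @export
extractProfile <- function(dose, axis = c("x", "y", "z"),
                           position = c(0, 0, 0)) {
  axis <- match.arg(axis)
  a <- match(axis, c("x", "y", "z"))
  dims <- dim(dose@dose)
  idx <- floor((position - dose@origin) / dose@spacing) + 1
  others <- setdiff(1:3, a)
  if (any(idx[others] < 1) || any(idx[others] > dims[others]))
    stop("position lies outside the dose grid")
  sel <- list(idx[1], idx[2], idx[3])
  sel[[a]] <- seq_len(dims[a])
  prof <- dose@dose[sel[[1]], sel[[2]], sel[[3]]]
  pos <- dose@origin[a] + (seq_len(dims[a]) - 0.5) * dose@spacing[a]
  data.frame(position = pos, dose = as.numeric(prof))
}

#' Histories for an output-factor run
#'
#' Histories scale with the open aperture area at a fixed per-point
#' statistical noise (the benchmark protocol scales history counts roughly
#' proportionally to field area): `H = 2e6 * A / 10^4 mm^2`, clipped to
#' [1e6, 8e6].
#'
#' @param area open aperture area (mm^2).
#' @return number of histories.
#' @export
defaultHistories <- function(area) {
  max(1e6, min(8e6, round(2e6 * area / 1e4)))
}

#' Filtered dose of a square benchmark field
#'
#' One arm of the output-factor protocol: builds the (possibly offset)
#' square field, runs the full phase-space + Monte Carlo pipeline on the
#' standard 300 mm water cube with the isocenter at 100 mm depth, scales to
#' absolute dose and applies the median window filter (radius 1 for fields
#' of width 10 mm, else 3).
#'
#' @param model a [BeamModel-class].
#' @param width field width (mm).
#' @param offsetX,offsetY field offset (mm, IEC61217).
#' @param mu monitor units.
#' @param histories histories (default [defaultHistories()] of the area).
#' @param seed integer seed.
#' @param phantom phantom (default [waterPhantom()]).
#' @param filterRadius median filter radius (default by field width).
#' @return an absolute-dose, filtered [DoseGrid-class].
#' @export
squareFieldDose <- function(model, width, offsetX = 0, offsetY = 0, mu = 100,
                            histories = NULL, seed = 1,
                            phantom = waterPhantom(),
                            filterRadius = if (width <= 10) 1 else 3) {
  ap <- makeSquareField(width, offsetX, offsetY, model@mlcTransmission,
                        model@geometry)
  seg <- segment(ap, mu = mu)
  if (is.null(histories)) histories <- defaultHistories(openArea(ap, model@geometry))
  computeBeamDose(model, seg, phantom, histories = histories, seed = seed,
                  filterRadius = filterRadius)
}

setMethod("show", "OutputFactorResult", function(object) {
  cat(sprintf("OutputFactor %s: %.3f +/- %.3f (test %.4g / ref %.4g at [%g, %g, %g] mm)\n",
              object@description, object@factor,
              object@factor * object@uncertainty,
              object@testDose, object@refDose,
              object@point[1], object@point[2], object@point[3]))
})

setMethod("show", "GammaResult", function(object) {
  cat(sprintf("Gamma %.3g / %.1f mm (threshold %.0f%%): pass rate %.1f%% over %g voxels\n",
              object@doseCriterion, object@dta, 100 * object@threshold,
              object@passRate, object@nEvaluated))
})
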