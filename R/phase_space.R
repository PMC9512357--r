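#' Isocenter-plane fluence grid coordinates
#'
#' Coordinates of the I x J fluence grid at the isocenter plane: grid point
#' (i, j) (0-based) lies at `(gx + i dx, gy + j dy, d)`.
#'
#' @param geometry a [MachineGeometry-class].
#' @return list with `x` (length I), `y` (length J) and `z` (the isocenter
#'   distance d), all in mm.
#' @export
buildGrid <- function(geometry = defaultGeometry()) {
  list(
    x = geometry@gridEdge[1] + (seq_len(geometry@gridSize[1]) - 1) * geometry@gridResolution[1],
    y = geometry@gridEdge[2] + (seq_len(geometry@gridSize[2]) - 1) * geometry@gridResolution[2],
    z = geometry@sourceToIsocenter)
}

#' Project isocenter grid points to the phase-space plane
#'
#' For a virtual source at `sn` on the beam axis, an isocenter grid point
#' (xd, yd, d) projects to the phase-space plane (z = p) at
#' `xp = xd (p - sn) / (d - sn)` (same in y), and the particle emitted there
#' travels along the unit vector from the source through that point.
#'
#' @param xd,yd isocenter-plane coordinates (mm), equal-length vectors.
#' @param sn source position (mm from nominal source), with `sn < p`.
#' @param geometry a [MachineGeometry-class].
#' @return list of matrices `position` (n x 3) and `direction` (n x 3).
#' @export
projectToPlane <- function(xd, yd, sn, geometry = defaultGeometry()) {
  p <- geometry@phasePlane; d <- geometry@sourceToIsocenter
  if (sn >= p) stop("source position must lie above the phase-space plane (sn < p)")
  f <- (p - sn) / (d - sn)
  xp <- xd * f; yp <- yd * f
  dz <- p - sn
  rp <- sqrt(xp^2 + yp^2 + dz^2)
  list(position = cbind(x = xp, y = yp, z = rep(p, length(xp))),
       direction = cbind(x = xp / rp, y = yp / rp, z = dz / rp))
}

#' Primary-divergent coordinates of grid points
#'
#' Collimator and fluence-profile settings are expressed at the isocenter
#' plane with divergence constructed from the primary source.  A grid point
#' seen from a secondary source at `sn` therefore maps to
#' `x'd = xd d (c - sn) / (c (d - sn))` (identity for `sn = 0`) before being
#' tested against the aperture or the radial fluence profile.
#'
#' @inheritParams projectToPlane
#' @return list with vectors `x`, `y` and the off-axis radius `r`.
#' @export
primaryDivergentCoords <- function(xd, yd, sn, geometry = defaultGeometry()) {
  cc <- geometry@collimator; d <- geometry@sourceToIsocenter
  if (sn >= cc) stop("source position must lie above the collimator (sn < c)")
  t <- d * (cc - sn) / (cc * (d - sn))
  xs <- xd * t; ys <- yd * t
  list(x = xs, y = ys, r = sqrt(xs^2 + ys^2))
}

#' Source width at the phase-space plane
#'
#' Gaussian width of a source of standard deviation (sigma_x, sigma_y),
#' located at `sn`, when projected through the collimator (at c) onto the
#' phase-space plane (at p): `sigma_p = sigma (p - c) / (c - sn)`.
#'
#' @param source a one-row data.frame or list with `position`, `sigma_x`,
#'   `sigma_y` (as in the `sources` slot of a [BeamModel-class]).
#' @param geometry a [MachineGeometry-class].
#' @return numeric(2): (sigma_xp, sigma_yp) in mm.
#' @export
sigmaAtPlane <- function(source, geometry = defaultGeometry()) {
  sn <- source$position
  cc <- geometry@collimator; p <- geometry@phasePlane
  if (abs(cc - sn) < 1e-12) stop("source cannot coincide with the collimator plane")
  if (sn > cc) stop("source position must lie above the collimator")
  f <- (p - cc) / (cc - sn)
  c(sigma_xp = source$sigma_x * f, sigma_yp = source$sigma_y * f)
}

#' Point-source fluence grid for one source and aperture
#'
#' The unblurred fluence of Eq.-(7)-type form: the radial primary fluence
#' profile evaluated at the primary-divergent off-axis radius of each grid
#' point, times the aperture function at the primary-divergent coordinates.
#'
#' @param model a [BeamModel-class].
#' @param aperture an [Aperture-class].
#' @param sn source position (mm).
#' @return I x J matrix (x indexes rows).
#' @export
rawFluence <- function(model, aperture, sn) {
  geo <- model@geometry
  grd <- buildGrid(geo)
  t <- geo@sourceToIsocenter * (geo@collimator - sn) /
       (geo@collimator * (geo@sourceToIsocenter - sn))
  xs <- grd$x * t; ys <- grd$y * t
  r <- sqrt(outer(xs^2, ys^2, "+"))
  phi <- matrix(interpProfile(model@fluenceProfile, as.vector(r)), nrow = length(xs))
  omega <- .apertureMaskGrid(aperture, xs, ys, geo)
  phi * omega
}

# aperture function evaluated on the outer grid xs x ys (vectors), returning
# a matrix of weights; same conventions as apertureMask() but O(I + J) setup.
.apertureMaskGrid <- function(aperture, xs, ys, geometry) {
  nPairs <- length(aperture@bankA)
  pitch <- geometry@mlcLeafWidth
  y0 <- -pitch * nPairs / 2
  leaf <- floor((ys - y0) / pitch) + 1
  okY <- leaf >= 1 & leaf <= nPairs &
         ys >= aperture@yJaws[1] & ys < aperture@yJaws[2]
  leafC <- pmin(pmax(leaf, 1L), nPairs)
  xlo <- pmax(aperture@bankA[leafC], -geometry@fixedXJaw)
  xhi <- pmin(aperture@bankB[leafC], geometry@fixedXJaw)
  xlo[!okY] <- Inf; xhi[!okY] <- -Inf
  open <- outer(xs, xlo, ">=") & outer(xs, xhi, "<")
  out <- matrix(aperture@transmission, length(xs), length(ys))
  out[open] <- 1
  out
}

#' Calibrated, source-blurred fluence map for one segment and source
#'
#' Convolves the point-source fluence with the source's Gaussian footprint at
#' the phase-space plane (via forward/inverse Fourier transforms; kernel
#' truncated at 5 sigma and renormalized to unit sum) and applies the scalar
#' calibration `w_n M A F(sqrt(A)) C`, where M are the segment's monitor
#' units, A its open area, F the collimator scatter factor and C the absolute
#' calibration factor.  The convolution conserves the grid integral, so
#' `sum(composeFluence(...)) = w_n M A F C sum(rawFluence(...))` up to mass
#' blurred off the grid edge.
#'
#' @param model a [BeamModel-class].
#' @param seg a [Segment-class].
#' @param sourceIndex which virtual source (row of `model@sources`).
#' @return I x J calibrated fluence matrix.
#' @export
composeFluence <- function(model, seg, sourceIndex = 1) {
  src <- model@sources[sourceIndex, ]
  A <- openArea(seg@aperture, model@geometry)
  if (A == 0) {
    g <- model@geometry
    return(matrix(0, g@gridSize[1], g@gridSize[2]))
  }
  raw <- rawFluence(model, seg@aperture, src$position)
  blurred <- .blurSource(raw, src, model@geometry)
  src$weight * seg@mu * A * scatterFactor(model, A) * model@calibration * blurred
}

.blurSource <- function(mat, src, geometry) {
  sig <- sigmaAtPlane(src, geometry)
  spacing <- .planeSpacing(geometry, src$position)
  .convolveGaussian(mat, sig[1] / spacing[1], sig[2] / spacing[2])
}

# grid cell size at the phase-space plane for a source at sn
.planeSpacing <- function(geometry, sn) {
  geometry@gridResolution * (geometry@phasePlane - sn) /
    (geometry@sourceToIsocenter - sn)
}

.blurSpacing <- function(model, sourceIndex) {
  .planeSpacing(model@geometry, model@sources$position[sourceIndex])
}

# Separable Gaussian convolution via 1-D FFTs along each dimension.
# sigma in units of cells; kernel truncated at +/- 5 sigma, unit sum.
.convolveGaussian <- function(mat, sigmaX, sigmaY) {
  mat <- .convolve1d(mat, sigmaX)
  t(.convolve1d(t(mat), sigmaY))
}

.gaussKernel <- function(sigma) {
  r <- ceiling(5 * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

.convolve1d <- function(mat, sigma) {
  if (sigma < 1e-9) return(mat)
  k <- .gaussKernel(sigma)
  K <- length(k); r <- (K - 1L) / 2L
  I <- nrow(mat)
  P <- stats::nextn(I + K - 1L, 2)
  pad <- matrix(0, P, ncol(mat)); pad[seq_len(I), ] <- mat
  kpad <- numeric(P); kpad[seq_len(K)] <- k
  out <- Re(mvfft(mvfft(pad) * fft(kpad), inverse = TRUE)) / P
  out[(r + 1L):(r + I), , drop = FALSE]
}

#' Build the phase-space map of a beam
#'
#' Composes the calibrated per-source fluence maps of one beam by summing
#' its segments' aperture-modulated fluence (each segment weighted by
#' `M F(sqrt(A)) C` times the cell area, so a cell's value is the number of
#' particles it contributes and the beam total is proportional to
#' `M A F(A) C`), blurring each sum with the source Gaussian, and applying
#' the 1%-of-maximum cutoff across the whole beam: cells below 1% of the
#' per-beam maximum are excluded from the sampling mask and the integral
#' fluence.
#'
#' @param model a [BeamModel-class].
#' @param beam a [Beam-class], a single [Segment-class], or a list of
#'   segments (one beam's worth).
#' @param maskThreshold relative cutoff (default 0.01 of the beam maximum).
#' @return a [PhaseSpaceMap-class].
#' @examples
#' bm <- loadBeamModel(quality = "flattened")
#' seg <- segment(makeSquareField(100), mu = 100)
#' ps <- computePhaseSpace(bm, seg)
#' ps
#' @export
computePhaseSpace <- function(model, beam, maskThreshold = 0.01) {
  segs <- if (is(beam, "Beam")) beam@segments
          else if (is(beam, "Segment")) list(beam)
          else beam
  stopifnot(length(segs) >= 1, all(vapply(segs, is, TRUE, class2 = "Segment")))
  geo <- model@geometry
  cellArea <- prod(geo@gridResolution)
  nSrc <- nrow(model@sources)

  fl <- vector("list", nSrc)
  for (n in seq_len(nSrc)) {
    src <- model@sources[n, ]
    acc <- matrix(0, geo@gridSize[1], geo@gridSize[2])
    for (sg in segs) {
      A <- openArea(sg@aperture, geo)
      if (A == 0) next
      # per-cell particle content: fluence density x cell area; the open
      # area enters through the integral of the aperture-modulated fluence
      acc <- acc + (sg@mu * scatterFactor(model, A) * cellArea) *
        rawFluence(model, sg@aperture, src$position)
    }
    fl[[n]] <- src$weight * model@calibration * .blurSource(acc, src, geo)
    fl[[n]][fl[[n]] < 0] <- 0     # clip FFT ringing at machine precision
  }

  peak <- max(vapply(fl, max, 0))
  thr <- maskThreshold * peak
  msk <- lapply(fl, function(m) m >= thr)
  ints <- mapply(function(m, k) sum(m[k]), fl, msk)

  f <- (geo@phasePlane - model@sources$position) /
       (geo@sourceToIsocenter - model@sources$position)
  planeSpacing <- cbind(geo@gridResolution[1] * f, geo@gridResolution[2] * f)

  new("PhaseSpaceMap",
    fluence = fl, mask = msk, sources = model@sources, geometry = geo,
    planeSpacing = planeSpacing, sourceIntegrals = as.numeric(ints),
    integralFluence = sum(ints), maskThreshold = thr, quality = model@quality)
}

#' Integral fluence of a phase-space map
#' @param x a [PhaseSpaceMap-class].
#' @return the masked integral fluence (particle count scale).
#' @export
integralFluence <- function(x) {
  stopifnot(is(x, "PhaseSpaceMap"))
  x@integralFluence
}

#' Sample particle records from a phase-space map
#'
#' Emits photon records from the masked fluence maps: the source is chosen in
#' proportion to its masked integral, the grid cell by rejection sampling
#' against the cell fluence (restricted to masked-in cells), and the energy
#' by rejection sampling of the tabulated spectrum lines.  The particle
#' position is the chosen cell projected to the phase-space plane with a
#' uniform intra-cell jitter; the direction points from the generating source
#' through that position.  The stream is reproducible for a fixed seed.
#'
#' @param phaseSpace a [PhaseSpaceMap-class].
#' @param model the generating [BeamModel-class] (for the energy spectrum).
#' @param count number of particles to emit.
#' @param seed integer seed.
#' @param jitter logical: apply intra-cell uniform jitter (default TRUE).
#' @return data.frame with columns `x, y, z` (mm, beam frame), `u, v, w`
#'   (unit direction), `energy` (MeV), `weight`, plus bookkeeping columns
#'   `source`, `i`, `j` (1-based cell indices).
#' @export
sampleParticles <- function(phaseSpace, model, count, seed, jitter = TRUE) {
  stopifnot(count > 0)
  if (phaseSpace@integralFluence <= 0) stop("empty beam: all-zero fluence")
  set.seed(as.integer(seed %% .Machine$integer.max))
  geo <- phaseSpace@geometry
  nSrc <- length(phaseSpace@fluence)

  srcDraw <- sample.int(nSrc, count, replace = TRUE,
                        prob = phaseSpace@sourceIntegrals)
  out <- vector("list", nSrc)
  for (n in seq_len(nSrc)) {
    m <- sum(srcDraw == n)
    if (m == 0) next
    vals <- phaseSpace@fluence[[n]][phaseSpace@mask[[n]]]
    cells <- which(phaseSpace@mask[[n]])
    if (!length(cells)) next
    picked <- .rejectionSampleCells(vals, m)
    cellIdx <- cells[picked]
    i <- ((cellIdx - 1L) %% geo@gridSize[1]) + 1L
    j <- ((cellIdx - 1L) %/% geo@gridSize[1]) + 1L
    jx <- if (jitter) runif(m, -0.5, 0.5) else 0
    jy <- if (jitter) runif(m, -0.5, 0.5) else 0
    xd <- geo@gridEdge[1] + (i - 1L + jx) * geo@gridResolution[1]
    yd <- geo@gridEdge[2] + (j - 1L + jy) * geo@gridResolution[2]
    en <- .rejectionSampleSpectrum(model@spectrum, m)
    pr <- projectToPlane(xd, yd, phaseSpace@sources$position[n], geo)
    out[[n]] <- data.frame(
      x = pr$position[, 1], y = pr$position[, 2], z = pr$position[, 3],
      u = pr$direction[, 1], v = pr$direction[, 2], w = pr$direction[, 3],
      energy = en, weight = 1, source = n, i = i, j = j)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(res) <- NULL
  res
}

# rejection sampling of cell indices proportional to vals (masked cells):
# propose uniformly among cells, accept with vals/max(vals).
.rejectionSampleCells <- function(vals, m) {
  vmax <- max(vals)
  accProb <- sum(vals) / (as.numeric(length(vals)) * vmax)
  picked <- integer(0)
  need <- m
  while (need > 0) {
    nProp <- min(5e6, ceiling(need / accProb * 1.1) + 16)
    prop <- sample.int(length(vals), size = nProp, replace = TRUE)
    acc <- prop[runif(nProp) < vals[prop] / vmax]
    picked <- c(picked, acc)
    need <- m - length(picked)
  }
  picked[seq_len(m)]
}

# rejection sampling of discrete spectrum lines with intensities as target.
.rejectionSampleSpectrum <- function(spectrum, m) {
  lam <- spectrum$intensity
  lmax <- max(lam)
  accProb <- sum(lam) / (length(lam) * lmax)
  en <- numeric(0)
  need <- m
  while (need > 0) {
    nProp <- min(5e6, ceiling(need / accProb * 1.1) + 16)
    prop <- sample.int(length(lam), size = nProp, replace = TRUE)
    acc <- prop[runif(nProp) < lam[prop] / lmax]
    en <- c(en, spectrum$energy[acc])
    need <- m - length(en)
  }
  en[seq_len(m)]
}

#' Write / read particle records as plain text
#'
#' CSV export of a sampled particle stream (columns x, y, z, u, v, w, energy,
#' weight in mm / MeV) with a commented header recording the beam quality,
#' seed and count.  Intended for small streams and interchange; large streams
#' should be regenerated from the seed.
#'
#' @param particles data.frame from [sampleParticles()].
#' @param path output file.
#' @param quality,seed metadata recorded in the header.
#' @return `path` invisibly.
#' @export
writeParticles <- function(particles, path, quality = "", seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vsmDose particle records (mm, MeV)",
    paste0("# quality=", quality, " seed=", seed, " count=", nrow(particles))), con)
  cols <- c("x", "y", "z", "u", "v", "w", "energy", "weight")
  write.table(particles[, cols], con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeParticles
#' @export
readParticles <- function(path) {
  read.table(path, header = TRUE, sep = ",", comment.char = "#")
}

setMethod("show", "PhaseSpaceMap", function(object) {
  cat(sprintf("PhaseSpaceMap (%s): %d source(s), grid %d x %d\n",
              object@quality, length(object@fluence),
              object@geometry@gridSize[1], object@geometry@gridSize[2]))
  for (n in seq_along(object@fluence))
    cat(sprintf("  source %d: masked cells %d, integral %.4g\n", n,
                sum(object@mask[[n]]), object@sourceIntegrals[n]))
  cat(sprintf("  integral fluence %.6g (mask threshold %.3g)\n",
              object@integralFluence, object@maskThreshold))
})
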