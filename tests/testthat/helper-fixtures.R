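# Shared fixtures and independent oracles for the test suite.
# Heavy Monte Carlo runs are cached so several test files can reuse them.

.fixtureCache <- new.env(parent = emptyenv())

cachedValue <- function(key, fn) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- fn()
  .fixtureCache[[key]]
}

flatModel <- function() cachedValue("bm_flat", function()
  loadBeamModel(quality = "flattened"))
fffModel <- function() cachedValue("bm_fff", function()
  loadBeamModel(quality = "FFF"))

# moderate-statistics shared dose runs (seeds fixed once)
sharedDose30 <- function() cachedValue("dose30", function()
  squareFieldDose(flatModel(), 30, histories = 3e5, seed = 101))
sharedDose100 <- function() cachedValue("dose100", function()
  squareFieldDose(flatModel(), 100, histories = 4e5, seed = 102))

# reduced fluence grid for convolution tests
smallGeometry <- function(n = 64, res = 2) {
  new("MachineGeometry",
      sourceToIsocenter = 1000, phasePlane = 548, collimator = 401.8,
      gridSize = c(as.integer(n), as.integer(n)), gridResolution = c(res, res),
      gridEdge = c(-n * res / 2, -n * res / 2), fixedXJaw = 200,
      mlcLeafCount = 160L, mlcLeafWidth = 5)
}

# Independent direct-summation 2-D convolution oracle (zero-extended edges,
# same support convention as the FFT path).
directConvolve2d <- function(mat, k2d) {
  I <- nrow(mat); J <- ncol(mat)
  rx <- (nrow(k2d) - 1) / 2; ry <- (ncol(k2d) - 1) / 2
  out <- matrix(0, I, J)
  for (a in -rx:rx) for (b in -ry:ry) {
    w <- k2d[a + rx + 1, b + ry + 1]
    if (w == 0) next
    di <- max(1, 1 + a):min(I, I + a)
    dj <- max(1, 1 + b):min(J, J + b)
    out[di, dj] <- out[di, dj] + w * mat[di - a, dj - b]
  }
  out
}

# Independent trilinear interpolation (voxel centers at 0-based integer
# index units, mirroring the gamma engine's convention).
triInterp <- function(a, fx, fy, fz) {
  n <- dim(a)
  if (fx < 0 || fy < 0 || fz < 0 ||
      fx > n[1] - 1 || fy > n[2] - 1 || fz > n[3] - 1) return(NA_real_)
  i <- min(floor(fx), max(n[1] - 2, 0)); j <- min(floor(fy), max(n[2] - 2, 0))
  k <- min(floor(fz), max(n[3] - 2, 0))
  wx <- fx - i; wy <- fy - j; wz <- fz - k
  acc <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    ii <- min(i + dx + 1, n[1]); jj <- min(j + dy + 1, n[2]); kk <- min(k + dz + 1, n[3])
    w <- (if (dx) wx else 1 - wx) * (if (dy) wy else 1 - wy) * (if (dz) wz else 1 - wz)
    acc <- acc + w * a[ii, jj, kk]
  }
  acc
}

# Independent exhaustive-search gamma oracle over the same offset lattice.
gammaOracle <- function(refArr, evalArr, spacing, doseCrit, dta, voxels,
                        searchStep = 0.2, searchFactor = 3) {
  rad <- searchFactor * dta
  kx <- floor(rad / searchStep)
  offs <- expand.grid(dx = (-kx:kx) * searchStep,
                      dy = (-kx:kx) * searchStep,
                      dz = (-kx:kx) * searchStep)
  offs <- offs[offs$dx^2 + offs$dy^2 + offs$dz^2 <= rad^2, ]
  out <- numeric(nrow(voxels))
  for (v in seq_len(nrow(voxels))) {
    ix <- voxels[v, 1]; iy <- voxels[v, 2]; iz <- voxels[v, 3]
    rd <- refArr[ix, iy, iz]
    g2 <- Inf
    for (o in seq_len(nrow(offs))) {
      de <- triInterp(evalArr,
                      (ix - 1) + offs$dx[o] / spacing[1],
                      (iy - 1) + offs$dy[o] / spacing[2],
                      (iz - 1) + offs$dz[o] / spacing[3])
      if (is.na(de)) next
      r2 <- offs$dx[o]^2 + offs$dy[o]^2 + offs$dz[o]^2
      g2 <- min(g2, r2 / dta^2 + ((de - rd) / doseCrit)^2)
    }
    out[v] <- sqrt(g2)
  }
  out
}

# flat synthetic dose grid helper
flatDoseGrid <- function(valueArr, spacing = c(2, 2, 2), origin = NULL) {
  d <- dim(valueArr)
  if (is.null(origin)) origin <- -d * spacing / 2
  new("DoseGrid", dose = valueArr,
      uncertainty = array(NA_real_, d),
      spacing = spacing, origin = origin, histories = 1, units = "cGy")
}
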