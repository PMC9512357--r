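# CT conversion, Monte Carlo engine behavior, dose scaling, median filter.

test_that("HU conversion follows the calibration table and density ranges", {
  r <- huToDensity(c(0, -1000, -700, 3000))
  expect_equal(r$density[1], 1.0, tolerance = 1e-9)
  expect_identical(r$materialName[1], "water")
  expect_identical(r$materialName[2], "air")
  expect_equal(r$density[3], 0.28, tolerance = 1e-9)   # exactly at a knot
  expect_identical(r$materialName[3], "lung")
  expect_identical(r$materialName[4], "bone")
  # below the table minimum clamps to air
  expect_equal(huToDensity(-5000)$density, huToDensity(-1000)$density)
  expect_identical(huToDensity(-5000)$materialName, "air")
})

test_that("HU conversion is monotone for any monotone calibration table", {
  set.seed(21)
  for (rep in 1:3) {
    tab <- data.frame(hu = sort(runif(8, -1000, 2000)),
                      red = sort(runif(8, 0, 2.5)))
    cal <- list(a = runif(1, 0.8, 1.2), b = runif(1, 0, 0.1),
                table = tab, ranges = NULL)
    hu <- sort(runif(50, -1200, 2200))
    d <- huToDensity(hu, cal)$density
    expect_true(all(diff(d) >= -1e-12))
  }
})

test_that("first-interaction depths follow exponential attenuation", {
  # 1 MeV pencil beam straight into the water cube; primary-only scoring
  # deposits the photon energy at its first interaction site, so the
  # depth histogram of deposited energy must follow exp(-mu z)
  ph <- waterPhantom()
  phys <- vsmDose:::.getPhysics()
  n <- 2e5
  pm <- cbind(x = rep(0.1, n), y = rep(0.1, n), z = rep(-452, n),
              u = 0, v = 0, w = 1, energy = 1)
  res <- vsmDose:::.cppTransport(pm, as.numeric(ph@density),
      as.integer(ph@material), as.integer(dim(ph@density)),
      ph@spacing, ph@origin, phys$energy, phys$muTot, phys$fPE, phys$fPair,
      phys$stopPow, phys$X0, 99, 0.05, 0.2, 1.0, TRUE, FALSE)
  edep <- array(res$edep, dim(ph@density))
  prof <- apply(edep, 3, sum)
  z <- seq_along(prof)                       # 2 mm slices
  keep <- prof > 0 & z <= 125
  fit <- lm(log(prof[keep]) ~ z[keep])
  muFit <- -coef(fit)[2] / 2                 # per mm
  muRef <- muTotal(1, "water") * 1.0 / 10    # rho = 1
  expect_equal(unname(muFit), muRef, tolerance = 0.03)
})

test_that("energy is conserved and deposits never exceed input", {
  ph <- waterPhantom(sideMM = 100, spacing = 4)
  phys <- vsmDose:::.getPhysics()
  n <- 2e4
  set.seed(1)
  pm <- cbind(x = runif(n, -20, 20), y = runif(n, -20, 20), z = rep(-452, n),
              u = 0, v = 0, w = 1, energy = sample(c(0.5, 2, 6), n, TRUE))
  res <- vsmDose:::.cppTransport(pm, as.numeric(ph@density),
      as.integer(ph@material), as.integer(dim(ph@density)),
      ph@spacing, ph@origin, phys$energy, phys$muTot, phys$fPE, phys$fPair,
      phys$stopPow, phys$X0, 12, 0.05, 0.2, 1.0, FALSE, FALSE)
  expect_lte(res$deposited, res$entering)
  expect_gt(res$deposited, 0.1 * res$entering)
  expect_true(all(res$edep >= 0))
})

test_that("symmetric centered field gives a mirror-symmetric dose", {
  dg <- sharedDose30()
  d <- doseArray(dg)
  prof <- extractProfile(dg, "x", c(0, 0, -50))     # 50 mm depth
  n <- length(prof$dose)
  l <- prof$dose[1:(n / 2)]; r <- rev(prof$dose[(n / 2 + 1):n])
  inf <- which(l > 0.5 * max(prof$dose))
  expect_lt(abs(mean(l[inf]) - mean(r[inf])) / max(prof$dose), 0.05)
})

test_that("central-axis depth dose shows buildup then monotone falloff", {
  dg <- sharedDose100()
  d <- doseArray(dg)
  ctr <- 74:77
  dd <- apply(d[ctr, ctr, ], 3, mean)
  imax <- which.max(dd)
  expect_gt(imax, 1)                  # buildup: maximum below the surface
  expect_lt(imax, 26)                 # within the first 50 mm
  expect_lt(dd[1], 0.75 * max(dd))    # low surface dose (no contamination)
  # monotone falloff beyond the maximum, on depth-band averages wide enough
  # to suppress the run's statistical wiggles
  bands <- list(20:30, 45:55, 70:80, 95:105, 120:130)
  deep <- vapply(bands, function(b) mean(dd[b]), 0)
  expect_true(all(diff(deep) < 0))
})

test_that("out-of-beam dose is scatter-only and small", {
  d <- doseArray(sharedDose30())
  # voxel far outside the 30 mm beam and its penumbra, at isocenter depth
  far <- d[15, 15, 50]
  expect_lt(far, 0.05 * max(d))
})

test_that("batch uncertainty scales as one over root histories", {
  bm <- flatModel()
  ph <- waterPhantom(sideMM = 160, spacing = 4)
  ps <- computePhaseSpace(bm, segment(makeSquareField(50), 100))
  gen <- function(n, s) sampleParticles(ps, bm, n, s)
  uAt <- function(H) {
    dg <- simulateDose(gen, ph, maxHistories = H, batchSize = H / 8,
                       seed = 41)
    d <- doseArray(dg); u <- uncertaintyArray(dg)
    hot <- d >= 0.5 * max(d)
    mean(u[hot], na.rm = TRUE)
  }
  H <- c(4e4, 1.6e5, 6.4e5)
  u <- vapply(H, uAt, 0)
  slope <- coef(lm(log(u) ~ log(H)))[2]
  expect_lt(abs(unname(slope) + 0.5), 0.1)
})

test_that("scaled dose is linear in the integral fluence and H-consistent", {
  dg <- sharedDose30()        # already scaled by its own run
  raw <- new("DoseGrid", dose = doseArray(dg), uncertainty = uncertaintyArray(dg),
             spacing = dg@spacing, origin = dg@origin,
             histories = 1000, units = "per-history")
  s1 <- scaleDose(raw, integralFluence = 1000)
  expect_equal(doseArray(s1), doseArray(raw))          # fluence = H: unchanged
  s2 <- scaleDose(raw, integralFluence = 2000)
  expect_equal(doseArray(s2), 2 * doseArray(s1))       # exact linearity
  expect_error(scaleDose(raw, 1000, histories = 0), "histories")

  # two runs of H and 2H agree after scaling (self-consistency)
  bm <- flatModel()
  ph <- waterPhantom(sideMM = 160, spacing = 4)
  ps <- computePhaseSpace(bm, segment(makeSquareField(50), 100))
  gen <- function(n, s) sampleParticles(ps, bm, n, s)
  dA <- scaleDose(simulateDose(gen, ph, maxHistories = 1e5, seed = 51),
                  integralFluence(ps))
  dB <- scaleDose(simulateDose(gen, ph, maxHistories = 2e5, seed = 52),
                  integralFluence(ps))
  hot <- doseArray(dB) >= 0.5 * max(doseArray(dB))
  expect_equal(mean(doseArray(dA)[hot]), mean(doseArray(dB)[hot]),
               tolerance = 0.05)
})

test_that("the run stops at the target uncertainty", {
  bm <- flatModel()
  ph <- waterPhantom(sideMM = 120, spacing = 4)
  ps <- computePhaseSpace(bm, segment(makeSquareField(50), 100))
  gen <- function(n, s) sampleParticles(ps, bm, n, s)
  dg <- simulateDose(gen, ph, targetUncertainty = 0.1, maxHistories = 2e6,
                     batchSize = 2e4, seed = 61)
  expect_lt(dg@histories, 2e6)
  d <- doseArray(dg); u <- uncertaintyArray(dg)
  hot <- d >= 0.5 * max(d)
  expect_lte(mean(u[hot], na.rm = TRUE), 0.1)
  expect_error(simulateDose(gen, ph, targetUncertainty = -1,
                            maxHistories = 100, seed = 1), "positive")
  expect_error(simulateDose(data.frame(), ph, seed = 1), "empty")
})

test_that("median filter matches a brute-force neighborhood median", {
  set.seed(71)
  arr <- array(runif(20 * 18 * 6), c(20, 18, 6))
  dg <- flatDoseGrid(arr)
  for (rad in c(1, 3)) {
    filt <- doseArray(medianFilterDose(dg, rad))
    oracle <- array(0, dim(arr))
    for (k in 1:6) for (j in 1:18) for (i in 1:20) {
      xs <- max(1, i - rad):min(20, i + rad)
      ys <- max(1, j - rad):min(18, j + rad)
      zs <- max(1, k - rad):min(6, k + rad)
      oracle[i, j, k] <- median(arr[xs, ys, zs])
    }
    expect_equal(filt, oracle, tolerance = 1e-12)
  }
})

test_that("median filter handles constants, spikes and the identity radius", {
  arr <- array(5, c(9, 9, 9))
  dg <- flatDoseGrid(arr)
  expect_equal(doseArray(medianFilterDose(dg, 3)), arr)        # constant
  arr2 <- arr; arr2[5, 5, 5] <- 500
  dg2 <- flatDoseGrid(arr2)
  expect_equal(doseArray(medianFilterDose(dg2, 1))[5, 5, 5], 5) # spike removed
  expect_equal(doseArray(medianFilterDose(dg2, 0)), arr2)       # identity
  expect_error(medianFilterDose(dg, -1), "radius")
})
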