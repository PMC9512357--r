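# Output factors, gamma analysis, profile extraction.

test_that("output factor is the point-dose ratio with averaging", {
  arr <- array(2, c(21, 21, 21))
  ref <- flatDoseGrid(arr, spacing = c(2, 2, 2))
  expect_equal(outputFactor(ref, ref)@factor, 1.000)

  test2 <- flatDoseGrid(arr * 0.85)
  expect_equal(outputFactor(test2, ref)@factor, 0.85, tolerance = 1e-12)

  refHalf <- flatDoseGrid(arr / 2)
  expect_equal(outputFactor(test2, refHalf)@factor, 1.7, tolerance = 1e-12)

  zero <- flatDoseGrid(array(0, c(21, 21, 21)))
  expect_error(outputFactor(test2, zero), "zero")

  small <- flatDoseGrid(array(1, c(5, 5, 5)))
  expect_error(outputFactor(small, ref), "geometry")
})

test_that("offset fields read the test dose off-axis and the reference on-axis", {
  arr <- array(1, c(21, 21, 21))
  arr[16:21, , ] <- 3                      # hot region at +x
  test <- flatDoseGrid(arr)
  ref <- flatDoseGrid(array(2, c(21, 21, 21)))
  of <- outputFactor(test, ref, point = c(15, 0, 0))
  expect_equal(of@factor, 3 / 2, tolerance = 1e-9)
  expect_equal(of@point, c(15, 0, 0))
})

test_that("point dose averages the 3x3x3 neighborhood", {
  arr <- array(0, c(9, 9, 9)); arr[4:6, 4:6, 4:6] <- 1:27
  dg <- flatDoseGrid(arr, spacing = c(1, 1, 1), origin = c(-4.5, -4.5, -4.5))
  expect_equal(pointDose(dg, c(0, 0, 0))$dose, mean(1:27))
  expect_error(pointDose(dg, c(100, 0, 0)), "outside")
})

test_that("gamma passes identical grids and fails a uniform 3% offset", {
  flat <- array(100, c(20, 20, 3))
  ref <- flatDoseGrid(flat)
  g <- gammaPassRate(ref, ref, doseCritPct = 2, normDose = 100, dtaMM = 2)
  expect_equal(g@passRate, 100)
  expect_true(all(g@gamma[!is.na(g@gamma)] == 0))

  off <- flatDoseGrid(flat * 1.03)
  g <- gammaPassRate(off, ref, doseCritPct = 2, normDose = 100, dtaMM = 2)
  expect_equal(g@passRate, 0)                       # gamma = 1.5 everywhere
  expect_equal(min(g@gamma, na.rm = TRUE), 1.5, tolerance = 1e-9)
})

test_that("a 1 mm shift of a linear gradient passes at 2 mm DTA", {
  # ramp with flat shoulders so every voxel (edges included) is evaluable
  n <- 20
  x <- ((1:n) - 0.5) * 2                            # voxel centers, mm
  ramp <- function(x) 50 + 2 * pmin(pmax(x, 8), 32)
  base <- array(rep(ramp(x), times = n * 3), c(n, n, 3))
  shift <- array(rep(ramp(x - 1), times = n * 3), c(n, n, 3))
  ref <- flatDoseGrid(base); ev <- flatDoseGrid(shift)
  g <- gammaPassRate(ev, ref, doseCritPct = 2, normDose = 100, dtaMM = 2,
                     thresholdPct = 10)
  expect_equal(g@passRate, 100)
  # in the gradient the optimum trades dose against distance:
  # gamma^2 = min_dx (dx/2)^2 + (dx-1)^2 = 0.2 at dx = 0.8 mm
  inner <- g@gamma[7:13, 5:15, 2]
  expect_equal(max(inner), sqrt(0.2), tolerance = 1e-6)
})

test_that("gamma agrees with the exhaustive-search oracle on random grids", {
  set.seed(33)
  n <- 20
  sm <- function() {
    m <- matrix(rnorm(n * n), n, n)
    m <- vsmDose:::.convolveGaussian(m, 2, 2)
    arr <- array(rep(m, 3), c(n, n, 3))
    50 + 10 * arr
  }
  refA <- sm()
  evA <- refA + 0.4 * array(rep(vsmDose:::.convolveGaussian(
    matrix(rnorm(n * n), n, n), 3, 3), 3), c(n, n, 3))
  ref <- flatDoseGrid(refA); ev <- flatDoseGrid(evA)
  res <- gammaPassRate(ev, ref, doseCritPct = 2, normDose = 50, dtaMM = 2,
                       thresholdPct = 50, searchStep = 0.5, searchFactor = 1.5)
  vox <- which(!is.na(res@gamma), arr.ind = TRUE)
  vox <- vox[vox[, 3] == 2, , drop = FALSE]
  set.seed(34)
  vox <- vox[sample(nrow(vox), 25), , drop = FALSE]
  oracle <- gammaOracle(refA, evA, spacing = c(2, 2, 2),
                        doseCrit = 0.02 * 50, dta = 2, voxels = vox,
                        searchStep = 0.5, searchFactor = 1.5)
  expect_equal(res@gamma[vox], oracle, tolerance = 1e-9)
})

test_that("looser gamma criteria never fail more voxels", {
  set.seed(35)
  n <- 16
  m <- vsmDose:::.convolveGaussian(matrix(rnorm(n * n), n, n), 2, 2)
  refA <- 60 + 15 * array(rep(m, 3), c(n, n, 3))
  evA <- refA + 2 * array(rep(vsmDose:::.convolveGaussian(
    matrix(rnorm(n * n), n, n), 2, 2), 3), c(n, n, 3))
  ref <- flatDoseGrid(refA); ev <- flatDoseGrid(evA)
  p22 <- gammaPassRate(ev, ref, 2, 60, 2, thresholdPct = 10)@passRate
  p33 <- gammaPassRate(ev, ref, 3, 60, 3, thresholdPct = 10)@passRate
  p24 <- gammaPassRate(ev, ref, 2, 60, 4, thresholdPct = 10)@passRate
  p42 <- gammaPassRate(ev, ref, 4, 60, 2, thresholdPct = 10)@passRate
  expect_gte(p33, p22)
  expect_gte(p24, p22)
  expect_gte(p42, p22)
  expect_error(gammaPassRate(ev, ref, -2, 60, 2), "positive")
})

test_that("profile extraction returns voxel-center lines", {
  arr <- array(7, c(10, 12, 14))
  dg <- flatDoseGrid(arr, spacing = c(2, 2, 2), origin = c(-10, -12, -14))
  pr <- extractProfile(dg, "x", c(0, 0, 0))
  expect_equal(pr$dose, rep(7, 10))
  expect_equal(pr$position, seq(-9, 9, by = 2))
  expect_error(extractProfile(dg, "x", c(0, 100, 0)), "outside")

  # depth profile of a simulated field peaks between surface and 50 mm
  dd <- extractProfile(sharedDose100(), "z", c(0, 0, 0))
  imax <- which.max(dd$dose)
  expect_gt(dd$position[imax], -100)      # below the entry surface
  expect_lt(dd$position[imax], -50)       # within the first 50 mm of water
})

test_that("lateral profile of a symmetric simulated field mirrors", {
  pr <- extractProfile(sharedDose30(), "y", c(0, 0, 0))
  n <- length(pr$dose)
  l <- pr$dose[1:(n / 2)]; r <- rev(pr$dose[(n / 2 + 1):n])
  inf <- which(l > 0.5 * max(pr$dose))
  expect_lt(mean(abs(l[inf] - r[inf])) / max(pr$dose), 0.1)
})
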