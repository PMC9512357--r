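# Phase-space geometry, fluence composition, convolution, sampling.

test_that("isocenter grid coordinates follow the edge + index convention", {
  g <- buildGrid(defaultGeometry())
  expect_equal(g$x[1], -200)             # point (0, 0)
  expect_equal(g$y[1], -200)
  expect_equal(g$z, 1000)
  expect_equal(g$x[401], 0)              # point (400, 400) -> (0, 0, 1000)
  expect_equal(g$y[401], 0)
  expect_equal(g$x[800], 199.5)          # point (799, .)
})

test_that("projection to the phase-space plane matches the closed forms", {
  geo <- defaultGeometry()
  pr <- projectToPlane(0, 0, 150, geo)
  expect_equal(pr$position[1, ], c(x = 0, y = 0, z = 548), tolerance = 1e-15)
  expect_equal(pr$direction[1, ], c(x = 0, y = 0, z = 1), tolerance = 1e-15)

  pr <- projectToPlane(100, 0, 0, geo)
  expect_equal(unname(pr$position[1, 1]), 100 * 548 / 1000, tolerance = 1e-12)

  pr <- projectToPlane(100, -40, 150, geo)
  expect_equal(unname(pr$position[1, 1]), 100 * 398 / 850, tolerance = 1e-12)
  expect_equal(unname(pr$position[1, 2]), -40 * 398 / 850, tolerance = 1e-12)
  expect_equal(sqrt(sum(pr$direction[1, ]^2)), 1, tolerance = 1e-12)

  expect_error(projectToPlane(0, 0, 600, geo), "phase-space plane")
})

test_that("primary-divergent coordinates match the closed form", {
  geo <- defaultGeometry()
  pd <- primaryDivergentCoords(c(100, 0), c(0, 0), 0, geo)
  expect_equal(pd$x, c(100, 0), tolerance = 1e-12)   # identity at sn = 0
  pd <- primaryDivergentCoords(100, 0, 150, geo)
  expect_equal(pd$x, 100 * (1000 * (401.8 - 150)) / (401.8 * 850),
               tolerance = 1e-12)
  expect_equal(primaryDivergentCoords(0, 0, 150, geo)$r, 0)
  expect_error(primaryDivergentCoords(1, 1, 500, geo), "collimator")
})

test_that("source width at the plane follows the collimator construction", {
  geo <- defaultGeometry()
  s1 <- list(position = 0, sigma_x = 1.5, sigma_y = 1.5)
  expect_equal(unname(sigmaAtPlane(s1, geo)),
               rep(1.5 * 146.2 / 401.8, 2), tolerance = 1e-12)
  s2 <- list(position = 150, sigma_x = 24, sigma_y = 24)
  expect_equal(unname(sigmaAtPlane(s2, geo)),
               rep(24 * 146.2 / 251.8, 2), tolerance = 1e-12)
  s0 <- list(position = 0, sigma_x = 0, sigma_y = 0)
  expect_equal(unname(sigmaAtPlane(s0, geo)), c(0, 0))
  expect_error(sigmaAtPlane(list(position = 401.8, sigma_x = 1, sigma_y = 1), geo),
               "collimator")
})

test_that("raw fluence is the profile modulated by the aperture", {
  bm <- flatModel()
  f <- rawFluence(bm, makeSquareField(100), 0)
  expect_equal(f[401, 401], 1.000)               # grid center, phi(0)
  expect_equal(f[401, 700], 0)                   # y = 149.5 mm: outside jaws
  expect_true(all(f >= 0))

  bf <- fffModel()
  f <- rawFluence(bf, makeSquareField(400), 0)
  expect_equal(f[601, 401], 0.684)               # x = 100 mm: FFF profile value
})

test_that("flattened and FFF profiles have the expected off-axis shape", {
  expect_lte(interpProfile(fffModel()@fluenceProfile, 100), 0.70)
  expect_gte(interpProfile(flatModel()@fluenceProfile, 100), 1.0)
})

test_that("FFT composition equals direct-summation convolution", {
  set.seed(11)
  mat <- matrix(0, 64, 64)
  mat[20:44, 16:48] <- 1 + 0.1 * matrix(rnorm(25 * 33), 25, 33)
  mat <- pmax(mat, 0)
  for (sig in list(c(2.3, 2.3), c(4.1, 1.7))) {
    fftRes <- vsmDose:::.convolveGaussian(mat, sig[1], sig[2])
    k2d <- outer(vsmDose:::.gaussKernel(sig[1]), vsmDose:::.gaussKernel(sig[2]))
    direct <- directConvolve2d(mat, k2d)
    expect_lt(max(abs(fftRes - direct)) / max(direct), 1e-6)
  }
})

test_that("composed fluence carries the M A F C scaling and conserves total", {
  bm <- flatModel()
  seg <- segment(makeSquareField(30), mu = 100)
  A <- openArea(seg@aperture)
  for (n in 1:2) {
    comp <- composeFluence(bm, seg, n)
    raw <- rawFluence(bm, seg@aperture, bm@sources$position[n])
    expect_equal(sum(comp),
                 bm@sources$weight[n] * 100 * A * scatterFactor(bm, A) *
                   bm@calibration * sum(raw),
                 tolerance = 1e-6)
  }
  # delta-kernel limit: vanishing source width leaves the map unchanged
  bmd <- bm
  bmd@sources$sigma_x <- c(1e-13, 1e-13); bmd@sources$sigma_y <- c(1e-13, 1e-13)
  comp <- composeFluence(bmd, seg, 1)
  raw <- rawFluence(bmd, seg@aperture, 0)
  sc <- bm@sources$weight[1] * 100 * A * scatterFactor(bm, A) * bm@calibration
  expect_equal(comp, sc * raw, tolerance = 1e-12)
})

test_that("a single-cell aperture composes to the source Gaussian", {
  bm <- flatModel()
  seg <- segment(makeSquareField(0.5), mu = 10)   # one 0.5 mm cell at center
  comp <- composeFluence(bm, seg, 2)              # broad secondary source
  expect_gt(max(comp), 0)
  kx <- vsmDose:::.gaussKernel(sigmaAtPlane(bm@sources[2, ])[1] /
                                 vsmDose:::.blurSpacing(bm, 2)[1])
  r <- (length(kx) - 1) / 2
  iPeak <- which(comp == max(comp), arr.ind = TRUE)[1, ]
  prof <- comp[(iPeak[1] - r):(iPeak[1] + r), iPeak[2]]
  expect_gt(cor(prof, kx), 0.9999)
})

test_that("doubling monitor units exactly doubles the integral fluence", {
  bm <- flatModel()
  ap <- makeSquareField(30)
  ps1 <- computePhaseSpace(bm, segment(ap, 50))
  ps2 <- computePhaseSpace(bm, segment(ap, 100))
  expect_equal(integralFluence(ps2), 2 * integralFluence(ps1), tolerance = 1e-12)
  expect_equal(sum(composeFluence(bm, segment(ap, 100), 1)),
               2 * sum(composeFluence(bm, segment(ap, 50), 1)), tolerance = 1e-12)
})

test_that("sampling frequencies follow the masked fluence distribution", {
  geo <- new("MachineGeometry",
             sourceToIsocenter = 1000, phasePlane = 548, collimator = 401.8,
             gridSize = c(2L, 2L), gridResolution = c(0.5, 0.5),
             gridEdge = c(-0.5, -0.5), fixedXJaw = 200,
             mlcLeafCount = 160L, mlcLeafWidth = 5)
  ps <- new("PhaseSpaceMap",
            fluence = list(matrix(1, 2, 2)), mask = list(matrix(TRUE, 2, 2)),
            sources = data.frame(position = 0, weight = 1,
                                 sigma_x = 1, sigma_y = 1),
            geometry = geo,
            planeSpacing = matrix(0.274, 1, 2),
            sourceIntegrals = 4, integralFluence = 4,
            maskThreshold = 0.01, quality = "flattened")
  bm <- flatModel()
  H <- 40000
  p <- sampleParticles(ps, bm, H, seed = 5)
  freq <- table(factor(paste(p$i, p$j), levels = c("1 1", "2 1", "1 2", "2 2"))) / H
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / H)))
})

test_that("energy sampling reproduces the spectrum lines", {
  bm <- flatModel()
  ap <- makeSquareField(30)
  ps <- computePhaseSpace(bm, segment(ap, 100))
  H <- 1e5
  p <- sampleParticles(ps, bm, H, seed = 17)
  lam <- bm@spectrum$intensity / sum(bm@spectrum$intensity)
  obs <- table(factor(p$energy, levels = bm@spectrum$energy))
  chi2 <- sum((obs - H * lam)^2 / (H * lam))
  expect_lt(chi2, qchisq(0.99, df = length(lam) - 1))
})

test_that("masked-out cells emit no particles and seeds reproduce streams", {
  bm <- flatModel()
  ps <- computePhaseSpace(bm, segment(makeSquareField(30), 100))
  p1 <- sampleParticles(ps, bm, 20000, seed = 23)
  p2 <- sampleParticles(ps, bm, 20000, seed = 23)
  expect_identical(p1, p2)
  p3 <- sampleParticles(ps, bm, 20000, seed = 24)
  expect_false(identical(p1, p3))
  # every sampled cell is inside the mask
  for (n in unique(p1$source)) {
    sel <- p1$source == n
    idx <- cbind(p1$i[sel], p1$j[sel])
    expect_true(all(ps@mask[[n]][idx]))
    expect_true(all(ps@fluence[[n]][idx] >= ps@maskThreshold))
  }
})

test_that("sampled rays pass through their generating grid cell at isocenter", {
  bm <- flatModel()
  ps <- computePhaseSpace(bm, segment(makeSquareField(50), 100))
  p <- sampleParticles(ps, bm, 5000, seed = 31)
  geo <- bm@geometry
  tTo <- (geo@sourceToIsocenter - p$z) / p$w
  xAtIso <- p$x + p$u * tTo
  yAtIso <- p$y + p$v * tTo
  xCell <- geo@gridEdge[1] + (p$i - 1) * geo@gridResolution[1]
  yCell <- geo@gridEdge[2] + (p$j - 1) * geo@gridResolution[2]
  expect_true(all(abs(xAtIso - xCell) <= geo@gridResolution[1] / 2 + 1e-9))
  expect_true(all(abs(yAtIso - yCell) <= geo@gridResolution[2] / 2 + 1e-9))
  expect_true(all(abs(sqrt(p$u^2 + p$v^2 + p$w^2) - 1) < 1e-9))
  expect_true(all(p$w > 0))
  expect_true(all(p$z == geo@phasePlane))
})

test_that("sampling an empty beam fails loudly", {
  bm <- flatModel()
  ps <- computePhaseSpace(bm, segment(makeSquareField(30), 100))
  ps@integralFluence <- 0
  expect_error(sampleParticles(ps, bm, 10, seed = 1), "empty beam")
})

test_that("particle records survive a text round trip", {
  bm <- flatModel()
  ps <- computePhaseSpace(bm, segment(makeSquareField(30), 100))
  p <- sampleParticles(ps, bm, 50, seed = 3)
  f <- tempfile(fileext = ".csv")
  writeParticles(p, f, quality = "flattened", seed = 3)
  q <- readParticles(f)
  expect_equal(q$x, p$x, tolerance = 1e-12)
  expect_equal(q$energy, p$energy)
})
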