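test_that("empty volume with noise and edges off reproduces the flat field", {
  att <- array(0, c(32, 32, 4))
  set <- simulateProjections(att, artifacts = quietArtifactModel(),
                             voxelSizeUm = 8)
  for (a in c(1, 90, 180))
    expect_identical(set@raw[, , a], set@flat)
})

test_that("zero photon flux leaves only dark statistics", {
  att <- diskVolume(16, 4, 5, 0.5)
  am <- quietArtifactModel(photonScale = 0)
  set <- simulateProjections(att, artifacts = am, voxelSizeUm = 8)
  expect_identical(set@raw[, , 1], set@dark)
})

test_that("disk transmission matches the analytic chord length within 1%", {
  R <- 16; mu <- 0.05; vox <- 8
  att <- diskVolume(64, 4, R, mu)
  set <- simulateProjections(att, artifacts = quietArtifactModel(),
                             voxelSizeUm = vox)
  stack <- correctProjections(set)
  sino <- assembleSinogram(stack, 2)
  central <- sino@values[1, 32:33]       # columns adjacent to the axis
  expect_lt(max(abs(central / (2 * R * mu * vox / 1000) - 1)), 0.01)
})

test_that("projector agrees with the brute-force ray-marching oracle", {
  set.seed(3)
  raw <- array(runif(32^3, 0, 1), c(32, 32, 32))
  ## box-smooth twice so the field varies on the voxel scale, not as noise
  sm <- raw
  for (pass in 1:2)
    for (z in 1:32) {
      m <- sm[, , z]
      sm[, , z] <- (m +
        m[c(1, 1:31), ] + m[c(2:32, 32), ] +
        m[, c(1, 1:31)] + m[, c(2:32, 32)]) / 5
    }
  set <- simulateProjections(sm, scanGeometry(anglesDeg = c(0, 37, 101),
                                              detectorShape = c(32L, 48L),
                                              pixelSizeUm = 10),
                             quietArtifactModel(), voxelSizeUm = 10)
  stack <- correctProjections(set)
  for (ai in 1:3) {
    sino <- assembleSinogram(stack, 16)
    for (col in c(18, 24, 30)) {
      oracle <- oracleRaySum(sm, c(0, 37, 101)[ai], col, 48, 10)[16]
      expect_lt(abs(sino@values[ai, col] - oracle), 0.02 * max(oracle, 1))
    }
  }
})

test_that("Poisson stage has the correct mean", {
  att <- array(0, c(2, 2, 2))
  lambda <- 4000
  vals <- vapply(1:1000, function(s) {
    am <- artifactModel(photonScale = lambda, darkOffsetCounts = 0,
                        darkNoiseSd = 0, flatRelief = 0,
                        edgeEnhanceStrength = 0, ringArtifactSd = 0,
                        poissonNoise = TRUE, rngSeed = s)
    set <- simulateProjections(att, scanGeometry(anglesDeg = 0,
                                                 detectorShape = c(2L, 2L),
                                                 pixelSizeUm = 8),
                               am, voxelSizeUm = 8)
    set@raw[1, 1, 1]
  }, numeric(1))
  se <- sqrt(lambda / 1000)
  expect_lt(abs(mean(vals) - lambda), 3 * se)
})

test_that("axis offset shifts projections by the stated amount", {
  att <- diskVolume(64, 4, 6, 0.5, center = c(40, 28))
  mk <- function(off) {
    g <- scanGeometry(anglesDeg = 0, detectorShape = c(4L, 64L),
                      axisOffsetPx = off, pixelSizeUm = 8)
    s <- simulateProjections(att, g, quietArtifactModel(), voxelSizeUm = 8)
    colMeans(correctProjections(s)@frames[, , 1])
  }
  p0 <- mk(0); p3 <- mk(3)
  lags <- -8:8
  cc <- vapply(lags, function(l) {
    j <- seq_along(p0); k <- j - l; ok <- k >= 1 & k <= length(p0)
    cor(p0[j[ok]], p3[k[ok]])
  }, numeric(1))
  ## projection of a fixed object moves opposite to the axis shift
  expect_identical(abs(lags[which.max(cc)]), 3L)
})

test_that("projection sets round-trip bit-identically through TIFF", {
  att <- diskVolume(32, 3, 8, 0.4)
  set <- simulateProjections(att, scanGeometry(anglesDeg = c(0, 45, 90, 135),
                                               detectorShape = c(3L, 32L),
                                               axisOffsetPx = 1.5,
                                               pixelSizeUm = 4.88),
                             artifactModel(rngSeed = 5), voxelSizeUm = 4.88)
  dir <- withr::local_tempdir()
  writeProjectionSet(set, dir)
  back <- readProjectionSet(dir)
  expect_identical(back@raw, set@raw)
  expect_identical(back@flat, set@flat)
  expect_identical(back@dark, set@dark)
  expect_equal(back@geometry@anglesDeg, set@geometry@anglesDeg)
  expect_equal(back@geometry@axisOffsetPx, 1.5)

  ## missing reference frames are reported by name
  file.remove(file.path(dir, "dark.tif"))
  expect_error(readProjectionSet(dir), "dark field absent")
  file.remove(file.path(dir, "flat.tif"))
  file.copy(file.path(dir, "proj_0000.tif"), file.path(dir, "dark.tif"))
  expect_error(readProjectionSet(dir), "flat field absent")

  ## frame count / angle count mismatch
  writeProjectionSet(set, dir)
  file.remove(file.path(dir, "proj_0002.tif"))
  expect_error(readProjectionSet(dir), "does not match angle count")
})

test_that("a volume wider than the detector is rejected with the overflow", {
  att <- diskVolume(64, 2, 28, 0.1)
  g <- scanGeometry(anglesDeg = 0:1, detectorShape = c(2L, 40L),
                    pixelSizeUm = 8)
  expect_error(simulateProjections(att, g, quietArtifactModel(),
                                   voxelSizeUm = 8), "px beyond the detector")
})

test_that("simulation is reproducible for a fixed seed", {
  att <- diskVolume(32, 4, 8, 0.3)
  g <- scanGeometry(anglesDeg = seq(0, 170, by = 10),
                    detectorShape = c(4L, 32L), pixelSizeUm = 8)
  s1 <- simulateProjections(att, g, artifactModel(rngSeed = 9),
                            voxelSizeUm = 8)
  s2 <- simulateProjections(att, g, artifactModel(rngSeed = 9),
                            voxelSizeUm = 8)
  expect_identical(s1@raw, s2@raw)
  s3 <- simulateProjections(att, g, artifactModel(rngSeed = 10),
                            voxelSizeUm = 8)
  expect_false(identical(s1@raw, s3@raw))
})
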