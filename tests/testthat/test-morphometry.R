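test_that("polyline length converts pixels with the calibration factor", {
  pts <- rbind(c(0, 0, 0), c(3, 4, 0))
  len <- polylineLength(pts, 1.22)
  expect_equal(len[["px"]], 5)
  expect_equal(len[["um"]], 6.10)
  expect_equal(polylineLength(matrix(c(1, 2, 3), 1, 3))[["um"]], 0)
  cl <- centerline(pts, 1.22)
  expect_equal(polylineLength(cl)[["mm"]], 6.10e-3)
})

test_that("polyline length is rigid-motion invariant", {
  set.seed(31)
  pts <- matrix(rnorm(45), 15, 3)
  base <- polylineLength(pts, 2.44)[["um"]]
  for (i in 1:8) {
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    moved <- pts %*% Q + matrix(rnorm(3, sd = 50), 15, 3, byrow = TRUE)
    expect_lt(abs(polylineLength(moved, 2.44)[["um"]] / base - 1), 1e-9)
  }
})

test_that("tangent frames follow straight lines, circles and helices", {
  z <- cbind(0, 0, seq(0, 10, by = 0.5))
  fr <- tangentFrames(z)
  expect_equal(fr$tangent, matrix(rep(c(0, 0, 1), each = nrow(z)),
                                  ncol = 3), tolerance = 1e-12)
  ## planar circle: tangents perpendicular to the radius
  th <- seq(0, 2 * pi, length.out = 100)
  circ <- cbind(cos(th), sin(th), 0)
  fc <- tangentFrames(circ)
  dots <- abs(rowSums(fc$tangent * circ))
  expect_lt(max(dots[2:98]), 1e-6)
  ## helix: analytic tangent z-component
  R <- 5; pitch <- 2
  t <- seq(0, 4 * pi, length.out = 400)
  helix <- cbind(R * cos(t), R * sin(t), pitch * t / (2 * pi))
  fh <- tangentFrames(helix)
  tzExpected <- (pitch / (2 * pi)) / sqrt(R^2 + (pitch / (2 * pi))^2)
  expect_lt(max(abs(fh$tangent[10:390, 3] - tzExpected)), 1e-3)
  ## frames stay orthonormal under parallel transport
  expect_lt(max(abs(rowSums(fh$normal * fh$tangent))), 1e-9)
  expect_lt(max(abs(rowSums(fh$normal * fh$binormal))), 1e-9)
  ## coincident points are named
  expect_error(tangentFrames(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))),
               "indices 1")
})

test_that("cross-section area matches a straight tube oracle", {
  n <- 48
  lab <- array(0L, c(n, n, n))
  c0 <- (n + 1) / 2
  for (x in 1:n) for (y in 1:n)
    if ((x - c0)^2 + (y - c0)^2 <= 10^2) lab[x, y, ] <- 2L
  lv <- new("LabelVolume", labels = lab, legend = cochlearLegend(),
            voxelSizeUm = 1, provenance = list())
  basis <- list(normal = c(1, 0, 0), binormal = c(0, 1, 0))
  center <- c(c0 - 0.5, c0 - 0.5, n / 2)
  m <- crossSectionArea(lv, center, basis, "st", planeExtentUm = 16,
                        sampleSpacingUm = 0.5)
  expect_lt(abs(m$area_mm2 * 1e6 / (pi * 100) - 1), 0.03)
  ## refining the sampling changes the estimate by < 1%
  m2 <- crossSectionArea(lv, center, basis, "st", planeExtentUm = 16,
                         sampleSpacingUm = 0.25)
  expect_lt(abs(m2$area_mm2 / m$area_mm2 - 1), 0.01)
  ## absent compartment: zero and valid
  sv <- crossSectionArea(lv, center, basis, "sv", planeExtentUm = 16,
                         sampleSpacingUm = 0.5)
  expect_equal(sv$area_mm2, 0)
  expect_true(sv$valid)
  ## unknown compartment
  expect_error(crossSectionArea(lv, center, basis, "nerve", 16), "compartment")
  ## sampling coarser than the voxel size is refused
  expect_error(crossSectionArea(lv, center, basis, "st", 16,
                                sampleSpacingUm = 2), "voxel")
})

test_that("sections truncated by the field of view are flagged", {
  lab <- array(0L, c(32, 32, 8))
  lab[1:10, 10:20, ] <- 2L                   # touches the x = 1 face
  lv <- new("LabelVolume", labels = lab, legend = cochlearLegend(),
            voxelSizeUm = 1, provenance = list())
  m <- crossSectionArea(lv, c(3, 15, 4),
                        list(normal = c(1, 0, 0), binormal = c(0, 1, 0)),
                        "st", planeExtentUm = 12, sampleSpacingUm = 0.5)
  expect_false(m$valid)
  expect_identical(m$reason, "fov")
  ## away from the border the same section is valid
  m2 <- crossSectionArea(lv, c(6, 15, 4),
                         list(normal = c(0, 1, 0), binormal = c(0, 0, 1)),
                         "st", planeExtentUm = 3, sampleSpacingUm = 0.5)
  expect_true(m2$valid)
})

test_that("area profile of an empty volume is zero everywhere and valid", {
  lv <- new("LabelVolume", labels = array(0L, c(24, 24, 24)),
            legend = cochlearLegend(), voxelSizeUm = 2,
            provenance = list())
  pts <- cbind(24, 24, seq(6, 40, by = 2))
  p <- areaProfile(lv, pts, c("st", "sm"), stepMm = 0.005,
                   planeExtentUm = 10)
  expect_true(all(p$area_mm2 == 0))
  expect_true(all(p$valid))
})

test_that("profile on phantom truth labels matches the analytic design", {
  pv <- cachedDefaultPhantom()
  lv <- new("LabelVolume", labels = tissueLabels(pv),
            legend = cochlearLegend(), voxelSizeUm = voxelSize(pv),
            provenance = list())
  prof <- areaProfile(lv, pv@centerlineTruth, stepMm = 0.1)
  for (nm in c("st", "sm", "sv")) {
    p <- prof[prof$compartment == nm & prof$valid, ]
    f <- areaProfileFun(pv@spec, nm)
    expected <- f(pmin(p$arc_mm / 6.67, 1))
    expect_lt(max(abs(p$area_mm2 - expected) / expected), 0.05)
  }
  ## strictly decreasing design -> smoothed measurement non-increasing
  st <- prof[prof$compartment == "st" & prof$valid, ]
  st <- st[order(st$arc_mm), ]
  sm3 <- stats::runmed(st$area_mm2, 3)
  expect_true(all(diff(sm3) <= 1e-12))
})

test_that("ridge landmarks reproduce the centerline they were guided by", {
  pv <- cachedDefaultPhantom()
  lv <- new("LabelVolume", labels = tissueLabels(pv),
            legend = cochlearLegend(), voxelSizeUm = voxelSize(pv),
            provenance = list())
  guide <- pv@centerlineTruth[seq(1, nrow(pv@centerlineTruth),
                                  length.out = 60), ]
  lm <- extractRidgeLandmarks(lv, guide, searchRadiusUm = 40)
  expect_identical(nrow(lm), 60L)
  d <- sqrt(rowSums((lm - guide)^2))
  expect_lt(max(d), 2.5 * voxelSize(pv))   # ridge centroid sits just above the centerline
  len <- polylineLength(lm / voxelSize(pv), voxelSize(pv))[["mm"]]
  expect_lt(abs(len - 6.67) / 6.67, 0.01)
})
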