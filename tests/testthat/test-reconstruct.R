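## helper: line integrals of a 2-D image via the forward projector
radon2d <- function(img, anglesDeg, nCols = nrow(img)) {
  vol <- array(img, c(dim(img), 1))
  proj <- cochleaCT:::cpp_project_volume(
    as.double(aperm(vol, c(3, 1, 2))), nrow(img), ncol(img), 1L,
    anglesDeg * pi / 180, as.integer(nCols), 0, 0.5,
    sqrt(2) / 2 * nrow(img) + 1, 1)
  t(proj[1, , ])                                # angles x columns
}

test_that("sinogram assembly applies the clamped log transform", {
  frames <- array(65536, c(3, 4, 2))
  frames[2, 1, ] <- 65536 / exp(1)
  frames[2, 2, ] <- 0                           # clamps to 1 count
  stack <- new("CorrectedStack", frames = frames, anglesDeg = c(0, 90),
               axisOffsetPx = 0, pixelSizeUm = 8, binned = FALSE)
  sino <- assembleSinogram(stack, 2)
  expect_equal(sino@values[1, 1], 1)
  expect_equal(sino@values[1, 2], log(65536))
  expect_equal(sino@values[1, 3], 0)
  expect_error(assembleSinogram(stack, 9), "out of range")
  ## disabling the log reconstructs transmission directly
  expect_equal(assembleSinogram(stack, 2, applyLog = FALSE)@values[1, 3], 1)
})

test_that("an all-zero sinogram reconstructs to an all-zero slice", {
  sino <- new("Sinogram", values = matrix(0, 90, 32),
              anglesDeg = seq(0, 178, by = 2), axisOffsetPx = 0,
              pixelSizeUm = 8)
  expect_equal(fbpSlice(sino), matrix(0, 32, 32))
})

test_that("angle checks reject degenerate sets", {
  sino <- new("Sinogram", values = matrix(0, 1, 16), anglesDeg = 0,
              axisOffsetPx = 0, pixelSizeUm = 8)
  expect_error(fbpSlice(sino), "at least 2 angles")
  sino2 <- new("Sinogram", values = matrix(0, 3, 16),
               anglesDeg = c(0, 10, 50), axisOffsetPx = 0, pixelSizeUm = 8)
  expect_error(fbpSlice(sino2), "non-uniform")
})

test_that("FBP is linear", {
  set.seed(5)
  v1 <- matrix(runif(45 * 32), 45, 32)
  v2 <- matrix(runif(45 * 32), 45, 32)
  mk <- function(v) new("Sinogram", values = v,
                        anglesDeg = seq(0, 176, by = 4), axisOffsetPx = 0,
                        pixelSizeUm = 8)
  lhs <- fbpSlice(mk(2 * v1 - 0.5 * v2))
  rhs <- 2 * fbpSlice(mk(v1)) - 0.5 * fbpSlice(mk(v2))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("offset compensation removes tuning-fork artifacts", {
  c0 <- (128 + 1) / 2
  r <- sqrt(outer((1:128 - c0)^2, (1:128 - c0)^2, "+"))
  ann <- r >= 24 & r <= 56
  sino <- diskSinogram(128, 180, 16, 0.01, axisOffsetPx = 4)
  good <- fbpSlice(sino)
  bad <- fbpSlice(sino, compensateOffset = FALSE)
  expect_lt(abs(mean(good[r <= 12]) / 0.01 - 1), 0.05)
  expect_gt(sd(bad[ann]), 3 * sd(good[ann]))
})

test_that("projection-domain round trip is consistent", {
  ## smooth test image: sum of Gaussian blobs
  n <- 64
  g <- function(cx, cy, s, a) {
    x <- outer(1:n - cx, rep(1, n)); y <- outer(rep(1, n), 1:n - cy)
    a * exp(-(x^2 + y^2) / (2 * s^2))
  }
  img <- g(30, 34, 6, 1) + g(42, 24, 4, 0.6) + g(24, 44, 9, 0.4)
  angles <- 0:179
  S <- radon2d(img, angles)
  rec <- fbpSlice(new("Sinogram", values = S, anglesDeg = angles,
                      axisOffsetPx = 0, pixelSizeUm = 8))
  S2 <- radon2d(rec, angles)
  expect_lt(sqrt(sum((S2 - S)^2) / sum(S^2)), 0.05)
})

test_that("reconstructing a symmetric sinogram gives a symmetric slice", {
  sino <- diskSinogram(96, 180, 20, 0.02)
  sl <- fbpSlice(sino)
  c0 <- (96 + 1) / 2
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  radial <- vapply(seq(2, 40, by = 2), function(rr) {
    vals <- vapply(th, function(a) {
      x <- c0 + rr * cos(a); y <- c0 + rr * sin(a)
      sl[round(x), round(y)]
    }, numeric(1))
    c(var(vals), mean(vals)^2)
  }, numeric(2))
  expect_lt(sum(radial[1, ]), 0.01 * sum(radial[2, ]))
})

test_that("volume reconstruction stacks rows consistently", {
  att <- diskVolume(64, 6, 14, 0.25)
  set <- simulateProjections(att, artifacts = quietArtifactModel(),
                             voxelSizeUm = 8)
  stack <- correctProjections(set)
  ## single-row volume equals the slice reconstruction (module scale)
  vol1 <- reconstructVolume(stack, rows = 3)
  sl <- fbpSlice(assembleSinogram(stack, 3)) / (8 / 1000)
  expect_equal(vol1@values[, , 1], sl, tolerance = 1e-12)
  ## an axis-aligned cylinder gives identical slices
  vol <- reconstructVolume(stack, rows = 2:5)
  mid <- vol@values[, , 1]
  disk <- mean(mid[diskVolume(64, 1, 12, 1)[, , 1] > 0])
  for (k in 2:4) {
    rms <- sqrt(mean((vol@values[, , k] - mid)^2))
    expect_lt(rms, 0.01 * disk)
  }
  ## all-zero stack reconstructs to zero
  z <- new("CorrectedStack",
           frames = array(65536, c(2, 16, 4)),
           anglesDeg = c(0, 45, 90, 135), axisOffsetPx = 0,
           pixelSizeUm = 8, binned = FALSE)
  expect_equal(max(abs(reconstructVolume(z)@values)), 0)
})

test_that("attenuation class means survive the full forward model", {
  pv <- buildPhantom(phantomSpec(voxelSizeUm = 16,
                                 gridShape = c(128, 128, 128)))
  set <- simulateProjections(pv, artifacts = quietArtifactModel())
  rec <- reconstructVolume(correctProjections(set))
  for (cd in c(1L, 2L, 5L)) {
    truth <- pv@spec@attenuationMap[[as.character(cd)]]
    m <- mean(volumeValues(rec)[tissueLabels(pv) == cd])
    expect_lt(abs(m / truth - 1), 0.10)
  }
})
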