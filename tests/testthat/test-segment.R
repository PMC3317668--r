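test_that("threshold rule assigns the boundary value to Interior", {
  vol <- array(c(0.1, 0.5, 0.5, 0.9), c(2, 2, 1))
  lab <- thresholdSegment(vol, 0.5)
  expect_identical(as.vector(tissueLabels(lab)), c(0L, 1L, 1L, 1L))
  expect_identical(sum(tissueLabels(thresholdSegment(vol, 1.0))), 0L)
  expect_identical(provenance(lab)$threshold, 0.5)
})

test_that("thresholding is monotone in the threshold", {
  set.seed(13)
  vol <- array(runif(8^3), c(8, 8, 8))
  prev <- tissueLabels(thresholdSegment(vol, 0))
  for (t in c(0.2, 0.5, 0.8, 1.1)) {
    cur <- tissueLabels(thresholdSegment(vol, t))
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("Otsu auto-threshold separates a bimodal volume", {
  set.seed(17)
  vol <- array(c(rnorm(4000, 0.1, 0.02), rnorm(4000, 0.9, 0.02)),
               c(20, 20, 20))
  lab <- thresholdSegment(vol, "auto")
  th <- provenance(lab)$threshold
  expect_gt(th, 0.2); expect_lt(th, 0.8)
  expect_equal(sum(tissueLabels(lab)), sum(vol >= th))
  expect_error(thresholdSegment(array(1, c(4, 4, 4)), "auto"),
               "degenerate histogram")
})

test_that("couch removal keeps only the largest component", {
  m <- array(0L, c(16, 8, 8))
  m[2:3, 2:3, 2:3] <- 1L       # 8 voxels
  m[8:10, 2:6, 2:6] <- 1L      # 75 voxels
  bin <- new("LabelVolume", labels = m, legend = interiorLegend(),
             voxelSizeUm = 1, provenance = list())
  kept <- keepLargestComponent(bin)
  expect_identical(sum(tissueLabels(kept)), 75L)
  expect_identical(sum(tissueLabels(kept)[2:3, 2:3, 2:3]), 0L)
  ## idempotent
  expect_identical(tissueLabels(keepLargestComponent(kept)),
                   tissueLabels(kept))
  ## empty interior warns and returns all-exterior
  empty <- new("LabelVolume", labels = array(0L, c(4, 4, 4)),
               legend = interiorLegend(), voxelSizeUm = 1,
               provenance = list())
  expect_warning(out <- keepLargestComponent(empty), "no interior")
  expect_identical(sum(tissueLabels(out)), 0L)
  expect_error(keepLargestComponent(bin, connectivity = 17),
               "connectivity")
})

test_that("connectivity setting decides diagonal coherence", {
  m <- array(0L, c(6, 6, 2))
  m[1:2, 1:2, 1] <- 1L
  m[3:4, 3:4, 1] <- 1L          # corner-touching second block
  m[6, 6, 2] <- 1L              # isolated single voxel
  bin <- new("LabelVolume", labels = m, legend = interiorLegend(),
             voxelSizeUm = 1, provenance = list())
  expect_identical(sum(tissueLabels(keepLargestComponent(bin, 26))), 8L)
  expect_identical(sum(tissueLabels(keepLargestComponent(bin, 6))), 4L)
})

test_that("size ties go to the component with the smallest linear index", {
  m <- array(0L, c(12, 4, 4))
  m[9:10, 3:4, 3:4] <- 1L      # later in raster order
  m[1:2, 1:2, 1:2] <- 1L       # contains voxel (1,1,1)
  bin <- new("LabelVolume", labels = m, legend = interiorLegend(),
             voxelSizeUm = 1, provenance = list())
  kept <- keepLargestComponent(bin)
  expect_identical(tissueLabels(kept)[1, 1, 1], 1L)
  expect_identical(sum(tissueLabels(kept)[9:10, 3:4, 3:4]), 0L)
})

test_that("propagation reproduces annotated slices and copies past ends", {
  disk <- function(r, n = 32, c0 = 16.5) {
    m <- matrix(0L, n, n)
    m[(row(m) - c0)^2 + (col(m) - c0)^2 <= r^2] <- 2L
    m
  }
  ## identical annotations propagate unchanged through the gap
  sparse <- list(list(slice = 1, labels = disk(6)),
                 list(slice = 11, labels = disk(6)))
  out <- propagateLabels(sparse, c(32L, 32L, 12L))
  for (z in 1:11)
    expect_identical(tissueLabels(out)[, , z], disk(6))
  expect_identical(tissueLabels(out)[, , 12], disk(6))  # copy beyond range
  ## a single annotated slice fills the whole stack
  one <- propagateLabels(list(list(slice = 3, labels = disk(5))),
                         c(32L, 32L, 5L))
  for (z in 1:5) expect_identical(tissueLabels(one)[, , z], disk(5))
})

test_that("signed-distance interpolation grows concentric disks linearly", {
  disk <- function(r, n = 32, c0 = 16.5) {
    m <- matrix(0L, n, n)
    m[(row(m) - c0)^2 + (col(m) - c0)^2 <= r^2] <- 2L
    m
  }
  sparse <- list(list(slice = 1, labels = disk(4)),
                 list(slice = 9, labels = disk(8)))
  out <- propagateLabels(sparse, c(32L, 32L, 9L))
  mid <- tissueLabels(out)[, , 5]
  rMid <- sqrt(sum(mid == 2L) / pi)
  expect_lt(abs(rMid - 6), 1)
})

test_that("conflicting legends between annotated slices are rejected", {
  m <- matrix(0L, 8, 8)
  sparse <- list(list(slice = 1, labels = m, legend = c(`0` = "bg")),
                 list(slice = 4, labels = m, legend = c(`0` = "air")))
  expect_error(propagateLabels(sparse, c(8L, 8L, 4L)), "conflicting legends")
})

test_that("manual corrections replace only flagged voxels", {
  lab <- new("LabelVolume",
             labels = array(1L, c(4, 4, 3)), legend = cochlearLegend(),
             voxelSizeUm = 1, provenance = list())
  noop <- matrix(NA_integer_, 4, 4)
  expect_identical(tissueLabels(applyManualCorrections(
    lab, list(list(slice = 2, overlay = noop)))), tissueLabels(lab))
  ov <- noop; ov[2, 3] <- 3L
  out <- applyManualCorrections(lab, list(list(slice = 2, overlay = ov)))
  expect_identical(sum(tissueLabels(out) != tissueLabels(lab)), 1L)
  expect_identical(tissueLabels(out)[2, 3, 2], 3L)
  expect_identical(provenance(out)$editedVoxels, 1L)
  bad <- noop; bad[1, 1] <- 99L
  expect_error(applyManualCorrections(
    lab, list(list(slice = 1, overlay = bad))), "99")
})

test_that("threshold + couch removal recover a phantom's foreground", {
  ## uniform-attenuation duct: the air/specimen histogram is bimodal, so
  ## the Otsu sentinel lands in the air-tissue gap
  spec <- cylinderSpec(attenuationMap = c(`0` = 0, `1` = 0.5, `2` = 0.5,
                                          `3` = 0.5, `4` = 0.5, `5` = 0.5,
                                          `6` = 0.5),
                       gridShape = c(96, 96, 96), voxelSizeUm = 10)
  pv <- buildPhantom(spec)
  set <- simulateProjections(pv, artifacts = quietArtifactModel())
  rec <- reconstructVolume(correctProjections(set))
  interior <- keepLargestComponent(thresholdSegment(rec, "auto"))
  fg <- sum(tissueLabels(pv) != 0L)
  expect_lt(abs(sum(tissueLabels(interior)) / fg - 1), 0.10)
})
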