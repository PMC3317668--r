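## Parallel-beam acquisition simulator.
##
## Forward model per angle: line integrals of attenuation along parallel
## rays (bilinear resampling in the volume frame, 0.5-voxel steps), then
## transmitted intensity photonScale * flatProfile * columnGain *
## exp(-integral), an optional Laplacian edge-enhancement term standing in
## for near-field in-line phase contrast, Poisson photon noise, dark offset
## plus Gaussian dark noise, and 16-bit quantization (round-half-to-even,
## clipped to [0, 65535]).

#' Construct a scan geometry
#'
#' @param anglesDeg strictly increasing angles in \[0, 180); default the
#'   printed protocol, 180 projections at 1 degree increments.
#' @param detectorShape integer (rows, columns).
#' @param axisOffsetPx signed rotation-axis offset from the detector center
#'   (columns, sub-pixel allowed).
#' @param pixelSizeUm detector pixel pitch (um).
#' @return a [ScanGeometry-class].
#' @export
scanGeometry <- function(anglesDeg = 0:179, detectorShape,
                         axisOffsetPx = 0, pixelSizeUm = 8) {
  new("ScanGeometry", anglesDeg = as.numeric(anglesDeg),
      detectorShape = as.integer(detectorShape),
      axisOffsetPx = axisOffsetPx, pixelSizeUm = pixelSizeUm)
}

#' Construct a detector/beam artifact model
#'
#' Defaults emulate the qualitative artifacts visible in synchrotron
#' phase-contrast scans (granular background noise, faint ring/line
#' artifacts, edge-enhanced interfaces); they are testing placeholders, not
#' physical estimates.
#'
#' @param photonScale expected counts at unity transmission.
#' @param darkOffsetCounts mean dark-field offset (counts).
#' @param darkNoiseSd Gaussian dark noise sd (counts).
#' @param flatRelief amplitude of the smooth illumination profile.
#' @param edgeEnhanceStrength Laplacian edge-enhancement weight (0 = off).
#' @param ringArtifactSd sd of fixed per-column multiplicative gain jitter.
#' @param poissonNoise apply Poisson photon noise?
#' @param rngSeed integer seed.
#' @return an [ArtifactModel-class].
#' @export
artifactModel <- function(photonScale = 20000, darkOffsetCounts = 100,
                          darkNoiseSd = 2, flatRelief = 0.15,
                          edgeEnhanceStrength = 0.3, ringArtifactSd = 0.005,
                          poissonNoise = TRUE, rngSeed = 1L) {
  new("ArtifactModel", photonScale = photonScale,
      darkOffsetCounts = darkOffsetCounts, darkNoiseSd = darkNoiseSd,
      flatRelief = flatRelief, edgeEnhanceStrength = edgeEnhanceStrength,
      ringArtifactSd = ringArtifactSd, poissonNoise = poissonNoise,
      rngSeed = as.integer(rngSeed))
}

#' Noise-free artifact model
#'
#' All stochastic and phase-contrast terms disabled; useful for oracle
#' comparisons against analytic forward models.
#'
#' @param photonScale expected counts at unity transmission.
#' @param darkOffsetCounts mean dark offset.
#' @return an [ArtifactModel-class] with every artifact switched off.
#' @export
quietArtifactModel <- function(photonScale = 20000, darkOffsetCounts = 100)
  artifactModel(photonScale = photonScale,
                darkOffsetCounts = darkOffsetCounts, darkNoiseSd = 0,
                flatRelief = 0, edgeEnhanceStrength = 0, ringArtifactSd = 0,
                poissonNoise = FALSE)

## smooth multiplicative illumination field (deterministic given shape)
flatProfileMatrix <- function(rows, cols, relief) {
  if (relief == 0) return(matrix(1, rows, cols))
  r <- (seq_len(rows) - (rows + 1) / 2) / rows
  c <- (seq_len(cols) - (cols + 1) / 2) / cols
  1 - relief * (outer(r^2, c^2, "+") * 2 + 0.2 * outer(rep(0, rows), c, "+") + 0.5 * outer(r^2, rep(0, cols), "+"))
}

## 4-neighbour discrete Laplacian with replicated borders
laplacian <- function(img) {
  up <- img[c(1, seq_len(nrow(img) - 1)), , drop = FALSE]
  dn <- img[c(seq_len(nrow(img) - 1) + 1, nrow(img)), , drop = FALSE]
  lf <- img[, c(1, seq_len(ncol(img) - 1)), drop = FALSE]
  rt <- img[, c(seq_len(ncol(img) - 1) + 1, ncol(img)), drop = FALSE]
  up + dn + lf + rt - 4 * img
}

quantize16 <- function(x) {
  x <- round(x)                     # round-half-to-even
  x[x < 0] <- 0
  x[x > 65535] <- 65535
  x
}

#' Simulate a projection acquisition of a phantom
#'
#' @param volume a [PhantomVolume-class], or a numeric 3-D attenuation array
#'   (mm^-1) with `voxelSizeUm` supplied.
#' @param geometry a [ScanGeometry-class]; by default one detector row per
#'   volume slice, one column per x voxel, axis centered.
#' @param artifacts an [ArtifactModel-class].
#' @param voxelSizeUm voxel size when `volume` is a bare array.
#' @return a [ProjectionSet-class].
#' @export
simulateProjections <- function(volume, geometry = NULL,
                                artifacts = artifactModel(),
                                voxelSizeUm = NULL) {
  if (is(volume, "PhantomVolume")) {
    att <- volume@attenuation
    voxelSizeUm <- volume@voxelSizeUm
  } else {
    att <- volume
    if (is.null(voxelSizeUm)) stop("voxelSizeUm required for a bare array")
  }
  d <- dim(att)
  if (is.null(geometry))
    geometry <- scanGeometry(detectorShape = c(d[3], d[1]),
                             pixelSizeUm = voxelSizeUm)
  validObject(geometry); validObject(artifacts)
  rows <- geometry@detectorShape[1]; cols <- geometry@detectorShape[2]
  if (rows != d[3])
    stop("detector rows (", rows, ") must equal volume z extent (", d[3], ")")

  ## content radius about the rotation axis, in voxels
  fgXY <- matrix(rowSums(matrix(att != 0, d[1] * d[2], d[3])) > 0, d[1], d[2])
  if (any(fgXY)) {
    idx <- which(fgXY, arr.ind = TRUE)
    rMax <- sqrt(max((idx[, 1] - (d[1] + 1) / 2)^2 +
                     (idx[, 2] - (d[2] + 1) / 2)^2))
  } else rMax <- 0
  over <- rMax + abs(geometry@axisOffsetPx) - (cols / 2 - 1)
  if (over > 0)
    stop(sprintf("volume extends %d px beyond the detector", ceiling(over)))

  proj <- cpp_project_volume(
    as.double(aperm(att, c(3, 1, 2))), d[1], d[2], d[3],
    geometry@anglesDeg * pi / 180, cols, geometry@axisOffsetPx,
    stepVox = 0.5, rMaxVox = rMax + 2, voxScale = voxelSizeUm / 1000)

  nA <- length(geometry@anglesDeg)
  flatProf <- flatProfileMatrix(rows, cols, artifacts@flatRelief)
  withr::local_seed(stageSeed(artifacts@rngSeed, "rings"))
  gain <- if (artifacts@ringArtifactSd > 0)
    exp(rnorm(cols, 0, artifacts@ringArtifactSd)) else rep(1, cols)
  beam <- artifacts@photonScale * flatProf *
    matrix(gain, rows, cols, byrow = TRUE)

  withr::local_seed(stageSeed(artifacts@rngSeed, "project"))
  raw <- array(0, dim = c(rows, cols, nA))
  for (a in seq_len(nA)) {
    ideal <- beam * exp(-proj[, , a])
    if (artifacts@edgeEnhanceStrength > 0) {
      ideal <- ideal - artifacts@edgeEnhanceStrength * laplacian(ideal)
      ideal[ideal < 0] <- 0
    }
    if (artifacts@poissonNoise)
      ideal <- array(rpois(length(ideal), ideal), dim = dim(ideal))
    if (artifacts@darkNoiseSd > 0)
      ideal <- ideal + rnorm(length(ideal), 0, artifacts@darkNoiseSd)
    raw[, , a] <- quantize16(ideal + artifacts@darkOffsetCounts)
  }

  withr::local_seed(stageSeed(artifacts@rngSeed, "flat"))
  flatI <- beam
  if (artifacts@poissonNoise)
    flatI <- matrix(rpois(length(flatI), flatI), rows, cols)
  if (artifacts@darkNoiseSd > 0)
    flatI <- flatI + rnorm(length(flatI), 0, artifacts@darkNoiseSd)
  flat <- quantize16(flatI + artifacts@darkOffsetCounts)

  withr::local_seed(stageSeed(artifacts@rngSeed, "dark"))
  darkI <- matrix(artifacts@darkOffsetCounts, rows, cols)
  if (artifacts@darkNoiseSd > 0)
    darkI <- darkI + rnorm(length(darkI), 0, artifacts@darkNoiseSd)
  dark <- quantize16(darkI)

  new("ProjectionSet", raw = raw, flat = flat, dark = dark,
      geometry = geometry)
}

#' Write / read a projection set as numbered 16-bit TIFFs
#'
#' Frames round-trip bit-identically; geometry travels in a YAML sidecar.
#'
#' @param set a [ProjectionSet-class].
#' @param dir directory (created if missing).
#' @return `writeProjectionSet`: `dir` invisibly. `readProjectionSet`: the
#'   restored [ProjectionSet-class].
#' @export
writeProjectionSet <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nA <- dim(set@raw)[3]
  for (a in seq_len(nA))
    tiff::writeTIFF(set@raw[, , a] / 65535,
                    file.path(dir, sprintf("proj_%04d.tif", a - 1L)),
                    bits.per.sample = 16L)
  tiff::writeTIFF(set@flat / 65535, file.path(dir, "flat.tif"),
                  bits.per.sample = 16L)
  tiff::writeTIFF(set@dark / 65535, file.path(dir, "dark.tif"),
                  bits.per.sample = 16L)
  g <- set@geometry
  yaml::write_yaml(list(angles_deg = as.numeric(g@anglesDeg),
                        detector_shape = as.integer(g@detectorShape),
                        axis_offset_px = g@axisOffsetPx,
                        pixel_size_um = g@pixelSizeUm),
                   file.path(dir, "metadata.yaml"))
  invisible(dir)
}

#' @rdname writeProjectionSet
#' @export
readProjectionSet <- function(dir) {
  meta <- file.path(dir, "metadata.yaml")
  if (!file.exists(meta)) stop("metadata.yaml absent in ", dir)
  m <- yaml::read_yaml(meta)
  if (!file.exists(file.path(dir, "flat.tif"))) stop("flat field absent")
  if (!file.exists(file.path(dir, "dark.tif"))) stop("dark field absent")
  files <- sort(list.files(dir, pattern = "^proj_\\d+\\.tif$",
                           full.names = TRUE))
  if (length(files) != length(m$angles_deg))
    stop("frame count (", length(files), ") does not match angle count (",
         length(m$angles_deg), ")")
  rd <- function(f) round(tiff::readTIFF(f) * 65535)
  frames <- vapply(files, rd, matrix(0, m$detector_shape[1],
                                     m$detector_shape[2]))
  dim(frames) <- c(m$detector_shape[1], m$detector_shape[2], length(files))
  new("ProjectionSet", raw = frames,
      flat = rd(file.path(dir, "flat.tif")),
      dark = rd(file.path(dir, "dark.tif")),
      geometry = scanGeometry(m$angles_deg, m$detector_shape,
                              m$axis_offset_px, m$pixel_size_um))
}
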