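## S4 containers for the tomography pipeline.
##
## Conventions used throughout:
##  * volumes are numeric/integer arrays indexed [x, y, z]; voxel (i,j,k)
##    (1-based) has its center at ((i-0.5), (j-0.5), (k-0.5)) * voxelSizeUm
##    in world coordinates (um);
##  * detector frames are matrices [row, column]; row r of every frame maps
##    to reconstructed slice z = r;
##  * angles are degrees in [0, 180), strictly increasing;
##  * physical lengths are um or mm, never bare pixels, except where a
##    quantity is defined per pixel (calibration factors, axis offsets).

#' Parametric description of a spiral cochlea phantom
#'
#' Describes a three-channel (scala tympani / media / vestibuli) spiral duct
#' with piecewise-linear cross-sectional area profiles, from which a label
#' volume with exactly known centerline length and area ground truth can be
#' rasterized with [buildPhantom()].
#'
#' @slot nTurns number of spiral revolutions (0 gives a straight vertical duct).
#' @slot centerlineLengthMm design arc length of the pillar-head ridge (mm);
#'   the generated curve is rescaled so its analytic length matches exactly.
#' @slot baseRadiusMm,apexRadiusMm nominal spiral radii (mm) at base/apex;
#'   radius is log-interpolated between them.
#' @slot pitchMm nominal axial rise per turn (mm).
#' @slot areaAnchors named list (`st`, `sm`, `sv`) of two-column matrices
#'   (normalized arc position s in \[0,1\], area mm^2); areas are linearly
#'   interpolated between anchors.
#' @slot membraneThicknessUm thickness of the separating membranes (um).
#' @slot wallThicknessUm thickness of the enclosing bony wall (um).
#' @slot aspectRatio width:height ratio of the elliptical channel sections.
#' @slot ridgeRadiusUm radius of the organ-of-Corti ridge tube (um).
#' @slot overhangMm extra duct length beyond both ends of the measured
#'   centerline (mm), so end stations have full sections.
#' @slot attenuationMap named numeric, label code -> attenuation (mm^-1).
#' @slot voxelSizeUm isotropic voxel edge (um).
#' @slot gridShape integer voxel counts per axis.
#' @export
setClass("PhantomSpec", representation(
  nTurns = "numeric", centerlineLengthMm = "numeric",
  baseRadiusMm = "numeric", apexRadiusMm = "numeric", pitchMm = "numeric",
  areaAnchors = "list", membraneThicknessUm = "numeric",
  wallThicknessUm = "numeric", aspectRatio = "numeric",
  ridgeRadiusUm = "numeric", overhangMm = "numeric",
  attenuationMap = "numeric", voxelSizeUm = "numeric",
  gridShape = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@centerlineLengthMm <= 0)
    msg <- c(msg, "centerlineLengthMm must be > 0")
  if (!all(c("st", "sm", "sv") %in% names(object@areaAnchors)))
    msg <- c(msg, "areaAnchors must contain 'st', 'sm', 'sv'")
  for (nm in intersect(c("st", "sm", "sv"), names(object@areaAnchors))) {
    a <- object@areaAnchors[[nm]]
    if (!is.matrix(a) || ncol(a) != 2 || any(a[, 2] <= 0))
      msg <- c(msg, sprintf("area anchors for '%s' must be a 2-column matrix with strictly positive areas", nm))
  }
  if (object@nTurns < 0) msg <- c(msg, "nTurns must be >= 0")
  if (object@voxelSizeUm <= 0) msg <- c(msg, "voxelSizeUm must be > 0")
  if (length(object@gridShape) != 3L || any(object@gridShape < 8L))
    msg <- c(msg, "gridShape must be three integers >= 8")
  if (length(msg)) msg else TRUE
})

#' Voxelized cochlea phantom with analytic ground truth
#'
#' @slot labels integer array \[x,y,z\]: 0 exterior, 1 bone/wall, 2 scala
#'   tympani, 3 scala media, 4 scala vestibuli, 5 membranes, 6 organ-of-Corti
#'   ridge.
#' @slot attenuation numeric array of the same shape (mm^-1).
#' @slot voxelSizeUm isotropic voxel edge (um).
#' @slot centerlineTruth ordered matrix (n x 3) of ridge centerline points
#'   (um, world coordinates).
#' @slot areaTruth data.frame of the analytic area profile (s, arc_mm,
#'   compartment, area_mm2).
#' @slot spec the generating [PhantomSpec-class].
#' @export
setClass("PhantomVolume", representation(
  labels = "array", attenuation = "array", voxelSizeUm = "numeric",
  centerlineTruth = "matrix", areaTruth = "data.frame", spec = "PhantomSpec"))

setValidity("PhantomVolume", function(object) {
  if (!identical(dim(object@labels), dim(object@attenuation)))
    return("labels and attenuation must share grid shape")
  if (ncol(object@centerlineTruth) != 3L)
    return("centerlineTruth must have 3 columns")
  TRUE
})

#' Parallel-beam scan geometry
#'
#' @slot anglesDeg strictly increasing projection angles in \[0, 180).
#' @slot detectorShape integer (rows, columns) of the detector.
#' @slot axisOffsetPx signed horizontal displacement of the rotation axis
#'   from the detector center, in columns (sub-pixel allowed).
#' @slot pixelSizeUm detector pixel pitch (um).
#' @export
setClass("ScanGeometry", representation(
  anglesDeg = "numeric", detectorShape = "integer",
  axisOffsetPx = "numeric", pixelSizeUm = "numeric"))

setValidity("ScanGeometry", function(object) {
  a <- object@anglesDeg
  if (length(a) < 1L || any(diff(a) <= 0) || a[1] < 0 || a[length(a)] >= 180)
    return("angles must be strictly increasing within [0, 180)")
  if (length(object@detectorShape) != 2L || any(object@detectorShape < 2L))
    return("detectorShape must be two integers >= 2")
  if (abs(object@axisOffsetPx) >= object@detectorShape[2] / 4)
    return("|axisOffsetPx| must be < detector columns / 4")
  TRUE
})

#' Detector and beam artifact model for the acquisition simulator
#'
#' @slot photonScale expected detector counts at unity transmission.
#' @slot darkOffsetCounts mean dark-field offset (counts).
#' @slot darkNoiseSd Gaussian dark noise standard deviation (counts).
#' @slot flatRelief amplitude of the smooth multiplicative illumination
#'   profile (0 = perfectly flat beam).
#' @slot edgeEnhanceStrength weight of the Laplacian edge-enhancement
#'   operator mimicking in-line phase contrast (0 disables).
#' @slot ringArtifactSd sd of the per-column fixed-pattern gain jitter that
#'   produces ring/line artifacts (0 disables).
#' @slot poissonNoise whether photon (Poisson) noise is applied.
#' @slot rngSeed integer seed for all stochastic stages.
#' @export
setClass("ArtifactModel", representation(
  photonScale = "numeric", darkOffsetCounts = "numeric",
  darkNoiseSd = "numeric", flatRelief = "numeric",
  edgeEnhanceStrength = "numeric", ringArtifactSd = "numeric",
  poissonNoise = "logical", rngSeed = "integer"))

setValidity("ArtifactModel", function(object) {
  if (object@photonScale < 0) return("photonScale must be >= 0")
  if (object@darkNoiseSd < 0 || object@ringArtifactSd < 0 ||
      object@flatRelief < 0)
    return("noise scales must be >= 0")
  TRUE
})

#' A raw projection series with its reference frames
#'
#' @slot raw integer array (rows, columns, angles) of 16-bit frames.
#' @slot flat,dark single 16-bit reference frames (matrices).
#' @slot geometry the [ScanGeometry-class].
#' @export
setClass("ProjectionSet", representation(
  raw = "array", flat = "matrix", dark = "matrix",
  geometry = "ScanGeometry"))

setValidity("ProjectionSet", function(object) {
  d <- dim(object@raw)
  g <- object@geometry
  if (length(d) != 3L) return("raw must be a 3-D array (rows, cols, angles)")
  if (d[3] != length(g@anglesDeg))
    return("frame count must equal angle count")
  if (!identical(d[1:2], dim(object@flat)) || !identical(d[1:2], dim(object@dark)))
    return("flat/dark must share the frame shape")
  if (!identical(as.integer(d[1:2]), g@detectorShape))
    return("frames must match geometry detectorShape")
  rng <- range(object@raw, object@flat, object@dark)
  if (rng[1] < 0 || rng[2] > 65535)
    return("pixel values must lie in [0, 65535]")
  TRUE
})

#' Flat/dark-corrected projection stack
#'
#' Real-valued frames on the 0..65536 transmission scale
#' (65536 = full transmission).
#'
#' @slot frames numeric array (rows, columns, angles).
#' @slot anglesDeg projection angles.
#' @slot axisOffsetPx rotation-axis offset (columns from detector center);
#'   NA until estimated or provided.
#' @slot pixelSizeUm effective pixel size (doubled by 2x2 binning).
#' @slot binned whether 2x2 binning has been applied.
#' @export
setClass("CorrectedStack", representation(
  frames = "array", anglesDeg = "numeric", axisOffsetPx = "numeric",
  pixelSizeUm = "numeric", binned = "logical"))

setValidity("CorrectedStack", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L || d[3] != length(object@anglesDeg))
    return("frames must be (rows, cols, angles) with one frame per angle")
  if (any(!is.finite(object@frames)))
    return("corrected frames must be finite everywhere")
  TRUE
})

#' One-row sinogram (angle x detector column), in -log transmission units
#'
#' @slot values numeric matrix, angles in rows, detector columns in columns.
#' @slot anglesDeg projection angles.
#' @slot axisOffsetPx rotation-axis offset in columns.
#' @slot pixelSizeUm detector pixel size (um).
#' @export
setClass("Sinogram", representation(
  values = "matrix", anglesDeg = "numeric", axisOffsetPx = "numeric",
  pixelSizeUm = "numeric"))

setValidity("Sinogram", function(object) {
  if (nrow(object@values) != length(object@anglesDeg))
    return("one sinogram row per angle required")
  if (any(!is.finite(object@values))) return("sinogram must be finite")
  TRUE
})

#' Reconstructed grayscale volume
#'
#' @slot values numeric array \[x, y, z\]; z indexes detector rows. Values
#'   are attenuation coefficients (mm^-1) when the log transform was applied.
#' @slot voxelSizeUm isotropic in-plane voxel size; row pitch equals it.
#' @slot provenance list of reconstruction metadata (filter, log flag,
#'   axis offset, angles).
#' @export
setClass("ReconVolume", representation(
  values = "array", voxelSizeUm = "numeric", provenance = "list"))

setValidity("ReconVolume", function(object) {
  if (length(dim(object@values)) != 3L) return("values must be 3-D")
  if (any(!is.finite(object@values))) return("values must be finite")
  TRUE
})

#' Integer-labeled volume
#'
#' @slot labels integer array \[x, y, z\].
#' @slot legend named character: names are label codes, values tissue names.
#' @slot voxelSizeUm voxel edge (um).
#' @slot provenance list of segmentation metadata.
#' @export
setClass("LabelVolume", representation(
  labels = "array", legend = "character", voxelSizeUm = "numeric",
  provenance = "list"))

setValidity("LabelVolume", function(object) {
  codes <- suppressWarnings(as.integer(names(object@legend)))
  if (any(is.na(codes))) return("legend names must be integer label codes")
  u <- unique(as.vector(object@labels))
  if (!all(u %in% codes))
    return(sprintf("labels outside legend: %s",
                   paste(setdiff(u, codes), collapse = ", ")))
  TRUE
})

#' Ordered landmark polyline with calibration
#'
#' @slot points matrix (n x 3) of landmark coordinates in pixel/voxel units
#'   (sub-voxel allowed).
#' @slot calibrationUmPerPx scalar conversion factor (um per pixel).
#' @export
setClass("Centerline", representation(
  points = "matrix", calibrationUmPerPx = "numeric"))

setValidity("Centerline", function(object) {
  if (ncol(object@points) != 3L || nrow(object@points) < 1L)
    return("points must be an n x 3 matrix with n >= 1")
  if (object@calibrationUmPerPx <= 0)
    return("calibrationUmPerPx must be > 0")
  TRUE
})
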