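#' Accessors for pipeline containers
#'
#' `labels()`, `values()`, `voxelSize()`, `legend()`, `angles()` and
#' `provenance()` extract the corresponding slots without touching the
#' internal representation.
#'
#' @param x a pipeline object.
#' @return the slot contents.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("tissueLabels", function(x) standardGeneric("tissueLabels"))

#' @rdname accessors
#' @export
setGeneric("volumeValues", function(x) standardGeneric("volumeValues"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("labelLegend", function(x) standardGeneric("labelLegend"))

#' @rdname accessors
#' @export
setGeneric("scanAngles", function(x) standardGeneric("scanAngles"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setMethod("tissueLabels", "LabelVolume", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("tissueLabels", "PhantomVolume", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("volumeValues", "ReconVolume", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("volumeValues", "PhantomVolume", function(x) x@attenuation)

#' @rdname accessors
#' @export
setMethod("voxelSize", "ReconVolume", function(x) x@voxelSizeUm)

#' @rdname accessors
#' @export
setMethod("voxelSize", "LabelVolume", function(x) x@voxelSizeUm)

#' @rdname accessors
#' @export
setMethod("voxelSize", "PhantomVolume", function(x) x@voxelSizeUm)

#' @rdname accessors
#' @export
setMethod("labelLegend", "LabelVolume", function(x) x@legend)

#' @rdname accessors
#' @export
setMethod("scanAngles", "ScanGeometry", function(x) x@anglesDeg)

#' @rdname accessors
#' @export
setMethod("scanAngles", "ProjectionSet", function(x) x@geometry@anglesDeg)

#' @rdname accessors
#' @export
setMethod("scanAngles", "CorrectedStack", function(x) x@anglesDeg)

#' @rdname accessors
#' @export
setMethod("provenance", "ReconVolume", function(x) x@provenance)

#' @rdname accessors
#' @export
setMethod("provenance", "LabelVolume", function(x) x@provenance)

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", object@nTurns, "turns,",
      object@centerlineLengthMm, "mm centerline\n")
  cat("  radii", object@baseRadiusMm, "->", object@apexRadiusMm,
      "mm, pitch", object@pitchMm, "mm/turn\n")
  cat("  grid", paste(object@gridShape, collapse = "x"),
      "at", object@voxelSizeUm, "um voxels\n")
})

setMethod("show", "PhantomVolume", function(object) {
  tab <- table(factor(object@labels, levels = 0:6))
  cat("PhantomVolume", paste(dim(object@labels), collapse = "x"),
      "at", object@voxelSizeUm, "um voxels\n")
  cat("  foreground voxels:", sum(tab[-1]), "\n")
  cat("  centerline:", nrow(object@centerlineTruth), "points,",
      round(sum(sqrt(rowSums(diff(object@centerlineTruth)^2))) / 1000, 4),
      "mm\n")
})

setMethod("show", "ProjectionSet", function(object) {
  d <- dim(object@raw)
  cat("ProjectionSet:", d[3], "frames of", d[1], "x", d[2],
      "(16-bit),", "axis offset", object@geometry@axisOffsetPx, "px\n")
})

setMethod("show", "CorrectedStack", function(object) {
  d <- dim(object@frames)
  cat("CorrectedStack:", d[3], "frames of", d[1], "x", d[2],
      if (object@binned) "(binned 2x2)" else "", "\n")
})

setMethod("show", "Sinogram", function(object) {
  cat("Sinogram:", nrow(object@values), "angles x",
      ncol(object@values), "columns\n")
})

setMethod("show", "ReconVolume", function(object) {
  cat("ReconVolume", paste(dim(object@values), collapse = "x"),
      "at", object@voxelSizeUm, "um voxels, filter:",
      object@provenance$filter %||% "?", "\n")
})

setMethod("show", "LabelVolume", function(object) {
  cat("LabelVolume", paste(dim(object@labels), collapse = "x"), "labels:",
      paste(sprintf("%s=%s", names(object@legend), object@legend),
            collapse = ", "), "\n")
})

setMethod("show", "Centerline", function(object) {
  len <- polylineLength(object)
  cat("Centerline:", nrow(object@points), "points,",
      round(len[["mm"]], 4), "mm at",
      object@calibrationUmPerPx, "um/px\n")
})
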