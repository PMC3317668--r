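## Semi-automated segmentation: global threshold into Exterior/Interior,
## largest-connected-component couch removal, signed-distance propagation of
## sparse slice annotations, and import of manual corrections.

#' Global threshold segmentation into exterior/interior
#'
#' Voxels with value below the threshold become Exterior (0); voxels with
#' value greater than or equal to the threshold become Interior (1).  With
#' `threshold = "auto"` the threshold is chosen by Otsu's method on the
#' volume histogram.
#'
#' @param volume a [ReconVolume-class] or numeric 3-D array.
#' @param threshold numeric threshold or `"auto"`.
#' @param voxelSizeUm voxel size when `volume` is a bare array.
#' @return a binary [LabelVolume-class]; the threshold used is recorded in
#'   `provenance(x)$threshold`.
#' @export
thresholdSegment <- function(volume, threshold = "auto", voxelSizeUm = NULL) {
  if (is(volume, "ReconVolume")) {
    vals <- volume@values
    voxelSizeUm <- volume@voxelSizeUm
  } else {
    vals <- volume
    voxelSizeUm <- voxelSizeUm %||% 1
  }
  if (identical(threshold, "auto")) {
    rng <- range(vals)
    if (rng[1] == rng[2]) stop("degenerate histogram: all voxels equal")
    norm <- (vals - rng[1]) / (rng[2] - rng[1])
    th <- EBImage::otsu(EBImage::Image(matrix(norm, ncol = 1L)),
                        range = c(0, 1), levels = 256L)
    threshold <- rng[1] + th * (rng[2] - rng[1])
  }
  if (!is.finite(threshold)) stop("threshold must be finite")
  lab <- array(0L, dim(vals))
  lab[vals >= threshold] <- 1L
  new("LabelVolume", labels = lab, legend = binaryLegend,
      voxelSizeUm = voxelSizeUm,
      provenance = list(threshold = threshold))
}

#' Keep only the largest connected interior component ("remove couch")
#'
#' Connected components of label 1 are computed at the configured
#' connectivity; only the largest by voxel count is kept, everything else
#' becomes exterior.  A size tie is broken deterministically in favor of the
#' component containing the smallest linear voxel index.
#'
#' @param binary a binary [LabelVolume-class].
#' @param connectivity 6, 18 or 26 (default) neighborhood.
#' @return the cleaned [LabelVolume-class].
#' @export
keepLargestComponent <- function(binary, connectivity = 26) {
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  lab <- binary@labels
  if (!all(lab %in% c(0L, 1L))) stop("binary labels (0/1) required")
  d <- dim(lab)
  if (!any(lab == 1L)) {
    warning("no interior voxels; returning all-exterior volume")
    return(binary)
  }
  comp <- cpp_label_components(lab == 1L, d[1], d[2], d[3],
                               as.integer(connectivity))
  sizes <- tabulate(comp, attr(comp, "nComponents"))
  keep <- which.max(sizes)       # first maximum = smallest first linear index
  out <- array(0L, d)
  out[comp == keep] <- 1L
  new("LabelVolume", labels = out, legend = binary@legend,
      voxelSizeUm = binary@voxelSizeUm,
      provenance = c(binary@provenance,
                     list(connectivity = connectivity,
                          componentsRemoved = length(sizes) - 1L,
                          largestComponentVoxels = sizes[keep])))
}

## signed Euclidean distance to the boundary of a binary 2-D mask
## (positive inside, negative outside).  An empty mask gets a constant
## negative field of magnitude `emptyDepth` (in pixels): a structure absent
## from one annotated slice then shrinks progressively across the gap
## instead of vanishing at the first interpolated slice.
signedDistance <- function(mask, emptyDepth = 4) {
  if (!any(mask)) return(matrix(-emptyDepth, nrow(mask), ncol(mask)))
  if (all(mask)) return(matrix(1e6, nrow(mask), ncol(mask)))
  din <- EBImage::distmap(EBImage::Image(mask * 1))
  dout <- EBImage::distmap(EBImage::Image((!mask) * 1))
  as.matrix(din) - as.matrix(dout)
}

#' Propagate sparse slice annotations through a stack
#'
#' Reproduces the "project along the stack" assistance of interactive
#' segmentation software: between two annotated slices each label's signed
#' distance field is linearly interpolated and every voxel takes the label
#' with the largest blended interior value (exterior if none is positive).
#' Slices outside the annotated range copy the nearest annotated slice.
#' A fully annotated stack is reproduced exactly.
#'
#' @param sparse list of entries `list(slice =, labels =)` with 1-based
#'   slice indices and integer label matrices; an optional `legend` entry
#'   per element must agree across elements.
#' @param volumeShape integer (nx, ny, nz).
#' @param legend label legend for the result.
#' @param voxelSizeUm voxel size of the result.
#' @return a [LabelVolume-class].
#' @export
propagateLabels <- function(sparse, volumeShape,
                            legend = cochlearLegend(), voxelSizeUm = 1) {
  if (length(sparse) < 1L) stop("at least one annotated slice required")
  legends <- Filter(Negate(is.null), lapply(sparse, `[[`, "legend"))
  if (length(legends) > 1L &&
      !all(vapply(legends, identical, logical(1), legends[[1]])))
    stop("conflicting legends between annotated slices")
  if (length(legends) >= 1L) legend <- legends[[1]]
  idx <- vapply(sparse, `[[`, numeric(1), "slice")
  if (any(idx < 1 | idx > volumeShape[3]))
    stop("annotated slice index outside the volume")
  ord <- order(idx)
  idx <- idx[ord]; sparse <- sparse[ord]
  mats <- lapply(sparse, function(e) {
    m <- e$labels
    storage.mode(m) <- "integer"
    if (!all(dim(m) == volumeShape[1:2]))
      stop("annotated slice shape does not match the volume")
    m
  })
  out <- array(0L, volumeShape)
  for (i in seq_along(idx)) out[, , idx[i]] <- mats[[i]]

  codes <- sort(setdiff(unique(unlist(lapply(mats, unique))), 0L))
  ## interior gaps: signed-distance blending
  if (length(idx) > 1L) for (g in seq_len(length(idx) - 1L)) {
    lo <- idx[g]; hi <- idx[g + 1L]
    if (hi - lo < 2L) next
    mids <- (lo + 1L):(hi - 1L)
    gap <- hi - lo
    sdLo <- lapply(codes, function(cd)
      signedDistance(mats[[g]] == cd, emptyDepth = gap))
    sdHi <- lapply(codes, function(cd)
      signedDistance(mats[[g + 1L]] == cd, emptyDepth = gap))
    for (z in mids) {
      alpha <- (z - lo) / (hi - lo)
      best <- matrix(0, volumeShape[1], volumeShape[2])
      lab <- matrix(0L, volumeShape[1], volumeShape[2])
      for (ci in seq_along(codes)) {
        blend <- (1 - alpha) * sdLo[[ci]] + alpha * sdHi[[ci]]
        take <- blend > best
        lab[take] <- codes[ci]
        best[take] <- blend[take]
      }
      out[, , z] <- lab
    }
  }
  ## outside the annotated range: copy the nearest annotated slice
  if (idx[1] > 1L) for (z in seq_len(idx[1] - 1L)) out[, , z] <- mats[[1]]
  nA <- length(idx)
  if (idx[nA] < volumeShape[3])
    for (z in (idx[nA] + 1L):volumeShape[3]) out[, , z] <- mats[[nA]]

  new("LabelVolume", labels = out, legend = legend,
      voxelSizeUm = voxelSizeUm,
      provenance = list(annotatedSlices = idx))
}

#' Apply manual slice corrections to a label volume
#'
#' Overlay matrices replace labels wherever they carry a non-reserved code;
#' `NA` is the reserved "no change" code.  The number of changed voxels is
#' recorded in the provenance.
#'
#' @param labels a [LabelVolume-class].
#' @param edits list of entries `list(slice =, overlay =)`; overlays are
#'   matrices of label codes with `NA` meaning "leave unchanged".
#' @return the corrected [LabelVolume-class].
#' @export
applyManualCorrections <- function(labels, edits) {
  lab <- labels@labels
  valid <- as.integer(names(labels@legend))
  changed <- 0L
  for (e in edits) {
    ov <- e$overlay
    if (!all(dim(ov) == dim(lab)[1:2]))
      stop("overlay shape does not match slice shape")
    codes <- unique(ov[!is.na(ov)])
    bad <- setdiff(codes, valid)
    if (length(bad))
      stop("overlay contains codes absent from the legend: ",
           paste(sort(bad), collapse = ", "))
    sl <- lab[, , e$slice]
    sel <- !is.na(ov) & ov != sl
    sl[sel] <- as.integer(ov[sel])
    lab[, , e$slice] <- sl
    changed <- changed + sum(sel)
  }
  new("LabelVolume", labels = lab, legend = labels@legend,
      voxelSizeUm = labels@voxelSizeUm,
      provenance = c(labels@provenance, list(editedVoxels = changed)))
}
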