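## Centerline length and perpendicular cross-sectional area morphometry.

#' Construct a landmark centerline
#'
#' @param points n x 3 matrix of ordered landmark coordinates in pixel
#'   (voxel) units; sub-voxel positions allowed.
#' @param calibrationUmPerPx conversion factor (um per pixel); 1.22 is the
#'   grid-calibrated value used for real detector data, phantom runs use
#'   the voxel size.
#' @return a [Centerline-class].
#' @export
centerline <- function(points, calibrationUmPerPx = 1.22) {
  new("Centerline", points = as.matrix(points),
      calibrationUmPerPx = calibrationUmPerPx)
}

#' Polyline length of a landmark chain
#'
#' Sum of Euclidean distances between consecutive landmarks, converted with
#' the calibration factor; a single landmark has length 0.  The length is
#' measured on the polyline itself, not a fitted curve.
#'
#' @param points a [Centerline-class], or an n x 3 matrix of points in
#'   pixel units.
#' @param calibrationUmPerPx um per pixel (ignored when `points` is a
#'   [Centerline-class]).
#' @return named numeric: `px`, `um`, `mm`.
#' @export
polylineLength <- function(points, calibrationUmPerPx = 1.22) {
  if (is(points, "Centerline")) {
    calibrationUmPerPx <- points@calibrationUmPerPx
    points <- points@points
  }
  points <- as.matrix(points)
  px <- if (nrow(points) < 2L) 0 else
    sum(sqrt(rowSums(diff(points)^2)))
  um <- px * calibrationUmPerPx
  c(px = px, um = um, mm = um / 1000)
}

#' Tangents and perpendicular-plane bases along a polyline
#'
#' Tangents are centered finite differences on the (optionally smoothed)
#' polyline, one-sided at the ends.  The in-plane orthonormal basis is
#' parallel-transported from the first frame (rotation-minimizing), so
#' consecutive section planes stay consistently oriented even where the
#' curve is locally straight.
#'
#' @param points n x 3 matrix (n >= 3) or [Centerline-class].
#' @param smoothingWindow odd running-mean window applied to the
#'   coordinates before differencing (1 = none).
#' @return list with `points`, unit `tangent`, and in-plane unit basis
#'   `normal`, `binormal` (n x 3 each).
#' @export
tangentFrames <- function(points, smoothingWindow = 1L) {
  if (is(points, "Centerline")) points <- points@points
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3L) stop("at least 3 points required for tangent estimation")
  seg <- sqrt(rowSums(diff(points)^2))
  if (any(seg == 0))
    stop("coincident consecutive points at indices ",
         paste(which(seg == 0), collapse = ", "))
  sm <- smoothPolyline(points, smoothingWindow)
  tg <- matrix(0, n, 3)
  tg[1, ] <- sm[2, ] - sm[1, ]
  tg[n, ] <- sm[n, ] - sm[n - 1, ]
  if (n > 2L) tg[2:(n - 1), ] <- sm[3:n, ] - sm[1:(n - 2), ]
  tg <- tg / sqrt(rowSums(tg^2))

  nor <- matrix(0, n, 3); bin <- matrix(0, n, 3)
  ref <- c(0, 0, 1)
  v <- ref - sum(ref * tg[1, ]) * tg[1, ]
  if (sqrt(sum(v^2)) < 1e-8) {
    ref <- c(1, 0, 0)
    v <- ref - sum(ref * tg[1, ]) * tg[1, ]
  }
  nor[1, ] <- v / sqrt(sum(v^2))
  bin[1, ] <- crossProd3(tg[1, ], nor[1, ])
  for (i in 2:n) {                       # parallel transport
    v <- nor[i - 1, ] - sum(nor[i - 1, ] * tg[i, ]) * tg[i, ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-8) v <- bin[i - 1, ] - sum(bin[i - 1, ] * tg[i, ]) * tg[i, ]
    nor[i, ] <- v / sqrt(sum(v^2))
    bin[i, ] <- crossProd3(tg[i, ], nor[i, ])
  }
  list(points = points, tangent = tg, normal = nor, binormal = bin)
}

crossProd3 <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

#' Cross-sectional area of a compartment in one perpendicular plane
#'
#' The plane is sampled on a regular 2-D grid with nearest-neighbor label
#' lookup; the area is the labeled sample count times the sample spacing
#' squared.  In a coiled organ one perpendicular plane can also graze
#' sections of neighboring turns, so only the connected in-plane section
#' lying nearest the plane center (the station's own section) is counted.
#' When a grid sample falls outside the volume while compartment label lies
#' next to it, the section is truncated by the field of view and the
#' measurement is flagged invalid with reason `"fov"`.
#'
#' @param labels a [LabelVolume-class].
#' @param centerUm plane center in um (world coordinates).
#' @param basis list with unit vectors `normal`, `binormal` spanning the
#'   plane (um frame).
#' @param compartment label code or tissue name.
#' @param planeExtentUm half-extent of the sampling grid (um).
#' @param sampleSpacingUm grid spacing (um); at most the voxel size.
#' @return list with `area_mm2`, `valid`, `reason` and `count`.
#' @export
crossSectionArea <- function(labels, centerUm, basis, compartment,
                             planeExtentUm, sampleSpacingUm = NULL) {
  vox <- labels@voxelSizeUm
  if (is.null(sampleSpacingUm)) sampleSpacingUm <- vox / 2
  if (sampleSpacingUm > vox)
    stop("sampleSpacingUm must not exceed the voxel size")
  code <- resolveCompartment(compartment, labels@legend)
  g <- seq(-planeExtentUm, planeExtentUm, by = sampleSpacingUm)
  ng <- length(g)
  ## sample positions: center + g1*normal + g2*binormal, as ng x ng grid
  p1 <- outer(g, basis$normal)                     # ng x 3
  p2 <- outer(g, basis$binormal)
  px <- outer(p1[, 1], p2[, 1], "+") + centerUm[1]
  py <- outer(p1[, 2], p2[, 2], "+") + centerUm[2]
  pz <- outer(p1[, 3], p2[, 3], "+") + centerUm[3]
  d <- dim(labels@labels)
  ix <- floor(px / vox) + 1L
  iy <- floor(py / vox) + 1L
  iz <- floor(pz / vox) + 1L
  inb <- ix >= 1L & ix <= d[1] & iy >= 1L & iy <= d[2] & iz >= 1L & iz <= d[3]
  labGrid <- matrix(NA_integer_, ng, ng)
  if (any(inb))
    labGrid[inb] <- labels@labels[cbind(ix[inb], iy[inb], iz[inb])]
  isComp <- !is.na(labGrid) & labGrid == code
  if (any(isComp)) {
    ## keep the connected section nearest the plane center; sliver
    ## components (grazing cuts) are ignored so they cannot hijack the
    ## proximity rule
    cc <- EBImage::bwlabel(EBImage::Image(isComp * 1))
    cc <- round(as.matrix(cc))
    if (max(cc) > 1L) {
      sizes <- tabulate(cc[cc > 0L], max(cc))
      keep <- which(sizes >= max(9, 0.02 * max(sizes)))
      mid <- (ng + 1) / 2
      d2grid <- outer((seq_len(ng) - mid)^2, (seq_len(ng) - mid)^2, "+")
      nearest <- keep[which.min(vapply(keep, function(k)
        min(d2grid[cc == k]), numeric(1)))]
      isComp <- cc == nearest
    }
  }
  count <- sum(isComp)
  area <- count * sampleSpacingUm^2 / 1e6
  valid <- TRUE; reason <- NA_character_
  if (any(!inb)) {
    ## out-of-bounds sample with compartment label in its 8-neighborhood
    oob <- !inb
    nb <- matrix(FALSE, ng, ng)
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      xs <- seq_len(ng) + dx; ys <- seq_len(ng) + dy
      okx <- xs >= 1 & xs <= ng; oky <- ys >= 1 & ys <= ng
      sub <- matrix(FALSE, ng, ng)
      sub[okx, oky] <- isComp[xs[okx], ys[oky]]
      nb <- nb | sub
    }
    if (any(oob & nb)) { valid <- FALSE; reason <- "fov" }
  }
  list(area_mm2 = area, valid = valid, reason = reason, count = count)
}

#' Cross-sectional area profile along a centerline
#'
#' Resamples the polyline at uniform arc steps and measures each requested
#' compartment in the plane perpendicular to the (parallel-transported)
#' local tangent at every station.  Invalid stations (field-of-view
#' truncation) are retained and flagged.
#'
#' @param labels a [LabelVolume-class].
#' @param points n x 3 centerline points in um (world coordinates).
#' @param compartments label codes or tissue names (default the three
#'   scalae).
#' @param stepMm arc sampling step (mm).
#' @param planeExtentUm half-extent of each section plane (um).
#' @param sampleSpacingUm plane grid spacing (um, default half voxel).
#' @param smoothingWindow odd window for tangent smoothing.
#' @return data.frame (arc_mm, s, compartment, area_mm2, valid, reason).
#' @export
areaProfile <- function(labels, points, compartments = c("st", "sm", "sv"),
                        stepMm = 0.05, planeExtentUm = 500,
                        sampleSpacingUm = NULL, smoothingWindow = 5L) {
  if (stepMm <= 0) stop("stepMm must be > 0")
  pts <- resamplePolyline(as.matrix(points), stepMm * 1000)
  arc <- attr(pts, "arcUm")
  fr <- tangentFrames(pts, smoothingWindow = smoothingWindow)
  total <- arc[length(arc)]
  rows <- list()
  for (comp in compartments) {
    code <- resolveCompartment(comp, labels@legend)
    nm <- labels@legend[[as.character(code)]]
    for (i in seq_along(arc)) {
      m <- crossSectionArea(labels, pts[i, ],
                            list(normal = fr$normal[i, ],
                                 binormal = fr$binormal[i, ]),
                            code, planeExtentUm, sampleSpacingUm)
      rows[[length(rows) + 1L]] <- data.frame(
        arc_mm = arc[i] / 1000, s = if (total > 0) arc[i] / total else 0,
        compartment = nm, area_mm2 = m$area_mm2, valid = m$valid,
        reason = m$reason)
    }
  }
  do.call(rbind, rows)
}

#' Extract ridge landmarks from a labeled volume
#'
#' Emulates the operator marking pillar heads: near each guide point the
#' centroid of the organ-of-Corti ridge label within a search ball becomes
#' the landmark.  Guide points only need to be near the ridge (operator
#' clicks); the returned landmarks reflect the segmented volume.
#'
#' @param labels a [LabelVolume-class].
#' @param guideUm m x 3 matrix of approximate ridge positions (um).
#' @param searchRadiusUm search ball radius (um).
#' @param ridgeCode ridge label code (default 6).
#' @return k x 3 matrix of landmarks (um); guide points with no ridge voxel
#'   in reach are dropped.
#' @export
extractRidgeLandmarks <- function(labels, guideUm, searchRadiusUm = 40,
                                  ridgeCode = 6L) {
  vox <- labels@voxelSizeUm
  idx <- which(labels@labels == ridgeCode, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("ridge label ", ridgeCode, " absent from volume")
  pos <- (idx - 0.5) * vox
  out <- matrix(NA_real_, nrow(guideUm), 3)
  for (i in seq_len(nrow(guideUm))) {
    d2 <- (pos[, 1] - guideUm[i, 1])^2 + (pos[, 2] - guideUm[i, 2])^2 +
      (pos[, 3] - guideUm[i, 3])^2
    sel <- d2 <= searchRadiusUm^2
    if (any(sel)) out[i, ] <- colMeans(pos[sel, , drop = FALSE])
  }
  out[stats::complete.cases(out), , drop = FALSE]
}
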