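## Spiral cochlea phantom generation.
##
## The duct centerline is the pillar-head (organ-of-Corti) ridge: a
## log-spiral in radius with linear pitch, uniformly rescaled so that its
## analytic arc length equals the design length exactly.  Channel sections
## are ellipses stacked along the local "up" direction (scala tympani below
## the basilar membrane, scala media in the middle, scala vestibuli above
## Reissner's membrane), so every design area is analytically exact.

#' Construct a phantom specification
#'
#' @param nTurns spiral revolutions (0 = straight vertical duct).
#' @param centerlineLengthMm design ridge arc length (mm).
#' @param baseRadiusMm,apexRadiusMm nominal spiral radii (mm); the radius is
#'   log-interpolated and the whole curve rescaled to the design length.
#' @param pitchMm nominal axial rise per turn (mm).
#' @param areaAnchors named list (`st`, `sm`, `sv`) of (s, area mm^2)
#'   anchor matrices, linearly interpolated.
#' @param membraneThicknessUm membrane thickness (um).
#' @param wallThicknessUm bony wall thickness (um).
#' @param aspectRatio ellipse width:height ratio of the channel sections.
#' @param ridgeRadiusUm organ-of-Corti ridge tube radius (um).
#' @param overhangMm duct extension beyond both centerline ends (mm).
#' @param attenuationMap named numeric label->attenuation (mm^-1).
#' @param voxelSizeUm isotropic voxel size (um).
#' @param gridShape integer voxel counts (x, y, z).
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(nTurns = 2,
                        centerlineLengthMm = 6.67,
                        baseRadiusMm = 0.56,
                        apexRadiusMm = 0.475,
                        pitchMm = 0.66,
                        areaAnchors = list(
                          st = cbind(c(0, 1), c(0.16, 0.031)),
                          sm = cbind(c(0, 1), c(0.035, 0.035)),
                          sv = cbind(c(0, 1), c(0.11, 0.011))),
                        membraneThicknessUm = 16,
                        wallThicknessUm = 25,
                        aspectRatio = 2.8,
                        ridgeRadiusUm = 18,
                        overhangMm = 0.08,
                        attenuationMap = c(`0` = 0, `1` = 1.0, `2` = 0.2,
                                           `3` = 0.2, `4` = 0.2, `5` = 0.5,
                                           `6` = 0.5),
                        voxelSizeUm = 8,
                        gridShape = c(256L, 256L, 256L)) {
  new("PhantomSpec", nTurns = nTurns,
      centerlineLengthMm = centerlineLengthMm,
      baseRadiusMm = baseRadiusMm, apexRadiusMm = apexRadiusMm,
      pitchMm = pitchMm, areaAnchors = areaAnchors,
      membraneThicknessUm = membraneThicknessUm,
      wallThicknessUm = wallThicknessUm, aspectRatio = aspectRatio,
      ridgeRadiusUm = ridgeRadiusUm, overhangMm = overhangMm,
      attenuationMap = attenuationMap, voxelSizeUm = voxelSizeUm,
      gridShape = as.integer(gridShape))
}

#' Default mouse-matched phantom specification
#'
#' Ground truth equals the printed morphometry of an adult C57BL6 mouse
#' cochlea: 6.67 mm ridge length over two turns; scala tympani area 0.16
#' mm^2 at the base declining to 0.031 mm^2; scala media constant 0.035
#' mm^2; scala vestibuli 0.11 mm^2 at the base to 0.011 mm^2 at the apex.
#'
#' @return a [PhantomSpec-class].
#' @examples
#' spec <- defaultPhantomSpec()
#' spec@centerlineLengthMm            # 6.67
#' areaProfileFun(spec, "sm")(0.5)    # 0.035
#' @export
defaultPhantomSpec <- function() phantomSpec()

#' Piecewise-linear design area profile of one compartment
#'
#' @param spec a [PhantomSpec-class].
#' @param compartment `"st"`, `"sm"`, `"sv"` (or label codes 2/3/4).
#' @return a function of normalized arc position s in \[0,1\] returning the
#'   design cross-sectional area in mm^2 (clamped to end values outside).
#' @export
areaProfileFun <- function(spec, compartment) {
  nm <- compartmentKey(compartment)
  a <- spec@areaAnchors[[nm]]
  approxfun(a[, 1], a[, 2], rule = 2)
}

compartmentKey <- function(compartment) {
  if (is.numeric(compartment))
    compartment <- c(`2` = "st", `3` = "sm", `4` = "sv")[as.character(compartment)]
  if (is.na(compartment) || !compartment %in% c("st", "sm", "sv"))
    stop("unknown compartment; expected 'st', 'sm' or 'sv' (codes 2/3/4)")
  compartment
}

#' Evaluate the analytic ground-truth area profile
#'
#' Evaluates the piecewise-linear design profile exactly; these are design
#' values, not voxel counts, so no validity masking applies.
#'
#' @param spec a [PhantomSpec-class].
#' @param compartment `"st"`, `"sm"` or `"sv"` (or codes 2/3/4).
#' @param positions normalized arc positions in \[0,1\].
#' @return data.frame with columns `s`, `arc_mm`, `compartment`,
#'   `area_mm2`, `valid`.
#' @export
analyticAreaProfile <- function(spec, compartment, positions) {
  nm <- compartmentKey(compartment)
  if (length(positions) == 0L)
    return(data.frame(s = numeric(), arc_mm = numeric(),
                      compartment = character(), area_mm2 = numeric(),
                      valid = logical()))
  if (any(positions < 0 | positions > 1))
    stop("positions must lie in [0, 1]")
  f <- areaProfileFun(spec, nm)
  data.frame(s = positions,
             arc_mm = positions * spec@centerlineLengthMm,
             compartment = nm, area_mm2 = f(positions), valid = TRUE)
}

## ---- centerline geometry ---------------------------------------------------

## Analytic centerline (mm, before placement into the grid).  Returns
## closures pos(t) (3-col matrix) and speed(t), the length-enforcing scale
## factor already applied.
spiralCurve <- function(spec) {
  L <- spec@centerlineLengthMm
  n <- spec@nTurns
  if (n == 0) {
    pos <- function(t) cbind(0, 0, t * L)
    speed <- function(t) rep(L, length(t))
    return(list(pos = pos, speed = speed, scale = 1))
  }
  rb <- spec@baseRadiusMm
  k <- log(spec@apexRadiusMm / rb)
  dz <- spec@pitchMm * n
  pos0 <- function(t) {
    r <- rb * exp(k * t); phi <- 2 * pi * n * t
    cbind(r * cos(phi), r * sin(phi), dz * t)
  }
  speed0 <- function(t) {
    r <- rb * exp(k * t)
    sqrt((k * r)^2 + (2 * pi * n * r)^2 + dz^2)
  }
  gl <- pracma::gaussLegendre(64, 0, 1)
  rawLen <- sum(gl$w * speed0(gl$x))
  scale <- L / rawLen
  list(pos = function(t) pos0(t) * scale,
       speed = function(t) speed0(t) * scale,
       scale = scale)
}

## Sample the curve at uniform arc spacing (um) over [tLo, tHi].  Also
## returns the t -> arc map so callers can convert to normalized arc
## position (the coordinate of the design area profiles).
sampleCurveByArc <- function(curve, tLo, tHi, stepUm) {
  tt <- seq(tLo, tHi, length.out = 4096)
  sp <- curve$speed(tt) * 1000                    # um per unit t
  arc <- c(0, cumsum((sp[-1] + sp[-length(sp)]) / 2 * diff(tt)))
  total <- arc[length(arc)]
  sArc <- seq(0, total, by = stepUm)
  if (sArc[length(sArc)] < total - 1e-9) sArc <- c(sArc, total)
  t <- approx(arc, tt, xout = sArc)$y
  list(t = t, arcUm = sArc, arcOfT = approxfun(tt, arc))
}

## Orthonormal frames along the curve: T tangent, B "up" (gravitational
## vertical projected off the tangent), N = B x T lateral.
curveFrames <- function(curve, t) {
  eps <- 1e-6
  p1 <- curve$pos(t + eps); p0 <- curve$pos(t - eps)
  Tm <- (p1 - p0) / (2 * eps)
  Tm <- Tm / sqrt(rowSums(Tm^2))
  Bz <- cbind(-Tm[, 1] * Tm[, 3], -Tm[, 2] * Tm[, 3], 1 - Tm[, 3]^2)
  nb <- sqrt(rowSums(Bz^2))
  flat <- nb < 1e-8                               # vertical tangent fallback
  if (any(flat)) {
    Bz[flat, ] <- cbind(1 - Tm[flat, 1]^2, -Tm[flat, 1] * Tm[flat, 2],
                        -Tm[flat, 1] * Tm[flat, 3])
    nb[flat] <- sqrt(rowSums(Bz[flat, , drop = FALSE]^2))
  }
  Bm <- Bz / nb
  Nm <- cbind(Bm[, 2] * Tm[, 3] - Bm[, 3] * Tm[, 2],
              Bm[, 3] * Tm[, 1] - Bm[, 1] * Tm[, 3],
              Bm[, 1] * Tm[, 2] - Bm[, 2] * Tm[, 1])
  list(T = Tm, N = Nm, B = Bm)
}

## Per-sample cross-section geometry (um).  Columns match cpp_voxelize_tube.
sectionGeometry <- function(spec, s) {
  q <- spec@aspectRatio
  m <- spec@membraneThicknessUm
  wall <- spec@wallThicknessUm
  semi <- function(nm) {
    A <- areaProfileFun(spec, nm)(pmin(pmax(s, 0), 1)) * 1e6   # um^2
    a <- sqrt(A * q / pi)
    cbind(a, a / q)
  }
  st <- semi("st"); sm <- semi("sm"); sv <- semi("sv")
  pad <- max(12, m + 4)
  aEnv <- pmax(st[, 1], sm[, 1], sv[, 1]) + pad
  vBot <- -m - 2 * st[, 2]
  vTop <- 2 * sm[, 2] + m + 2 * sv[, 2]
  vEnvC <- (vBot + vTop) / 2
  ## minimal bEnv of the exponent-4 superellipse envelope containing all
  ## three section ellipse boundaries (+ pad)
  theta <- seq(0, 2 * pi, length.out = 65)[-65]
  bEnv <- (vTop - vBot) / 2 + pad
  centers <- list(cbind(-m - st[, 2], st[, 1], st[, 2]),
                  cbind(sm[, 2], sm[, 1], sm[, 2]),
                  cbind(2 * sm[, 2] + m + sv[, 2], sv[, 1], sv[, 2]))
  for (e in centers) {
    for (th in theta) {
      u <- e[, 2] * cos(th)
      v <- e[, 1] + e[, 3] * sin(th)
      denom <- 1 - (u / aEnv)^4
      req <- ifelse(denom > 1e-6, abs(v - vEnvC) / denom^0.25, 0)
      bEnv <- pmax(bEnv, req + 2)
    }
  }
  cbind(aST = st[, 1], bST = st[, 2], aSM = sm[, 1], bSM = sm[, 2],
        aSV = sv[, 1], bSV = sv[, 2], mem = m, wall = wall,
        rOC = spec@ridgeRadiusUm, aEnv = aEnv, bEnv = bEnv, vEnvC = vEnvC)
}

## ---- phantom build ---------------------------------------------------------

#' Rasterize a phantom specification into a label + attenuation volume
#'
#' Deterministic: identical specifications produce identical volumes.  The
#' returned ground truth (`centerlineTruth`, `areaTruth`) is analytic, not a
#' voxel count.
#'
#' @param spec a [PhantomSpec-class].
#' @return a [PhantomVolume-class].
#' @export
buildPhantom <- function(spec) {
  validObject(spec)
  vox <- spec@voxelSizeUm
  grid <- spec@gridShape
  curve <- spiralCurve(spec)
  tOver <- spec@overhangMm / spec@centerlineLengthMm

  arcStep <- vox / 2
  samp <- sampleCurveByArc(curve, -tOver, 1 + tOver, arcStep)
  P <- curve$pos(samp$t) * 1000                   # um, pre-placement
  fr <- curveFrames(curve, samp$t)
  ## normalized arc position of each sample (design-profile coordinate)
  arc0 <- samp$arcOfT(0); arc1 <- samp$arcOfT(1)
  sNorm <- (samp$arcUm - arc0) / (arc1 - arc0)
  geom <- sectionGeometry(spec, sNorm)

  ## world bounding box of the duct
  aOut <- geom[, "aEnv"] + geom[, "wall"]
  bOut <- geom[, "bEnv"] + geom[, "wall"]
  vLo <- geom[, "vEnvC"] - bOut
  vHi <- geom[, "vEnvC"] + bOut
  extHi <- matrix(0, nrow(P), 3)
  extLo <- matrix(0, nrow(P), 3)
  for (ax in 1:3) {
    be <- fr$B[, ax]
    extHi[, ax] <- aOut * abs(fr$N[, ax]) + pmax(vHi * be, vLo * be)
    extLo[, ax] <- aOut * abs(fr$N[, ax]) + pmax(-vHi * be, -vLo * be)
  }
  lo <- apply(P - extLo, 2, min)
  hi <- apply(P + extHi, 2, max)

  ## center the duct in the grid; require a 2-voxel margin
  gridUm <- grid * vox
  offset <- gridUm / 2 - (lo + hi) / 2
  need <- hi - lo + 4 * vox
  if (any(need > gridUm)) {
    minGrid <- ceiling(need / vox)
    stop(sprintf(
      "grid %s too small for the phantom; minimal grid is %s at %g um voxels",
      paste(grid, collapse = "x"), paste(minGrid, collapse = "x"), vox))
  }
  P <- sweep(P, 2, offset, "+")

  labels <- cpp_voxelize_tube(grid, vox, P, fr$T, fr$N, fr$B, geom,
                              slabHalf = arcStep)
  labels <- absorbShards(labels)
  attByCode <- spec@attenuationMap[as.character(0:6)]
  attByCode[is.na(attByCode)] <- 0
  att <- array(as.double(attByCode[labels + 1L]), dim = grid)

  truthSamp <- sampleCurveByArc(curve, 0, 1, vox)
  truth <- sweep(curve$pos(truthSamp$t) * 1000, 2, offset, "+")
  colnames(truth) <- c("x_um", "y_um", "z_um")

  sGrid <- seq(0, 1, by = 0.01)
  areaTruth <- do.call(rbind, lapply(c("st", "sm", "sv"), function(nm)
    analyticAreaProfile(spec, nm, sGrid)))

  new("PhantomVolume", labels = labels, attenuation = att,
      voxelSizeUm = vox, centerlineTruth = truth, areaTruth = areaTruth,
      spec = spec)
}

## Rasterizing a swept tube on a voxel grid can strand a handful of voxels
## of a tissue class away from its main body (clipped corners where winding
## cells meet).  Reassign every small disconnected fragment (< 1% of its
## label's largest component) to the label most common among its neighbors,
## so each tissue class forms a single connected component.
absorbShards <- function(labels) {
  d <- dim(labels)
  for (cd in sort(setdiff(unique(as.vector(labels)), 0L))) {
    cc <- cpp_label_components(labels == cd, d[1], d[2], d[3], 26L)
    n <- attr(cc, "nComponents")
    if (n <= 1L) next
    sizes <- tabulate(cc, n)
    main <- which.max(sizes)
    small <- setdiff(which(sizes < 0.01 * sizes[main]), main)
    if (!length(small)) next
    lin <- which(cc %in% small)
    byComp <- split(lin, cc[lin])
    for (k in small) {
      idx <- arrayInd(byComp[[as.character(k)]], d)
      votes <- integer(7)
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        nb <- idx + matrix(c(dx, dy, dz), nrow(idx), 3, byrow = TRUE)
        ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 &
          nb[, 2] <= d[2] & nb[, 3] >= 1 & nb[, 3] <= d[3]
        if (!any(ok)) next
        lv <- labels[nb[ok, , drop = FALSE]]
        lv <- lv[lv != cd]
        if (length(lv)) {
          t <- tabulate(lv + 1L, 7L)
          votes <- votes + t
        }
      }
      labels[idx] <- if (any(votes > 0)) which.max(votes) - 1L else 0L
    }
  }
  labels
}

#' Write a phantom volume to disk
#'
#' Writes the attenuation volume as multi-page 16-bit TIFF (with the scale
#' recorded in the YAML sidecar), labels as 8-bit TIFF, the specification as
#' YAML and the analytic ground truth as CSV.
#'
#' @param vol a [PhantomVolume-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writePhantomVolume <- function(vol, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  maxAtt <- max(vol@attenuation, 1e-12)
  pages <- lapply(seq_len(dim(vol@attenuation)[3]), function(z)
    t(vol@attenuation[, , z]) / maxAtt)
  tiff::writeTIFF(pages, file.path(dir, "attenuation.tif"),
                  bits.per.sample = 16L)
  labPages <- lapply(seq_len(dim(vol@labels)[3]), function(z)
    t(vol@labels[, , z]) / 255)
  tiff::writeTIFF(labPages, file.path(dir, "labels.tif"),
                  bits.per.sample = 8L)
  spec <- vol@spec
  yaml::write_yaml(list(
    voxel_size_um = vol@voxelSizeUm,
    attenuation_scale = maxAtt,
    n_turns = spec@nTurns,
    centerline_length_mm = spec@centerlineLengthMm,
    base_radius_mm = spec@baseRadiusMm, apex_radius_mm = spec@apexRadiusMm,
    pitch_mm = spec@pitchMm,
    membrane_thickness_um = spec@membraneThicknessUm,
    wall_thickness_um = spec@wallThicknessUm,
    aspect_ratio = spec@aspectRatio,
    grid_shape = as.integer(spec@gridShape)),
    file.path(dir, "phantom.yaml"))
  truth <- vol@areaTruth
  truth$arc_mm <- truth$s * spec@centerlineLengthMm
  write.csv(truth[, c("s", "arc_mm", "compartment", "area_mm2")],
            file.path(dir, "area_truth.csv"), row.names = FALSE)
  write.csv(as.data.frame(vol@centerlineTruth),
            file.path(dir, "centerline_truth.csv"), row.names = FALSE)
  invisible(dir)
}
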