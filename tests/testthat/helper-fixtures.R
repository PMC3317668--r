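## Shared fixtures, built in code and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

## the paper-matched default phantom (256^3 at 8 um); ~10 s to build
cachedDefaultPhantom <- function() {
  if (is.null(.fixtures$phantom))
    .fixtures$phantom <- buildPhantom(defaultPhantomSpec())
  .fixtures$phantom
}

## the full noise-free default pipeline run (several minutes); shared by the
## length and area recovery checks
cachedDefaultRun <- function() {
  if (is.null(.fixtures$run))
    .fixtures$run <- runPipeline(runConfig(artifacts = "off", seed = 1L))
  .fixtures$run
}

## straight vertical duct (degenerate spiral), constant areas
cylinderSpec <- function(voxelSizeUm = 8, gridShape = c(128, 128, 128),
                         attenuationMap = NULL) {
  args <- list(
    nTurns = 0, centerlineLengthMm = 0.6, baseRadiusMm = 0.2,
    apexRadiusMm = 0.2, pitchMm = 0,
    areaAnchors = list(st = cbind(c(0, 1), c(0.02, 0.02)),
                       sm = cbind(c(0, 1), c(0.01, 0.01)),
                       sv = cbind(c(0, 1), c(0.015, 0.015))),
    ridgeRadiusUm = 10,
    voxelSizeUm = voxelSizeUm, gridShape = gridShape)
  if (!is.null(attenuationMap)) args$attenuationMap <- attenuationMap
  do.call(phantomSpec, args)
}

## small spiral for fast end-to-end runs
tinySpec <- function() {
  phantomSpec(nTurns = 1.25, centerlineLengthMm = 2.0,
              baseRadiusMm = 0.28, apexRadiusMm = 0.22, pitchMm = 0.35,
              areaAnchors = list(st = cbind(c(0, 1), c(0.02, 0.012)),
                                 sm = cbind(c(0, 1), c(0.008, 0.008)),
                                 sv = cbind(c(0, 1), c(0.015, 0.008))),
              voxelSizeUm = 12, gridShape = c(96L, 96L, 96L))
}

## single-slice centered disk attenuation volume (mm^-1)
diskVolume <- function(n = 64, nz = 4, radiusPx = 16, mu = 0.05,
                       center = c((n + 1) / 2, (n + 1) / 2)) {
  att <- array(0, c(n, n, nz))
  for (x in seq_len(n)) for (y in seq_len(n))
    if ((x - center[1])^2 + (y - center[2])^2 <= radiusPx^2)
      att[x, y, ] <- mu
  att
}

## brute-force ray-sum oracle: nearest-voxel marching at 0.25-voxel steps
oracleRaySum <- function(att, angleDeg, col, nCols, voxelSizeUm,
                         axisOffsetPx = 0) {
  d <- dim(att)
  th <- angleDeg * pi / 180
  u <- col - (nCols - 1) / 2 - 1 - axisOffsetPx       # 0-based center
  cx <- (d[1] - 1) / 2; cy <- (d[2] - 1) / 2
  tmax <- sqrt(sum(d[1:2]^2))
  ts <- seq(-tmax, tmax, by = 0.25)
  xs <- cx + u * cos(th) - ts * sin(th)
  ys <- cy + u * sin(th) + ts * cos(th)
  ix <- round(xs) + 1; iy <- round(ys) + 1
  ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2]
  out <- numeric(d[3])
  for (z in seq_len(d[3]))
    out[z] <- sum(att[cbind(ix[ok], iy[ok], z)]) * 0.25 * voxelSizeUm / 1000
  out
}
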