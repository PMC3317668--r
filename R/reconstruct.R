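## Row-wise filtered backprojection.
##
## Each detector row yields one sinogram; corrected intensities are mapped
## to line integrals with s = -ln(c / 65536) (c clamped to [1, 65536]),
## ramp-filtered in the frequency domain (discrete Ram-Lak kernel,
## zero-padded to the next power of two >= 2x columns, optional
## Shepp-Logan / Hann apodization), shifted by -axisOffsetPx to center the
## rotation axis, and backprojected with linear interpolation and angular
## weight pi / (2 N).

#' Extract the sinogram of one detector row
#'
#' @param stack a [CorrectedStack-class].
#' @param rowIndex detector row (1-based).
#' @param applyLog map corrected intensity c to -ln(c/65536) with c clamped
#'   to \[1, 65536\] (the attenuation line-integral convention). With
#'   `FALSE` the raw transmission c/65536 is reconstructed directly.
#' @return a [Sinogram-class] (angles x columns).
#' @export
assembleSinogram <- function(stack, rowIndex, applyLog = TRUE) {
  d <- dim(stack@frames)
  if (rowIndex < 1 || rowIndex > d[1])
    stop("row index ", rowIndex, " out of range 1..", d[1])
  vals <- t(stack@frames[rowIndex, , ])            # angles x columns
  if (applyLog) {
    vals <- -log(pmin(pmax(vals, 1), 65536) / 65536)
  } else {
    vals <- vals / 65536
  }
  new("Sinogram", values = vals, anglesDeg = stack@anglesDeg,
      axisOffsetPx = stack@axisOffsetPx, pixelSizeUm = stack@pixelSizeUm)
}

## discrete ramp filter (frequency response of the exact discrete kernel)
## with optional apodization, length n (padded size)
rampFilter <- function(n, type = c("ramlak", "shepp", "hann")) {
  type <- match.arg(type)
  m <- c(0:(n / 2), (-n / 2 + 1):-1)               # wrapped sample offsets
  f <- numeric(n)
  f[1] <- 0.25
  odd <- which(m %% 2 != 0)
  f[odd] <- -1 / (pi * m[odd])^2
  filt <- 2 * Re(fft(f))
  if (type != "ramlak") {
    fr <- m / n                                    # cycles/sample, [-0.5, 0.5)
    if (type == "shepp") {
      w <- rep(1, n)
      nz <- fr != 0
      w[nz] <- sin(pi * fr[nz]) / (pi * fr[nz])
    } else {
      w <- 0.5 * (1 + cos(2 * pi * fr))
    }
    filt <- filt * w
  }
  filt
}

## shift each row of a matrix by `shift` columns (sub-pixel, linear
## interpolation, zero fill outside)
shiftRows <- function(m, shift) {
  if (shift == 0) return(m)
  n <- ncol(m)
  xout <- seq_len(n) - shift
  t(apply(m, 1, function(r) {
    y <- approx(seq_len(n), r, xout = xout, rule = 1)$y
    y[is.na(y)] <- 0
    y
  }))
}

#' Filtered backprojection of one sinogram
#'
#' @param sinogram a [Sinogram-class] with uniformly spaced angles.
#' @param filter `"ramlak"` (default), `"shepp"` or `"hann"`.
#' @param compensateOffset shift filtered projections by `-axisOffsetPx`
#'   before backprojection to center the rotation axis.
#' @return a square slice (columns x columns matrix), in the sinogram's
#'   per-pixel units.
#' @export
fbpSlice <- function(sinogram, filter = "ramlak", compensateOffset = TRUE) {
  vals <- sinogram@values
  nA <- nrow(vals); nDet <- ncol(vals)
  if (nA < 2) stop("at least 2 angles required")
  sp <- diff(sinogram@anglesDeg)
  if (max(abs(sp - sp[1])) > 1e-6)
    stop("non-uniform angle spacing; uniform angles are required")
  pad <- 2^ceiling(log2(2 * nDet))
  filt <- rampFilter(pad, filter)
  Z <- matrix(0, pad, nA)
  Z[seq_len(nDet), ] <- t(vals)
  Ff <- mvfft(Z) * filt
  filtered <- t(Re(mvfft(Ff, inverse = TRUE))[seq_len(nDet), ]) / pad
  off <- sinogram@axisOffsetPx
  if (compensateOffset && is.finite(off) && off != 0)
    filtered <- shiftRows(filtered, -off)
  cpp_backproject(filtered, sinogram@anglesDeg * pi / 180) * pi / (2 * nA)
}

#' Reconstruct a volume row by row
#'
#' Stacks [fbpSlice()] outputs over the requested detector rows.  With the
#' log transform active the output is scaled to attenuation per mm.
#'
#' @param stack a [CorrectedStack-class] with a known axis offset.
#' @param rows detector rows to reconstruct (default all).
#' @param filter ramp filter apodization, see [fbpSlice()].
#' @param applyLog see [assembleSinogram()].
#' @param compensateOffset see [fbpSlice()].
#' @return a [ReconVolume-class] (x, y, z = row).
#' @export
reconstructVolume <- function(stack, rows = NULL, filter = "ramlak",
                              applyLog = TRUE, compensateOffset = TRUE) {
  d <- dim(stack@frames)
  if (is.null(rows)) rows <- seq_len(d[1])
  if (!is.finite(stack@axisOffsetPx))
    stop("axis offset not set; run estimateAxisOffset() or assign one")
  scale <- if (applyLog) 1 / (stack@pixelSizeUm / 1000) else 1
  out <- array(0, c(d[2], d[2], length(rows)))
  for (i in seq_along(rows)) {
    sino <- assembleSinogram(stack, rows[i], applyLog = applyLog)
    out[, , i] <- fbpSlice(sino, filter = filter,
                           compensateOffset = compensateOffset) * scale
  }
  new("ReconVolume", values = out, voxelSizeUm = stack@pixelSizeUm,
      provenance = list(filter = filter, log = applyLog,
                        axisOffsetPx = stack@axisOffsetPx,
                        anglesDeg = stack@anglesDeg, rows = rows))
}

#' Analytic sinogram of a centered uniform disk
#'
#' Parallel-beam line integrals of a disk of radius `radiusPx` and
#' attenuation `muPerPx` are the chord lengths `2 sqrt(R^2 - u^2) * mu`,
#' identical at every angle.  Serves as a closed-form oracle input for the
#' reconstruction stage.
#'
#' @param nDet detector columns.
#' @param nAngles number of uniformly spaced angles over \[0, 180).
#' @param radiusPx disk radius (pixels).
#' @param muPerPx attenuation per pixel.
#' @param axisOffsetPx rotation-axis offset baked into the sinogram.
#' @param pixelSizeUm pixel size metadata.
#' @return a [Sinogram-class].
#' @export
diskSinogram <- function(nDet, nAngles, radiusPx, muPerPx,
                         axisOffsetPx = 0, pixelSizeUm = 1) {
  u <- (seq_len(nDet) - (nDet + 1) / 2) - axisOffsetPx
  chord <- 2 * sqrt(pmax(radiusPx^2 - u^2, 0)) * muPerPx
  new("Sinogram",
      values = matrix(chord, nAngles, nDet, byrow = TRUE),
      anglesDeg = seq(0, 180, length.out = nAngles + 1)[seq_len(nAngles)],
      axisOffsetPx = axisOffsetPx, pixelSizeUm = pixelSizeUm)
}
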