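## Flat/dark-field correction, 2x2 binning and rotation-axis estimation.

#' Flat/dark-field correction of one frame
#'
#' Applies the standard normalization
#' `(raw - dark) / (flat - dark) * 65536`, where 65536 rescales the result
#' back onto the 16-bit intensity scale.  Output stays floating-point;
#' pixels where the flat equals the dark field carry no information and are
#' set to 0.
#'
#' @param raw,flat,dark numeric matrices of identical shape.
#' @return the corrected frame (numeric matrix, not re-quantized).
#' @export
correctFrame <- function(raw, flat, dark) {
  if (!all(dim(raw) == dim(flat)) || !all(dim(raw) == dim(dark)))
    stop("raw, flat and dark frames must share shape")
  denom <- flat - dark
  degenerate <- denom == 0
  nDeg <- sum(degenerate)
  if (nDeg == length(denom))
    stop("flat field equals dark field everywhere; correction undefined")
  if (nDeg > 0.01 * length(denom))
    warning(nDeg, " degenerate pixels (flat = dark) set to 0")
  out <- (raw - dark) / denom * 65536
  out[degenerate] <- 0
  out
}

#' Correct a whole projection set
#'
#' @param set a [ProjectionSet-class].
#' @return a [CorrectedStack-class]; the axis offset recorded in the scan
#'   geometry is carried over (re-estimate with [estimateAxisOffset()] if
#'   it is unknown for real data).
#' @export
correctProjections <- function(set) {
  d <- dim(set@raw)
  frames <- array(0, d)
  for (a in seq_len(d[3]))
    frames[, , a] <- correctFrame(set@raw[, , a], set@flat, set@dark)
  new("CorrectedStack", frames = frames,
      anglesDeg = set@geometry@anglesDeg,
      axisOffsetPx = set@geometry@axisOffsetPx,
      pixelSizeUm = set@geometry@pixelSizeUm, binned = FALSE)
}

#' 2x2 binning by block mean
#'
#' Each output pixel is the arithmetic mean of a 2x2 input block, so the
#' corrected intensity scale is preserved; the effective pixel size doubles.
#' An odd trailing row/column is dropped with a warning.
#'
#' @param x a numeric matrix or a [CorrectedStack-class].
#' @return the binned matrix, or the binned stack with doubled
#'   `pixelSizeUm` and `binned = TRUE`.
#' @export
bin2x2 <- function(x) {
  if (is(x, "CorrectedStack")) {
    d <- dim(x@frames)
    first <- bin2x2(x@frames[, , 1])
    out <- array(0, c(dim(first), d[3]))
    out[, , 1] <- first
    if (d[3] > 1) for (a in 2:d[3])
      out[, , a] <- suppressWarnings(bin2x2(x@frames[, , a]))
    return(new("CorrectedStack", frames = out, anglesDeg = x@anglesDeg,
               axisOffsetPx = x@axisOffsetPx / 2,
               pixelSizeUm = x@pixelSizeUm * 2, binned = TRUE))
  }
  nr <- nrow(x); nc <- ncol(x)
  if (nr %% 2L || nc %% 2L) {
    warning("odd dimension; trailing row/column dropped")
    nr <- nr - nr %% 2L; nc <- nc - nc %% 2L
    x <- x[seq_len(nr), seq_len(nc), drop = FALSE]
  }
  ro <- seq(1, nr, by = 2); co <- seq(1, nc, by = 2)
  (x[ro, co, drop = FALSE] + x[ro + 1, co, drop = FALSE] +
     x[ro, co + 1, drop = FALSE] + x[ro + 1, co + 1, drop = FALSE]) / 4
}

#' Estimate the rotation-axis offset from a 0/180-degree mirror pair
#'
#' Cross-correlates the column profile of the first (0 degree) frame with
#' the horizontally mirrored profile of the last frame (at 180 - delta
#' degrees, delta <= 1); the correlation peak sits at twice the axis offset.
#' Parabolic interpolation around the peak gives sub-pixel precision.
#'
#' @param stack a [CorrectedStack-class] containing frames at 0 and at
#'   >= 179 degrees.
#' @return the estimated offset in columns from the detector center.
#' @export
estimateAxisOffset <- function(stack) {
  a <- stack@anglesDeg
  if (abs(a[1]) > 1e-6 || a[length(a)] < 179 - 1e-6)
    stop("stack must contain a 0 degree frame and a frame at >= 179 degrees")
  p0 <- colMeans(stack@frames[, , 1])
  pM <- rev(colMeans(stack@frames[, , length(a)]))
  if (sd(p0) < 1e-9 || sd(pM) < 1e-9)
    stop("featureless frames; supply the axis offset manually")
  p0 <- p0 - mean(p0); pM <- pM - mean(pM)
  n <- length(p0)
  L <- floor(n / 4)
  lags <- -L:L
  cc <- vapply(lags, function(l) {
    j <- seq_len(n)
    k <- j - l
    ok <- k >= 1 & k <= n
    if (sum(ok) < 8) return(-Inf)
    suppressWarnings(cor(p0[j[ok]], pM[k[ok]]))
  }, numeric(1))
  cc[!is.finite(cc)] <- -Inf
  i <- which.max(cc)
  if (cc[i] < 0.2)
    stop("featureless frames (correlation peak ", round(cc[i], 3),
         " < 0.2); supply the axis offset manually")
  lag <- lags[i]
  if (i > 1 && i < length(cc) && is.finite(cc[i - 1]) && is.finite(cc[i + 1])) {
    d2 <- cc[i - 1] - 2 * cc[i] + cc[i + 1]
    if (d2 < 0) lag <- lag + 0.5 * (cc[i - 1] - cc[i + 1]) / d2
  }
  lag / 2
}
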