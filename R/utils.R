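`%||%` <- function(a, b) if (is.null(a)) b else a

## standard label legends
binaryLegend <- c(`0` = "exterior", `1` = "interior")
compartmentLegend <- c(`0` = "exterior", `1` = "bone", `2` = "st",
                       `3` = "sm", `4` = "sv", `5` = "membranes",
                       `6` = "organ_of_corti")

#' Label legends used by the pipeline
#'
#' `cochlearLegend()` returns the compartment legend (0 exterior, 1 bone,
#' 2 scala tympani, 3 scala media, 4 scala vestibuli, 5 membranes, 6
#' organ-of-Corti ridge); `interiorLegend()` the binary exterior/interior
#' legend of the thresholding stage.
#'
#' @return named character vector mapping label codes to tissue names.
#' @export
cochlearLegend <- function() compartmentLegend

#' @rdname cochlearLegend
#' @export
interiorLegend <- function() binaryLegend

## resolve a compartment given as code or name against a legend
resolveCompartment <- function(compartment, legend) {
  if (is.character(compartment)) {
    hit <- match(compartment, legend)
    if (is.na(hit))
      stop("unknown compartment '", compartment, "'; legend has: ",
           paste(legend, collapse = ", "))
    return(as.integer(names(legend)[hit]))
  }
  code <- as.integer(compartment)
  if (!as.character(code) %in% names(legend))
    stop("unknown compartment code ", code)
  code
}

## derive a deterministic per-stage seed from the run seed
stageSeed <- function(seed, stage) {
  offsets <- c(project = 1L, flat = 2L, dark = 3L, rings = 4L)
  s <- (as.integer(seed) + 7919L * (offsets[[stage]] %||% 0L)) %% 2147483647L
  as.integer(s)
}

## uniform arc-length resampling of an n x 3 polyline (rows = points)
resamplePolyline <- function(points, stepUm) {
  seg <- sqrt(rowSums(diff(points)^2))
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  s <- seq(0, total, by = stepUm)
  if (s[length(s)] < total - 1e-9) s <- c(s, total)
  out <- cbind(approx(arc, points[, 1], xout = s)$y,
               approx(arc, points[, 2], xout = s)$y,
               approx(arc, points[, 3], xout = s)$y)
  attr(out, "arcUm") <- s
  out
}

## running-mean smoothing of polyline coordinates (odd window); windows
## shrink symmetrically near the ends so end tangents are not biased inward
smoothPolyline <- function(points, window) {
  if (window <= 1L) return(points)
  if (window %% 2L == 0L) stop("smoothing window must be odd")
  h <- (window - 1L) / 2L
  n <- nrow(points)
  out <- points
  for (i in seq_len(n)) {
    hi <- min(h, i - 1L, n - i)
    j <- (i - hi):(i + hi)
    out[i, ] <- colMeans(points[j, , drop = FALSE])
  }
  out
}
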