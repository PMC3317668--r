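## End-to-end phantom study: simulate -> correct -> reconstruct -> segment
## -> measure, with persisted intermediates, a resolved config beside the
## outputs, and a report comparing measured morphometry against the
## phantom's analytic ground truth.

#' Construct a pipeline run configuration
#'
#' @param spec `"default"` or a [PhantomSpec-class].
#' @param artifacts `"default"`, `"off"` (noise-free) or an
#'   [ArtifactModel-class]; the run seed always overrides the model's seed.
#' @param anglesDeg projection angles.
#' @param axisOffsetPx simulated rotation-axis offset (columns).
#' @param axis `"auto"` (estimate from the 0/180 mirror pair), `"known"`
#'   (trust the simulation geometry) or a numeric offset.
#' @param binFactor 1 (no binning) or 2 (2x2 binning after correction).
#' @param threshold `"auto"` (Otsu) or numeric, for the exterior/interior
#'   stage.
#' @param connectivity 6, 18 or 26 for couch removal.
#' @param annotationStride every k-th slice of the phantom labels acts as
#'   an operator-annotated slice for propagation.
#' @param stepMm arc step of landmarks and area stations (mm).
#' @param planeExtentUm half-extent of the section planes (um).
#' @param searchRadiusUm ridge landmark search radius (um).
#' @param maskToInterior zero compartment labels outside the binary
#'   interior mask before measuring.
#' @param seed integer run seed feeding all stage substreams.
#' @param outputDir directory for intermediates and the report (created);
#'   `NULL` keeps everything in memory.
#' @param writeIntermediates persist projections/volumes/labels (TIFF).
#' @return a validated run configuration (list, class `cochleaRunConfig`).
#' @export
runConfig <- function(spec = "default", artifacts = "default",
                      anglesDeg = 0:179, axisOffsetPx = 0, axis = "auto",
                      binFactor = 1, threshold = "auto", connectivity = 26,
                      annotationStride = 4L, stepMm = 0.05,
                      planeExtentUm = 500, searchRadiusUm = 40,
                      maskToInterior = FALSE, seed = 1L, outputDir = NULL,
                      writeIntermediates = FALSE) {
  cfg <- list(spec = spec, artifacts = artifacts, anglesDeg = anglesDeg,
              axisOffsetPx = axisOffsetPx, axis = axis,
              binFactor = binFactor, threshold = threshold,
              connectivity = connectivity,
              annotationStride = as.integer(annotationStride),
              stepMm = stepMm, planeExtentUm = planeExtentUm,
              searchRadiusUm = searchRadiusUm,
              maskToInterior = maskToInterior, seed = as.integer(seed),
              outputDir = outputDir, writeIntermediates = writeIntermediates)
  class(cfg) <- "cochleaRunConfig"
  validateRunConfig(cfg)
  cfg
}

#' @rdname runConfig
#' @param config a run configuration to validate.
#' @export
validateRunConfig <- function(config) {
  if (!config$connectivity %in% c(6, 18, 26))
    stop("invalid connectivity ", config$connectivity,
         "; must be 6, 18 or 26")
  if (!config$binFactor %in% c(1, 2))
    stop("binFactor must be 1 or 2")
  if (!(identical(config$threshold, "auto") ||
        (is.numeric(config$threshold) && is.finite(config$threshold))))
    stop("threshold must be 'auto' or a finite number")
  if (config$annotationStride < 1L) stop("annotationStride must be >= 1")
  if (config$stepMm <= 0) stop("stepMm must be > 0")
  if (!(identical(config$axis, "auto") || identical(config$axis, "known") ||
        is.numeric(config$axis)))
    stop("axis must be 'auto', 'known' or a number")
  if (!identical(config$spec, "default") && !is(config$spec, "PhantomSpec"))
    stop("spec must be 'default' or a PhantomSpec")
  invisible(config)
}

resolveArtifacts <- function(artifacts, seed) {
  am <- if (identical(artifacts, "default")) artifactModel()
  else if (identical(artifacts, "off")) quietArtifactModel()
  else artifacts
  am@rngSeed <- as.integer(seed)
  am
}

## median-of-3 smoothing of areas within one compartment, ordered by arc
smoothProfile <- function(areas, k = 3L) {
  if (length(areas) < k) return(areas)
  as.numeric(stats::runmed(areas, k))
}

profileSummary <- function(profile, truthFun, lengthMm) {
  out <- list()
  for (nm in unique(profile$compartment)) {
    p <- profile[profile$compartment == nm & profile$valid, ]
    p <- p[order(p$arc_mm), ]
    if (nrow(p) == 0L) next
    sm <- smoothProfile(p$area_mm2)
    tf <- truthFun(nm)
    truthAreas <- tf(pmin(p$arc_mm / lengthMm, 1))
    out[[nm]] <- list(
      base_mm2 = p$area_mm2[1],
      min_mm2 = min(sm),
      mean_mm2 = mean(p$area_mm2),
      truth_base_mm2 = truthAreas[1],
      truth_min_mm2 = min(tf(seq(0, 1, by = 0.01))),
      truth_mean_mm2 = mean(tf(seq(0, 1, by = 0.01))),
      stations = nrow(p),
      invalid_stations = sum(profile$compartment == nm & !profile$valid))
  }
  out
}

#' Run the full phantom pipeline
#'
#' Executes phantom build, projection simulation, flat/dark correction,
#' optional binning, axis estimation, filtered backprojection,
#' exterior/interior thresholding with couch removal, sparse-annotation
#' propagation, ridge landmark extraction, centerline length and area
#' profiling, and compares every measurement against the phantom's
#' analytic ground truth.  Identical configuration and seed give an
#' identical report.
#'
#' @param config a [runConfig()] object.
#' @return invisibly, a list with `report` plus the main in-memory stage
#'   products (`phantom`, `projections`, `recon`, `interior`,
#'   `compartments`, `landmarksUm`, `profile`).
#' @export
runPipeline <- function(config) {
  validateRunConfig(config)
  outDir <- config$outputDir
  persist <- !is.null(outDir) && config$writeIntermediates
  if (!is.null(outDir)) dir.create(outDir, recursive = TRUE,
                                   showWarnings = FALSE)

  spec <- if (identical(config$spec, "default")) defaultPhantomSpec()
          else config$spec
  phantom <- buildPhantom(spec)
  vox <- phantom@voxelSizeUm
  d <- dim(phantom@labels)

  geometry <- scanGeometry(anglesDeg = config$anglesDeg,
                           detectorShape = c(d[3], d[1]),
                           axisOffsetPx = config$axisOffsetPx,
                           pixelSizeUm = vox)
  artifacts <- resolveArtifacts(config$artifacts, config$seed)
  projections <- simulateProjections(phantom, geometry, artifacts)
  if (persist) writeProjectionSet(projections,
                                  file.path(outDir, "projections"))

  stack <- correctProjections(projections)
  if (config$binFactor == 2) stack <- bin2x2(stack)
  if (identical(config$axis, "auto")) {
    stack@axisOffsetPx <- estimateAxisOffset(stack)
  } else if (is.numeric(config$axis)) {
    stack@axisOffsetPx <- config$axis
  }
  recon <- reconstructVolume(stack)
  if (persist) writeVolumeTiff(recon@values, file.path(outDir, "recon.tif"))

  binary <- thresholdSegment(recon, config$threshold)
  interior <- keepLargestComponent(binary, config$connectivity)

  nz <- dim(phantom@labels)[3]
  annotated <- unique(c(seq(1L, nz, by = config$annotationStride), nz))
  sparse <- lapply(annotated, function(z)
    list(slice = z, labels = phantom@labels[, , z]))
  compartments <- propagateLabels(sparse, dim(phantom@labels),
                                  legend = cochlearLegend(),
                                  voxelSizeUm = vox)
  if (config$maskToInterior) {
    lab <- compartments@labels
    lab[interior@labels == 0L] <- 0L
    compartments <- new("LabelVolume", labels = lab,
                        legend = compartments@legend, voxelSizeUm = vox,
                        provenance = compartments@provenance)
  }
  if (persist) writeVolumeTiff(compartments@labels / 255,
                               file.path(outDir, "labels.tif"), bits = 8L)

  guide <- resamplePolyline(phantom@centerlineTruth, config$stepMm * 1000)
  landmarks <- extractRidgeLandmarks(compartments, guide,
                                     searchRadiusUm = config$searchRadiusUm)
  len <- polylineLength(landmarks / vox, calibrationUmPerPx = vox)
  truthLen <- spec@centerlineLengthMm

  profile <- areaProfile(compartments, landmarks,
                         stepMm = config$stepMm,
                         planeExtentUm = config$planeExtentUm)
  if (persist) write.csv(profile, file.path(outDir, "area_profile.csv"),
                         row.names = FALSE)

  truthFun <- function(nm) areaProfileFun(spec, nm)
  areas <- profileSummary(profile, truthFun, truthLen)
  fgCount <- sum(phantom@labels != 0L)
  report <- list(
    seed = config$seed,
    stages = c("phantom", "simulate", "preprocess", "reconstruct",
               "segment", "measure"),
    phantom = list(grid = as.integer(d), voxel_um = vox,
                   foreground_voxels = fgCount),
    axis = list(simulated_px = config$axisOffsetPx,
                used_px = stack@axisOffsetPx),
    binary = list(threshold = interior@provenance$threshold,
                  interior_voxels = interior@provenance$largestComponentVoxels,
                  phantom_foreground_voxels = fgCount),
    length = list(measured_mm = unname(len[["mm"]]),
                  truth_mm = truthLen,
                  abs_error_mm = unname(len[["mm"]]) - truthLen,
                  rel_error = (unname(len[["mm"]]) - truthLen) / truthLen,
                  landmarks = nrow(landmarks)),
    areas = lapply(areas, function(a) {
      a$rel_error_base <- (a$base_mm2 - a$truth_base_mm2) / a$truth_base_mm2
      a$rel_error_min <- (a$min_mm2 - a$truth_min_mm2) / a$truth_min_mm2
      a$rel_error_mean <- (a$mean_mm2 - a$truth_mean_mm2) / a$truth_mean_mm2
      a
    }))
  if (!is.null(outDir)) {
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    yaml::write_yaml(configAsList(config), file.path(outDir, "config.yaml"))
  }
  invisible(list(report = report, phantom = phantom,
                 projections = projections, recon = recon,
                 interior = interior, compartments = compartments,
                 landmarksUm = landmarks, profile = profile))
}

## write a numeric volume as multi-page TIFF (32-bit float by default)
writeVolumeTiff <- function(vol, path, bits = 32L) {
  pages <- lapply(seq_len(dim(vol)[3]), function(z) {
    pg <- t(vol[, , z])
    if (bits == 32L) pg else pmin(pmax(pg, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Compare a measured area profile against ground truth
#'
#' Interpolates the (dense) truth profile at every valid measured station
#' and tabulates absolute and relative errors.
#'
#' @param profile measured profile data.frame from [areaProfile()].
#' @param truth ground-truth profile data.frame (e.g.
#'   [analyticAreaProfile()] output, or the phantom's `areaTruth` slot).
#' @return data.frame of per-station errors with a `summary` attribute
#'   (mean/max absolute relative error per compartment).
#' @export
compareToTruth <- function(profile, truth) {
  shared <- intersect(unique(profile$compartment),
                      unique(truth$compartment))
  if (length(shared) == 0L)
    stop("no shared compartments between profile and truth")
  rows <- list()
  for (nm in shared) {
    p <- profile[profile$compartment == nm & profile$valid, ]
    tr <- truth[truth$compartment == nm, ]
    if (nrow(p) == 0L) next
    if (min(p$arc_mm) > max(tr$arc_mm) || max(p$arc_mm) < min(tr$arc_mm))
      stop("disjoint arc ranges for compartment ", nm)
    tf <- approxfun(tr$arc_mm, tr$area_mm2, rule = 2)
    expect <- tf(p$arc_mm)
    rows[[nm]] <- data.frame(
      arc_mm = p$arc_mm, compartment = nm, measured_mm2 = p$area_mm2,
      truth_mm2 = expect, abs_error_mm2 = p$area_mm2 - expect,
      rel_error = (p$area_mm2 - expect) / expect)
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- do.call(rbind, lapply(split(out, out$compartment),
    function(g) data.frame(compartment = g$compartment[1],
                           mean_abs_rel = mean(abs(g$rel_error)),
                           max_abs_rel = max(abs(g$rel_error)))))
  out
}

## serializable form of a run configuration (YAML round trip)
configAsList <- function(config) {
  out <- unclass(config)
  out$outputDir <- NULL
  if (is(out$spec, "PhantomSpec")) out$spec <- specAsList(out$spec)
  if (is(out$artifacts, "ArtifactModel"))
    out$artifacts <- artifactsAsList(out$artifacts)
  out
}

specAsList <- function(spec) list(
  nTurns = spec@nTurns, centerlineLengthMm = spec@centerlineLengthMm,
  baseRadiusMm = spec@baseRadiusMm, apexRadiusMm = spec@apexRadiusMm,
  pitchMm = spec@pitchMm,
  areaAnchors = lapply(spec@areaAnchors, function(m)
    list(s = as.numeric(m[, 1]), area_mm2 = as.numeric(m[, 2]))),
  membraneThicknessUm = spec@membraneThicknessUm,
  wallThicknessUm = spec@wallThicknessUm, aspectRatio = spec@aspectRatio,
  ridgeRadiusUm = spec@ridgeRadiusUm, overhangMm = spec@overhangMm,
  attenuationMap = as.list(spec@attenuationMap),
  voxelSizeUm = spec@voxelSizeUm, gridShape = as.integer(spec@gridShape))

artifactsAsList <- function(a) list(
  photonScale = a@photonScale, darkOffsetCounts = a@darkOffsetCounts,
  darkNoiseSd = a@darkNoiseSd, flatRelief = a@flatRelief,
  edgeEnhanceStrength = a@edgeEnhanceStrength,
  ringArtifactSd = a@ringArtifactSd, poissonNoise = a@poissonNoise,
  rngSeed = a@rngSeed)
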