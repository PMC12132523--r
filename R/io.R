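## Readers and writers: TIFF stacks, CSV schemas, JSON transforms, YAML
## config. CSV dialect: comma-separated, UTF-8, '.' decimal, header row,
## NA as empty field.

writeCsv <- function(df, path) {
  write.csv(df, path, row.names = FALSE, na = "")
}

readCsv <- function(path) {
  if (!file.exists(path)) stopFormat(paste("file not found:", path))
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a recording's image stack as multi-frame grayscale TIFF
#'
#' Frames are stored as 32-bit float planes in acquisition order, scaled
#' into `[0, 1]` by the global stack maximum (every downstream measurement
#' step is invariant to a global intensity scale). Unrendered frames are
#' skipped with a warning.
#'
#' @param recording a [SyntheticRecording-class] with a rendered stack.
#' @param path output file.
#' @return invisibly, the number of frames written.
#' @export
writeRecordingTiff <- function(recording, path) {
  if (is.null(recording@stack)) stopValidation("recording has no image stack")
  frames <- apply(recording@stack, 3L, identity, simplify = FALSE)
  ok <- vapply(frames, function(f) all(is.finite(f)), logical(1L))
  if (!all(ok)) {
    warning("skipping unrendered frames: ",
            paste(which(!ok), collapse = ", "))
    frames <- frames[ok]
  }
  lo <- min(vapply(frames, min, numeric(1L)))
  hi <- max(vapply(frames, max, numeric(1L)))
  scale <- if (hi > lo) hi - lo else 1
  frames <- lapply(frames, function(f) (f - lo) / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(length(frames))
}

#' Read an ablation recording from a TIFF stack and geometry row
#'
#' @param stackPath multi-frame grayscale TIFF (>= 3 frames).
#' @param geometryRow one-row data.frame or list with recording_id,
#'   center_x_um, center_y_um, axis ("ML"/"RC"), length_um, pixel_size_um
#'   and optionally frame_interval_s, region, orientation, embryo_id.
#' @return a [SyntheticRecording-class] (truth tracks empty: real mode).
#' @export
readRecording <- function(stackPath, geometryRow) {
  frames <- tiff::readTIFF(stackPath, all = TRUE)
  if (length(frames) < 3L)
    stopFormat("recording must contain at least 3 frames (pre/post pair)")
  px <- geometryRow$pixel_size_um
  if (is.null(px) || is.na(px) || px <= 0)
    stopFormat("missing or invalid pixel size")
  stack <- array(NA_real_, c(dim(frames[[1L]])[1:2], length(frames)))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (length(dim(f)) == 3L) f <- f[, , 1L]
    stack[, , i] <- f
  }
  center <- c(geometryRow$center_x_um, geometryRow$center_y_um)
  axis <- geometryRow$axis
  len <- geometryRow$length_um %||% 36
  spec <- ablationSpec(center = center, axis = axis, length = len,
                       frameInterval = geometryRow$frame_interval_s %||% 0.416,
                       nFrames = length(frames))
  fieldUm <- c(ncol(stack[, , 1L]), nrow(stack[, , 1L])) * px
  ends <- rbind(spec@center + spec@axis * len / 2,
                spec@center - spec@axis * len / 2)
  if (any(ends < 0) || any(ends[, 1L] > fieldUm[1L]) ||
      any(ends[, 2L] > fieldUm[2L]))
    stopGeometry("ablation line exits the image")
  new("SyntheticRecording",
      recordingId = as.character(geometryRow$recording_id %||% "rec"),
      embryoId = as.character(geometryRow$embryo_id %||% "unknown"),
      stack = stack, pixelSize = px, spec = spec, measuredCenter = center,
      measuredAxis = spec@axis,
      truthTracks = data.frame(landmark_id = character(0),
                               role = character(0), side = character(0),
                               frame = integer(0), x_um = numeric(0),
                               y_um = numeric(0)),
      truthV0 = NA_real_,
      region = as.character(geometryRow$region %||% "unknown"),
      orientation = as.character(geometryRow$orientation %||% "unknown"),
      flags = list(bubbles = FALSE, outside_region = FALSE,
                   heartbeat_ok = TRUE))
}

#' Write ground-truth tracks for a set of recordings
#' @param recordings list of [SyntheticRecording-class].
#' @param path output CSV (recording_id, landmark_id, role, frame, x_um,
#'   y_um).
#' @return invisibly, the path.
#' @export
writeTracksCsv <- function(recordings, path) {
  rows <- lapply(recordings, function(r)
    cbind(recording_id = r@recordingId,
          r@truthTracks[, c("landmark_id", "role", "frame", "x_um", "y_um")]))
  writeCsv(do.call(rbind, rows), path)
  invisible(path)
}

#' Serialize / restore a rigid transform as JSON
#' @param transform a [RigidTransform-class].
#' @param path JSON file.
#' @return `writeTransformJson`: invisibly the path; `readTransformJson`:
#'   the [RigidTransform-class].
#' @export
writeTransformJson <- function(transform, path) {
  jsonlite::write_json(list(rotation_deg = transform@rotation,
                            tx_px = transform@translation[1L],
                            ty_px = transform@translation[2L],
                            cx_px = transform@center[1L],
                            cy_px = transform@center[2L]),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTransformJson
#' @export
readTransformJson <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigidTransform(j$rotation_deg, c(j$tx_px, j$ty_px), c(j$cx_px, j$cy_px))
}

# Fixed column order for the measurements CSV schema.
measurementColumns <- function() {
  c("recording_id", "embryo_id", "irv", "orth_irv", "par_irv",
    paste0("recoil_pre", 1:3), paste0("orth_pre", 1:3),
    paste0("par_pre", 1:3), paste0("recoil_post", 1:3),
    paste0("orth_post", 1:3), paste0("par_post", 1:3),
    "delta_t_s", "region", "orientation", "bubbles", "outside_region",
    "insufficient_landmarks")
}

#' Write / read the measurements CSV (bit-stable column order)
#' @param measurements data.frame from [measureCohort()].
#' @param path CSV file.
#' @return `writeMeasurementsCsv`: invisibly the path;
#'   `readMeasurementsCsv`: the data.frame.
#' @export
writeMeasurementsCsv <- function(measurements, path) {
  writeCsv(measurements[, measurementColumns()], path)
  invisible(path)
}

#' @rdname writeMeasurementsCsv
#' @export
readMeasurementsCsv <- function(path) {
  df <- readCsv(path)
  miss <- setdiff(measurementColumns(), names(df))
  if (length(miss))
    stopFormat(paste("measurements CSV missing columns:",
                     paste(miss, collapse = ", ")))
  df
}

#' Serialize a [SimulationConfig-class] to / from YAML
#' @param config a [SimulationConfig-class].
#' @param path YAML file.
#' @return `writeConfigYaml`: invisibly the path; `readConfigYaml`: the
#'   config.
#' @export
writeConfigYaml <- function(config, path) {
  lst <- list(
    groupMeans = config@groupMeans, embryoSd = config@embryoSd,
    withinSd = config@withinSd, nEmbryos = config@nEmbryos,
    ablationsPerEmbryo = config@ablationsPerEmbryo,
    femaleProb = config@femaleProb, somiteRange = config@somiteRange,
    regionWeights = as.list(config@regionWeights),
    orientationWeights = as.list(config@orientationWeights),
    kinetics = list(v0 = config@kinetics@v0, tau = config@kinetics@tau,
                    plateauHalfWidth = config@kinetics@plateauHalfWidth,
                    perpDecayLength = config@kinetics@perpDecayLength,
                    decayAlongCut = config@kinetics@decayAlongCut,
                    endDecayLength = config@kinetics@endDecayLength),
    artifact = list(
      heartbeatAmplitude = config@artifact@heartbeatAmplitude,
      heartbeatPeriod = config@artifact@heartbeatPeriod,
      heartbeatPhase = config@artifact@heartbeatPhase,
      heartbeatDirection = config@artifact@heartbeatDirection,
      drift = config@artifact@drift,
      rotationAmplitude = config@artifact@rotationAmplitude),
    noise = list(photonGain = config@noise@photonGain,
                 readNoiseSd = config@noise@readNoiseSd,
                 background = config@noise@background,
                 membraneIntensity = config@noise@membraneIntensity,
                 psfSigma = config@noise@psfSigma),
    fieldSize = config@fieldSize, pixelSize = config@pixelSize,
    renderImages = config@renderImages,
    unknownSexProb = config@unknownSexProb,
    unknownStageProb = config@unknownStageProb,
    bubblesProb = config@bubblesProb,
    outsideRegionProb = config@outsideRegionProb, seed = config@seed)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname writeConfigYaml
#' @export
readConfigYaml <- function(path) {
  if (!file.exists(path)) stopInvalidConfig(paste("config not found:", path))
  l <- yaml::read_yaml(path)
  simulationConfig(
    groupMeans = as.data.frame(l$groupMeans),
    embryoSd = l$embryoSd, withinSd = l$withinSd, nEmbryos = l$nEmbryos,
    ablationsPerEmbryo = l$ablationsPerEmbryo, femaleProb = l$femaleProb,
    somiteRange = unlist(l$somiteRange),
    regionWeights = unlist(l$regionWeights),
    orientationWeights = unlist(l$orientationWeights),
    kinetics = do.call(recoilKinetics, l$kinetics),
    artifact = do.call(artifactModel, lapply(l$artifact, unlist)),
    noise = do.call(noiseModel, l$noise),
    fieldSize = l$fieldSize, pixelSize = l$pixelSize,
    renderImages = l$renderImages, unknownSexProb = l$unknownSexProb,
    unknownStageProb = l$unknownStageProb, bubblesProb = l$bubblesProb,
    outsideRegionProb = l$outsideRegionProb, seed = l$seed)
}
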