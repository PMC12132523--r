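## Synthetic ablation recordings: ground-truth tracks plus optional
## rasterized membrane-stain frames.

# Along-cut (s) and signed perpendicular (q) coordinates of points relative
# to the ablation line.
cutCoordinates <- function(points, center, axis) {
  n <- normalVector(axis)
  rel <- sweep(points, 2L, center)
  list(s = rel %*% axis, q = rel %*% n)
}

# Per-margin displacement magnitude at time t since ablation. Amplitude is
# solved so that the margin separation increase over the first frame
# interval equals v0 * frameInterval exactly.
marginDisplacement <- function(kinetics, frameInterval, t) {
  if (kinetics@v0 == 0) return(rep(0, length(t)))
  A <- kinetics@v0 * frameInterval /
    (2 * (1 - exp(-frameInterval / kinetics@tau)))
  ifelse(t > 0, A * (1 - exp(-t / kinetics@tau)), 0)
}

# Spatial attenuation of the recoil displacement field. Full displacement on
# a plateau near the cut so that any landmark pair abutting the cut margins
# separates at exactly the ground-truth rate; exponential decay beyond.
recoilAttenuation <- function(s, q, spec, kinetics) {
  L <- spec@length
  aq <- abs(q)
  perp <- ifelse(aq <= kinetics@plateauHalfWidth, 1,
                 exp(-(aq - kinetics@plateauHalfWidth) /
                       kinetics@perpDecayLength))
  as <- abs(s)
  along <- ifelse(as <= L / 2, 1,
                  (1 - kinetics@decayAlongCut) *
                    exp(-(as - L / 2) / kinetics@endDecayLength))
  perp * along
}

# Displacement (n x 2, um) of tissue points at time t since ablation.
recoilField <- function(points, spec, kinetics, t) {
  if (t <= 0 || kinetics@v0 == 0)
    return(matrix(0, nrow(points), 2L))
  cc <- cutCoordinates(points, spec@center, spec@axis)
  d <- marginDisplacement(kinetics, spec@frameInterval, t)
  mag <- d * sign(cc$q) * recoilAttenuation(cc$s, cc$q, spec, kinetics)
  outer(as.numeric(mag), normalVector(spec@axis))
}

# Whole-frame rigid artifact pose at absolute time t (seconds): rotation
# (degrees, about fieldCenter) and translation (um).
artifactPose <- function(artifact, t) {
  ph <- 2 * pi * t / artifact@heartbeatPeriod + artifact@heartbeatPhase
  list(
    rotation = artifact@rotationAmplitude * sin(ph + pi / 3),
    translation = artifact@heartbeatAmplitude * sin(ph) *
      artifact@heartbeatDirection + artifact@drift * t
  )
}

applyPose <- function(points, pose, fieldCenter) {
  R <- rotationMatrix2(pose$rotation)
  sweep(sweep(points, 2L, fieldCenter) %*% t(R), 2L,
        fieldCenter + pose$translation, "+")
}

# Time of frame k (1-based) and recoil time elapsed at frame k. The
# ablation instant is taken as the acquisition time of the pre-ablation
# frame, so the first post-ablation frame sits one full interval after it.
frameTime <- function(spec, frame) (frame - 1) * spec@frameInterval
recoilTime <- function(spec, frame) {
  pmax(0, (frame - spec@ablationBetween[1L])) * spec@frameInterval
}

# Classify mesh vertices into landmark roles around the cut.
assignLandmarkRoles <- function(mesh, spec, kinetics) {
  cc <- cutCoordinates(mesh@vertices, spec@center, spec@axis)
  s <- as.numeric(cc$s); q <- as.numeric(cc$q)
  L <- spec@length
  qmin <- spec@gapWidth / 2 + 0.3
  qmax <- kinetics@plateauHalfWidth - 0.5
  role <- rep(NA_character_, nrow(mesh@vertices))
  role[abs(s) <= L / 6 + 3 & abs(q) >= qmin & abs(q) <= qmax] <- "recoil"
  role[is.na(role) & abs(s) <= L / 2 & abs(q) >= 2 & abs(q) <= 6] <-
    "orthogonal_control"
  role[is.na(role) & abs(s) >= L / 2 + 2 & abs(s) <= L / 2 + 14 &
         abs(q) <= 8] <- "parallel_control"
  data.frame(vertex = which(!is.na(role)), role = role[!is.na(role)],
             side = ifelse(q[!is.na(role)] >= 0, "A", "B"),
             stringsAsFactors = FALSE)
}

# Sample membrane edges as dense points for rendering; returns positions
# plus a weight (splat amplitude factor).
sampleMeshPoints <- function(mesh, spacing = 0.15) {
  v1 <- mesh@vertices[mesh@edges[, 1L], , drop = FALSE]
  v2 <- mesh@vertices[mesh@edges[, 2L], , drop = FALSE]
  len <- sqrt(rowSums((v2 - v1)^2))
  nseg <- pmax(2L, ceiling(len / spacing))
  idx <- rep(seq_len(nrow(v1)), nseg)
  tfrac <- unlist(lapply(nseg, function(k) (seq_len(k) - 0.5) / k))
  pts <- v1[idx, , drop = FALSE] +
    (v2 - v1)[idx, , drop = FALSE] * tfrac
  w <- rep(len / nseg, nseg)   # um of membrane represented by each point
  list(points = pts, weight = w)
}

# Gaussian splat of weighted points onto the pixel grid (rows = y):
# points are binned on a supersampled grid and convolved with the Gaussian
# via FFT, then the fine cells containing the pixel centres are read out.
.kernelCache <- new.env(parent = emptyenv())

splatPoints <- function(points, weight, dims, pixelSize, sigma_um,
                        supersample = 3L) {
  img <- matrix(0, dims[1L], dims[2L])
  if (!nrow(points)) return(img)
  ss <- supersample
  cell <- pixelSize / ss
  n1 <- stats::nextn(dims[1L] * ss + 4L * ss, c(2L, 3L, 5L))
  n2 <- stats::nextn(dims[2L] * ss + 4L * ss, c(2L, 3L, 5L))
  ix <- floor(points[, 1L] / cell) + 1L
  iy <- floor(points[, 2L] / cell) + 1L
  ok <- ix >= 1L & ix <= n2 & iy >= 1L & iy <= n1
  acc <- matrix(0, n1, n2)
  lin <- iy[ok] + (ix[ok] - 1L) * n1
  w <- rowsum(weight[ok], lin)
  acc[as.integer(rownames(w))] <- w[, 1L]

  key <- sprintf("%d_%d_%g_%g", n1, n2, sigma_um, cell)
  Kf <- .kernelCache[[key]]
  if (is.null(Kf)) {
    circ <- function(n) {
      d <- c(0:(n %/% 2L), -((n - n %/% 2L - 1L):1L)) * cell
      d
    }
    k <- outer(exp(-circ(n1)^2 / (2 * sigma_um^2)),
               exp(-circ(n2)^2 / (2 * sigma_um^2))) / (sqrt(2 * pi) * sigma_um)
    Kf <- stats::fft(k)
    .kernelCache[[key]] <- Kf
  }
  conv <- Re(stats::fft(stats::fft(acc) * Kf, inverse = TRUE)) / (n1 * n2)
  # pixel (i, j) centre at ((j - 0.5) px, (i - 0.5) px) -> fine cell
  rows <- floor((seq_len(dims[1L]) - 0.5) * ss) + 1L
  cols <- floor((seq_len(dims[2L]) - 0.5) * ss) + 1L
  img[] <- conv[rows, cols]
  img
}

# Render one frame: membranes (displaced by recoil + artifact), vertex
# blobs, vaporized band removal, background and noise. Noise uses the
# current RNG stream.
renderFrame <- function(mesh, spec, kinetics, artifact, noise, frame,
                        pixelSize, fieldSize, meshSamples, landmarkIdx) {
  dims <- c(round(fieldSize[2L] / pixelSize), round(fieldSize[1L] / pixelSize))
  t_rec <- recoilTime(spec, frame)
  pose <- artifactPose(artifact, frameTime(spec, frame))
  fc <- fieldSize / 2

  pts <- meshSamples$points
  w <- meshSamples$weight
  if (frame >= spec@ablationBetween[2L]) {
    cc <- cutCoordinates(pts, spec@center, spec@axis)
    vaporized <- abs(cc$q) < spec@gapWidth / 2 & abs(cc$s) <= spec@length / 2
    pts <- pts[!vaporized, , drop = FALSE]
    w <- w[!vaporized]
  }
  # tricellular junction enrichment: extra blob at each mesh vertex
  vp <- mesh@vertices
  if (frame >= spec@ablationBetween[2L]) {
    cc <- cutCoordinates(vp, spec@center, spec@axis)
    keepv <- !(abs(cc$q) < spec@gapWidth / 2 & abs(cc$s) <= spec@length / 2)
    vp <- vp[keepv, , drop = FALSE]
  }
  allPts <- rbind(pts, vp)
  allW <- c(w, rep(0.15 * sqrt(2 * pi) * noise@psfSigma, nrow(vp)))
  disp <- allPts + recoilField(allPts, spec, kinetics, t_rec)
  disp <- applyPose(disp, pose, fc)
  img <- noise@membraneIntensity *
    splatPoints(disp, allW, dims, pixelSize, noise@psfSigma)

  img <- img + noise@background
  if (noise@photonGain > 0) {
    img[] <- rpois(length(img), pmax(img, 0) / noise@photonGain) *
      noise@photonGain
  }
  if (noise@readNoiseSd > 0)
    img[] <- img + rnorm(length(img), 0, noise@readNoiseSd)
  img
}

#' Simulate one ablation recording
#'
#' Landmarks on opposite sides of the cut separate over the post-ablation
#' frames following the damped recoil law; orthogonal and parallel control
#' landmarks move only with the rigid artifact. Ground-truth tracks are
#' always produced; frames can optionally be rasterized into a membrane
#' image stack.
#'
#' @param mesh a [TissueMesh-class].
#' @param spec an [AblationSpec-class]; the cut (with a 2 \eqn{\mu m}
#'   safety margin) must lie inside the mesh field.
#' @param kinetics a [RecoilKinetics-class].
#' @param artifact an [ArtifactModel-class].
#' @param noise a [NoiseModel-class] (used only when rendering).
#' @param seed integer; output is deterministic given the seed.
#' @param pixelSize \eqn{\mu m}/px for rendering (default 0.21).
#' @param renderFrames integer vector of frames to rasterize (default none:
#'   tracks-only). Use `2:3` for the measurement pair or
#'   `seq_len(spec@nFrames)` for the full stack.
#' @param recordingId,embryoId identifiers.
#' @param region,orientation grouping labels; `orientation` is the axis of
#'   the measured recoil (orthogonal to the cut) and defaults to that
#'   convention.
#' @param flags list of QC annotations.
#' @return a [SyntheticRecording-class].
#' @examples
#' mesh <- buildCellMesh(64, 6, seed = 2)
#' rec <- simulateAblationRecording(mesh, ablationSpec(c(32, 32), "RC"),
#'                                  recoilKinetics(v0 = 3), seed = 2)
#' truthV0(rec)
#' @export
simulateAblationRecording <- function(mesh, spec, kinetics,
                                      artifact = artifactModel(),
                                      noise = noiseModel(), seed = 1L,
                                      pixelSize = 0.21,
                                      renderFrames = integer(0),
                                      recordingId = "rec1",
                                      embryoId = "embryo1",
                                      region = "lateral",
                                      orientation = NULL,
                                      flags = list()) {
  ends <- rbind(spec@center + spec@axis * spec@length / 2,
                spec@center - spec@axis * spec@length / 2)
  if (any(ends < 2) || any(ends[, 1L] > mesh@fieldSize[1L] - 2) ||
      any(ends[, 2L] > mesh@fieldSize[2L] - 2))
    stopGeometry("ablation line exits the field (2 um margin required)")
  if (is.null(orientation))
    orientation <- if (abs(spec@axis[1L]) >= abs(spec@axis[2L])) "RC" else "ML"

  withr::with_seed(as.integer(seed), {
    roles <- assignLandmarkRoles(mesh, spec, kinetics)
    p0 <- mesh@vertices[roles$vertex, , drop = FALSE]
    fc <- mesh@fieldSize / 2
    frames <- seq_len(spec@nFrames)
    tracks <- do.call(rbind, lapply(frames, function(f) {
      p <- p0 + recoilField(p0, spec, kinetics, recoilTime(spec, f))
      p <- applyPose(p, artifactPose(artifact, frameTime(spec, f)), fc)
      data.frame(landmark_id = sprintf("L%03d", seq_len(nrow(p0))),
                 role = roles$role, side = roles$side, frame = f,
                 x_um = p[, 1L], y_um = p[, 2L], stringsAsFactors = FALSE)
    }))

    pose2 <- artifactPose(artifact, frameTime(spec, spec@ablationBetween[1L]))
    mCenter <- as.numeric(applyPose(matrix(spec@center, 1L), pose2, fc))
    mAxis <- as.numeric(rotationMatrix2(pose2$rotation) %*% spec@axis)

    stack <- NULL
    if (length(renderFrames)) {
      samples <- sampleMeshPoints(mesh)
      dims <- c(round(mesh@fieldSize[2L] / pixelSize),
                round(mesh@fieldSize[1L] / pixelSize))
      stack <- array(NA_real_, c(dims, spec@nFrames))
      for (f in renderFrames)
        stack[, , f] <- renderFrame(mesh, spec, kinetics, artifact, noise,
                                    f, pixelSize, mesh@fieldSize, samples,
                                    roles$vertex)
    }

    new("SyntheticRecording", recordingId = recordingId, embryoId = embryoId,
        stack = stack, pixelSize = pixelSize, spec = spec,
        measuredCenter = mCenter, measuredAxis = unitVector(mAxis),
        truthTracks = tracks, truthV0 = kinetics@v0, region = region,
        orientation = orientation,
        flags = utils::modifyList(list(bubbles = FALSE,
                                       outside_region = FALSE,
                                       heartbeat_ok = TRUE), flags))
  })
}

#' Simulate an ablation cohort
#'
#' Draws embryos (sex, somite stage, between-embryo random effect) and per
#' embryo up to five ablations with region/orientation assignments, then
#' simulates each recording. Per-ablation ground truth is the group mean
#' plus the embryo effect plus within-embryo noise, truncated at zero.
#'
#' @param config a [SimulationConfig-class].
#' @return list with elements `recordings` (list of
#'   [SyntheticRecording-class]) and `metadata` (data.frame: embryo_id, sex,
#'   somites, heartbeat_ok).
#' @examples
#' sim <- simulateCohort(simulationConfig(nEmbryos = 2, seed = 5))
#' length(sim$recordings); sim$metadata
#' @export
simulateCohort <- function(config) {
  validObject(config)
  if (config@nEmbryos == 0L) stopInvalidConfig("cohort is empty")
  gm <- config@groupMeans
  withr::with_seed(config@seed, {
    embryoIds <- sprintf("E%03d", seq_len(config@nEmbryos))
    sexTrue <- ifelse(runif(config@nEmbryos) < config@femaleProb, "F", "M")
    somites <- sample(seq(config@somiteRange[1L], config@somiteRange[2L]),
                      config@nEmbryos, replace = TRUE)
    sexRec <- ifelse(runif(config@nEmbryos) < config@unknownSexProb,
                     "unknown", sexTrue)
    somRec <- ifelse(runif(config@nEmbryos) < config@unknownStageProb,
                     NA_integer_, somites)
    metadata <- data.frame(embryo_id = embryoIds, sex = sexRec,
                           somites = somRec, heartbeat_ok = TRUE,
                           stringsAsFactors = FALSE)
    embryoEff <- rnorm(config@nEmbryos, 0, config@embryoSd)

    recordings <- list()
    k <- 0L
    for (e in seq_len(config@nEmbryos)) {
      for (a in seq_len(config@ablationsPerEmbryo)) {
        k <- k + 1L
        region <- sample(names(config@regionWeights), 1L,
                         prob = config@regionWeights)
        orientation <- sample(names(config@orientationWeights), 1L,
                              prob = config@orientationWeights)
        row <- gm[gm$region == region & gm$orientation == orientation &
                    gm$sex == sexTrue[e], , drop = FALSE]
        if (!nrow(row))
          stopInvalidConfig(sprintf("no group mean for %s/%s/%s",
                                    region, orientation, sexTrue[e]))
        v0 <- max(0, row$v0[1L] + embryoEff[e] +
                    rnorm(1L, 0, config@withinSd))
        # cut axis is orthogonal to the measured-recoil orientation
        cutAxis <- if (orientation == "ML") "RC" else "ML"
        phase <- runif(1L, 0, 2 * pi)
        dirAng <- runif(1L, 0, 2 * pi)
        art <- artifactModel(
          heartbeatAmplitude = config@artifact@heartbeatAmplitude,
          heartbeatPeriod = config@artifact@heartbeatPeriod,
          heartbeatPhase = phase,
          heartbeatDirection = c(cos(dirAng), sin(dirAng)),
          drift = config@artifact@drift,
          rotationAmplitude = config@artifact@rotationAmplitude)
        kin <- config@kinetics
        kin@v0 <- v0
        recSeed <- sample.int(.Machine$integer.max - 1L, 1L)
        meshSeed <- sample.int(.Machine$integer.max - 1L, 1L)
        mesh <- buildCellMesh(config@fieldSize, seed = meshSeed)
        spec <- ablationSpec(center = config@fieldSize / 2 * c(1, 1),
                             axis = cutAxis)
        flags <- list(
          bubbles = runif(1L) < config@bubblesProb,
          outside_region = runif(1L) < config@outsideRegionProb)
        recordings[[k]] <- simulateAblationRecording(
          mesh, spec, kin, art, config@noise, seed = recSeed,
          pixelSize = config@pixelSize,
          renderFrames = if (config@renderImages) 2:3 else integer(0),
          recordingId = sprintf("R%04d", k), embryoId = embryoIds[e],
          region = if (flags$outside_region) "other" else region,
          orientation = orientation, flags = flags)
      }
    }
    list(recordings = recordings, metadata = metadata)
  })
}
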