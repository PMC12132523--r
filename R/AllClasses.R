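#' @title Core classes for ablation-recoil analysis
#' @name RecoilQuant-classes
#' @description S4 containers used across the simulation and measurement
#'   pipeline. All geometry is in micrometres (\eqn{\mu m}) with image
#'   conventions: origin at the top-left pixel corner, x rightwards
#'   (medial-lateral, ML), y downwards (rostral-caudal, RC).
NULL

setClassUnion("arrayOrNULL", c("array", "matrix", "NULL"))

#' Ablation line geometry and acquisition timing
#'
#' Describes one laser-ablation event: a straight cut of given length and
#' orientation, imaged as a fixed-interval time lapse with the ablation
#' between two stated frames.
#'
#' @slot center numeric(2), cut midpoint in \eqn{\mu m}.
#' @slot axis numeric(2), unit vector along the cut line.
#' @slot length cut length in \eqn{\mu m} (default 36, six mean cell
#'   diameters).
#' @slot frameInterval seconds between frames (default 0.416).
#' @slot nFrames frames in the recording (default 20).
#' @slot ablationBetween 1-based frame indices bracketing the ablation
#'   (default c(2, 3): frame 2 is pre-, frame 3 post-ablation).
#' @slot gapWidth width of the vaporized band in \eqn{\mu m} (default 2).
#' @exportClass AblationSpec
setClass("AblationSpec",
  representation(center = "numeric", axis = "numeric", length = "numeric",
                 frameInterval = "numeric", nFrames = "integer",
                 ablationBetween = "integer", gapWidth = "numeric"))

setValidity("AblationSpec", function(object) {
  msg <- character()
  if (length(object@center) != 2L) msg <- c(msg, "center must be length 2")
  if (length(object@axis) != 2L || abs(sqrt(sum(object@axis^2)) - 1) > 1e-8)
    msg <- c(msg, "axis must be a 2D unit vector")
  if (object@length <= 0) msg <- c(msg, "length must be > 0")
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
  if (object@nFrames < 4L) msg <- c(msg, "nFrames must be >= 4")
  if (length(object@ablationBetween) != 2L ||
      object@ablationBetween[2L] != object@ablationBetween[1L] + 1L ||
      object@ablationBetween[1L] < 1L ||
      object@ablationBetween[2L] > object@nFrames)
    msg <- c(msg, "ablationBetween must be consecutive in-range frames")
  if (object@gapWidth < 0) msg <- c(msg, "gapWidth must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct an [AblationSpec-class]
#'
#' @param center cut midpoint, \eqn{\mu m}.
#' @param axis direction of the cut line; normalised internally. `"ML"` and
#'   `"RC"` are accepted as shorthands for the image x and y axes.
#' @param length,frameInterval,nFrames,ablationBetween,gapWidth see slots.
#' @return an `AblationSpec`.
#' @examples
#' ablationSpec(center = c(32, 32), axis = "ML")
#' @export
ablationSpec <- function(center, axis = c(1, 0), length = 36,
                         frameInterval = 0.416, nFrames = 20L,
                         ablationBetween = c(2L, 3L), gapWidth = 2) {
  if (is.character(axis))
    axis <- switch(match.arg(axis, c("ML", "RC")), ML = c(1, 0), RC = c(0, 1))
  obj <- new("AblationSpec", center = as.numeric(center),
             axis = unitVector(as.numeric(axis)), length = length,
             frameInterval = frameInterval, nFrames = as.integer(nFrames),
             ablationBetween = as.integer(ablationBetween),
             gapWidth = gapWidth)
  obj
}

#' Ground-truth recoil kinetics
#'
#' The two cut margins retract with saturating exponential displacement
#' \eqn{d(t) = A (1 - e^{-t/\tau})} per margin (overdamped, Kelvin-Voigt
#' like). The amplitude `A` is solved so that the margin-to-margin
#' separation increase over the first post-ablation frame interval divided
#' by that interval equals `v0` exactly: ground truth is defined on the very
#' quantity the estimator measures.
#'
#' Spatially the displacement is uniform (a plateau) within
#' `plateauHalfWidth` of the cut line and decays exponentially beyond
#' (`perpDecayLength`); along the cut it is uniform over the cut length and
#' attenuates at the cut ends (`decayAlongCut` = fractional attenuation, 1 =
#' complete), continuing an exponential decay (`endDecayLength`) beyond the
#' ends. Uniformity along the cut is what makes the orthogonal and parallel
#' control landmarks recoil-free by construction.
#'
#' @slot v0 \eqn{\mu m/s}, ground-truth first-frame recoil velocity (rate of
#'   increase of the margin-to-margin separation).
#' @slot tau relaxation time, seconds.
#' @slot plateauHalfWidth,perpDecayLength,decayAlongCut,endDecayLength see
#'   description; \eqn{\mu m} except `decayAlongCut` (dimensionless in
#'   `[0, 1]`).
#' @exportClass RecoilKinetics
setClass("RecoilKinetics",
  representation(v0 = "numeric", tau = "numeric",
                 plateauHalfWidth = "numeric", perpDecayLength = "numeric",
                 decayAlongCut = "numeric", endDecayLength = "numeric"))

setValidity("RecoilKinetics", function(object) {
  msg <- character()
  if (object@v0 < 0) msg <- c(msg, "v0 must be >= 0")
  if (object@tau <= 0) msg <- c(msg, "tau must be > 0")
  if (object@plateauHalfWidth <= 0 || object@perpDecayLength <= 0 ||
      object@endDecayLength <= 0)
    msg <- c(msg, "spatial decay scales must be > 0")
  if (object@decayAlongCut < 0 || object@decayAlongCut > 1)
    msg <- c(msg, "decayAlongCut must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname RecoilKinetics-class
#' @param v0,tau,plateauHalfWidth,perpDecayLength,decayAlongCut,endDecayLength
#'   see slots.
#' @return a `RecoilKinetics`.
#' @export
recoilKinetics <- function(v0, tau = 1.5, plateauHalfWidth = 6,
                           perpDecayLength = 8, decayAlongCut = 1,
                           endDecayLength = 2) {
  new("RecoilKinetics", v0 = v0, tau = tau,
      plateauHalfWidth = plateauHalfWidth, perpDecayLength = perpDecayLength,
      decayAlongCut = decayAlongCut, endDecayLength = endDecayLength)
}

#' Rigid whole-frame motion artifact
#'
#' Models artifactual background movement, dominated by the embryonic
#' heartbeat, as whole-frame rigid motion: a sinusoidal translation along a
#' fixed direction plus a small sinusoidal rotation, on top of a linear
#' drift.
#'
#' @slot heartbeatAmplitude peak translation, \eqn{\mu m}.
#' @slot heartbeatPeriod seconds.
#' @slot heartbeatPhase radians.
#' @slot heartbeatDirection unit 2-vector of the translation.
#' @slot drift \eqn{\mu m/s} 2-vector.
#' @slot rotationAmplitude peak rotation, degrees (about the field centre).
#' @exportClass ArtifactModel
setClass("ArtifactModel",
  representation(heartbeatAmplitude = "numeric", heartbeatPeriod = "numeric",
                 heartbeatPhase = "numeric", heartbeatDirection = "numeric",
                 drift = "numeric", rotationAmplitude = "numeric"))

setValidity("ArtifactModel", function(object) {
  msg <- character()
  if (object@heartbeatAmplitude < 0) msg <- c(msg, "amplitude must be >= 0")
  if (object@heartbeatPeriod <= 0) msg <- c(msg, "period must be > 0")
  if (length(object@drift) != 2L) msg <- c(msg, "drift must be length 2")
  if (length(msg)) msg else TRUE
})

#' @rdname ArtifactModel-class
#' @param heartbeatAmplitude,heartbeatPeriod,heartbeatPhase,heartbeatDirection,drift,rotationAmplitude
#'   see slots.
#' @return an `ArtifactModel`.
#' @export
artifactModel <- function(heartbeatAmplitude = 0, heartbeatPeriod = 0.9,
                          heartbeatPhase = 0, heartbeatDirection = c(0.8, 0.6),
                          drift = c(0, 0), rotationAmplitude = 0) {
  new("ArtifactModel", heartbeatAmplitude = heartbeatAmplitude,
      heartbeatPeriod = heartbeatPeriod, heartbeatPhase = heartbeatPhase,
      heartbeatDirection = unitVector(heartbeatDirection),
      drift = as.numeric(drift), rotationAmplitude = rotationAmplitude)
}

#' Imaging noise model for the rasterizer
#'
#' @slot photonGain a.u. per detected photon (Poisson shot noise applied as
#'   `rpois(intensity / gain) * gain`; 0 disables shot noise).
#' @slot readNoiseSd additive Gaussian read noise, a.u.
#' @slot background constant background, a.u.
#' @slot membraneIntensity peak membrane brightness, a.u.
#' @slot psfSigma Gaussian point-spread sigma, \eqn{\mu m}.
#' @exportClass NoiseModel
setClass("NoiseModel",
  representation(photonGain = "numeric", readNoiseSd = "numeric",
                 background = "numeric", membraneIntensity = "numeric",
                 psfSigma = "numeric"))

setValidity("NoiseModel", function(object) {
  vals <- c(object@photonGain, object@readNoiseSd, object@background,
            object@membraneIntensity, object@psfSigma)
  if (any(vals < 0)) "all noise parameters must be non-negative" else TRUE
})

#' @rdname NoiseModel-class
#' @param photonGain,readNoiseSd,background,membraneIntensity,psfSigma see
#'   slots.
#' @return a `NoiseModel`.
#' @export
noiseModel <- function(photonGain = 1, readNoiseSd = 2, background = 10,
                       membraneIntensity = 100, psfSigma = 0.3) {
  new("NoiseModel", photonGain = photonGain, readNoiseSd = readNoiseSd,
      background = background, membraneIntensity = membraneIntensity,
      psfSigma = psfSigma)
}

#' Polygonal cell mesh
#'
#' A tessellation of the imaged field into simple polygonal cells whose
#' bright edges emulate a membrane stain.
#'
#' @slot vertices n x 2 matrix of vertex positions, \eqn{\mu m}.
#' @slot edges m x 2 integer matrix of vertex indices.
#' @slot cells list of integer vectors, each a closed polygon (vertex
#'   indices in order).
#' @slot meanCellDiameter configured mean equivalent diameter, \eqn{\mu m}.
#' @slot fieldSize numeric(2), field extent, \eqn{\mu m}.
#' @exportClass TissueMesh
setClass("TissueMesh",
  representation(vertices = "matrix", edges = "matrix", cells = "list",
                 meanCellDiameter = "numeric", fieldSize = "numeric"))

setValidity("TissueMesh", function(object) {
  msg <- character()
  if (ncol(object@vertices) != 2L) msg <- c(msg, "vertices must be n x 2")
  if (ncol(object@edges) != 2L) msg <- c(msg, "edges must be m x 2")
  if (max(object@edges) > nrow(object@vertices))
    msg <- c(msg, "edge index out of range")
  if (length(msg)) msg else TRUE
})

#' 2D rigid-body transform
#'
#' Maps a point p to `R(p - center) + center + translation` where R is the
#' rotation matrix. Composition with its inverse is the identity to within
#' 1e-6 px on any in-frame point.
#'
#' @slot rotation degrees.
#' @slot translation numeric(2), pixels.
#' @slot center numeric(2), pixel position of the rotation centre.
#' @exportClass RigidTransform
setClass("RigidTransform",
  representation(rotation = "numeric", translation = "numeric",
                 center = "numeric"))

#' @rdname RigidTransform-class
#' @param rotation,translation,center see slots.
#' @return a `RigidTransform`.
#' @export
rigidTransform <- function(rotation = 0, translation = c(0, 0),
                           center = c(0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation), center = as.numeric(center))
}

#' One simulated ablation recording
#'
#' Holds the (optional) rasterized image stack, the ground-truth landmark
#' tracks, the ablation geometry both in tissue coordinates (`spec`) and as
#' it appears in the pre-ablation frame (`measuredCenter`/`measuredAxis`,
#' i.e. after the frame-2 artifact motion), and the ground-truth recoil
#' velocity.
#'
#' @slot recordingId,embryoId character identifiers.
#' @slot stack H x W x F array of frames (a.u.), or NULL in tracks-only
#'   mode. Frames not rendered are all-NA planes.
#' @slot pixelSize \eqn{\mu m}/pixel.
#' @slot spec an [AblationSpec-class] in tissue coordinates.
#' @slot measuredCenter,measuredAxis ablation geometry in frame-2 (image)
#'   coordinates.
#' @slot truthTracks data.frame: landmark_id, role (recoil/orthogonal_control/
#'   parallel_control), side, frame, x_um, y_um (image coordinates including
#'   artifact, noise-free).
#' @slot truthV0 ground-truth first-frame recoil velocity, \eqn{\mu m/s}.
#' @slot region,orientation grouping labels ("midline"/"lateral";
#'   orientation is the axis of the measured recoil, orthogonal to the cut).
#' @slot flags list of QC annotations (bubbles, outside_region,
#'   heartbeat_ok).
#' @exportClass SyntheticRecording
setClass("SyntheticRecording",
  representation(recordingId = "character", embryoId = "character",
                 stack = "arrayOrNULL", pixelSize = "numeric",
                 spec = "AblationSpec", measuredCenter = "numeric",
                 measuredAxis = "numeric", truthTracks = "data.frame",
                 truthV0 = "numeric", region = "character",
                 orientation = "character", flags = "list"))

setValidity("SyntheticRecording", function(object) {
  msg <- character()
  tt <- object@truthTracks
  need <- c("landmark_id", "role", "side", "frame", "x_um", "y_um")
  if (nrow(tt) && !all(need %in% names(tt)))
    msg <- c(msg, "truthTracks missing required columns")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (length(msg)) msg else TRUE
})

#' One per-ablation recoil measurement
#'
#' @slot recordingId character.
#' @slot irv measured initial recoil velocity, \eqn{\mu m/s}.
#' @slot orthogonalIrv,parallelIrv control IRVs, \eqn{\mu m/s}.
#' @slot preDistances,postDistances 3 x 3 matrices (rows: recoil,
#'   orthogonal, parallel; columns: the three replicate point pairs),
#'   \eqn{\mu m}.
#' @slot deltaT seconds between the pre and post frames.
#' @slot region,orientation grouping labels carried from the recording.
#' @slot provenance list: selected points, registration transform, options.
#' @exportClass RecoilMeasurement
setClass("RecoilMeasurement",
  representation(recordingId = "character", irv = "numeric",
                 orthogonalIrv = "numeric", parallelIrv = "numeric",
                 preDistances = "matrix", postDistances = "matrix",
                 deltaT = "numeric", region = "character",
                 orientation = "character", provenance = "list"))

setValidity("RecoilMeasurement", function(object) {
  msg <- character()
  if (!all(dim(object@preDistances) == c(3L, 3L)) ||
      !all(dim(object@postDistances) == c(3L, 3L)))
    msg <- c(msg, "distance matrices must be 3 x 3 (roles x replicates)")
  if (object@deltaT <= 0) msg <- c(msg, "deltaT must be > 0")
  # arithmetic identity: irv is exactly mean(post - pre)/deltaT for recoil
  expect <- mean(object@postDistances[1L, ] - object@preDistances[1L, ]) /
    object@deltaT
  if (!isTRUE(all.equal(expect, object@irv, tolerance = 1e-12)))
    msg <- c(msg, "irv must equal mean(post - pre)/deltaT exactly")
  if (length(msg)) msg else TRUE
})

#' Cohort simulation configuration
#'
#' Defines the ground-truth group structure and nuisance processes for a
#' simulated ablation cohort.
#'
#' @slot groupMeans data.frame with columns region, orientation, sex, v0:
#'   ground-truth first-frame recoil velocity per group, \eqn{\mu m/s}.
#' @slot embryoSd between-embryo random-effect SD, \eqn{\mu m/s}.
#' @slot withinSd between-ablation SD within embryo, \eqn{\mu m/s}.
#' @slot nEmbryos embryos in the cohort.
#' @slot ablationsPerEmbryo integer in 1..5.
#' @slot femaleProb probability an embryo is female (default 0.7).
#' @slot somiteRange integer(2), uniform somite-count range.
#' @slot regionWeights,orientationWeights named sampling weights for the
#'   per-ablation region/orientation assignment.
#' @slot kinetics,artifact,noise component models (kinetics@v0 is a
#'   placeholder; the per-ablation truth v0 overrides it).
#' @slot fieldSize field extent, \eqn{\mu m} (square).
#' @slot pixelSize \eqn{\mu m}/px for rasterization.
#' @slot renderImages render frames 2 and 3 (FALSE = tracks-only).
#' @slot unknownSexProb,unknownStageProb,bubblesProb,outsideRegionProb
#'   probabilities of deliberate QC defects in the generated metadata/flags.
#' @slot seed integer RNG seed.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(groupMeans = "data.frame", embryoSd = "numeric",
                 withinSd = "numeric", nEmbryos = "integer",
                 ablationsPerEmbryo = "integer", femaleProb = "numeric",
                 somiteRange = "integer", regionWeights = "numeric",
                 orientationWeights = "numeric", kinetics = "RecoilKinetics",
                 artifact = "ArtifactModel", noise = "NoiseModel",
                 fieldSize = "numeric", pixelSize = "numeric",
                 renderImages = "logical", unknownSexProb = "numeric",
                 unknownStageProb = "numeric", bubblesProb = "numeric",
                 outsideRegionProb = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  gm <- object@groupMeans
  if (!all(c("region", "orientation", "sex", "v0") %in% names(gm)))
    msg <- c(msg, "groupMeans must have region, orientation, sex, v0")
  else if (any(gm$v0 < 0)) msg <- c(msg, "ground-truth v0 must be >= 0")
  if (object@nEmbryos < 0) msg <- c(msg, "nEmbryos must be >= 0")
  if (object@ablationsPerEmbryo < 1L || object@ablationsPerEmbryo > 5L)
    msg <- c(msg, "ablationsPerEmbryo must be in 1..5")
  if (object@embryoSd < 0 || object@withinSd < 0)
    msg <- c(msg, "variance components must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Printed group means used as simulation defaults
#'
#' Ground-truth first-frame recoil velocities per (region, orientation, sex)
#' taken from the reported group means: lateral folds are anisotropic
#' (female ML 3.77, RC 2.73; male ML 3.45, RC 2.19 \eqn{\mu m/s}) while the
#' midline is isotropic at the per-sex midline mean (female 2.30, male
#' 2.57). Orientation labels refer to the axis of the measured recoil.
#'
#' @return data.frame with columns region, orientation, sex, v0.
#' @export
defaultGroupMeans <- function() {
  data.frame(
    region = rep(c("lateral", "midline"), each = 4L),
    orientation = rep(c("ML", "ML", "RC", "RC"), 2L),
    sex = rep(c("F", "M"), 4L),
    v0 = c(3.77, 3.45, 2.73, 2.19, 2.30, 2.57, 2.30, 2.57),
    stringsAsFactors = FALSE
  )
}

#' Construct a [SimulationConfig-class]
#'
#' @param groupMeans see slots; default [defaultGroupMeans()].
#' @param embryoSd,withinSd,nEmbryos,ablationsPerEmbryo,femaleProb,somiteRange
#'   see slots.
#' @param regionWeights,orientationWeights named weights.
#' @param kinetics,artifact,noise component models.
#' @param fieldSize,pixelSize,renderImages rasterization controls.
#' @param unknownSexProb,unknownStageProb,bubblesProb,outsideRegionProb QC
#'   defect rates.
#' @param seed integer.
#' @return a `SimulationConfig`.
#' @export
simulationConfig <- function(groupMeans = defaultGroupMeans(),
                             embryoSd = 0.4, withinSd = 0.6,
                             nEmbryos = 20L, ablationsPerEmbryo = 3L,
                             femaleProb = 0.7, somiteRange = c(4L, 10L),
                             regionWeights = c(lateral = 0.5, midline = 0.5),
                             orientationWeights = c(ML = 0.5, RC = 0.5),
                             kinetics = recoilKinetics(v0 = 0),
                             artifact = artifactModel(heartbeatAmplitude = 1,
                                                      rotationAmplitude = 0.2),
                             noise = noiseModel(),
                             fieldSize = 64, pixelSize = 0.21,
                             renderImages = FALSE,
                             unknownSexProb = 0, unknownStageProb = 0,
                             bubblesProb = 0, outsideRegionProb = 0,
                             seed = 1L) {
  new("SimulationConfig", groupMeans = groupMeans, embryoSd = embryoSd,
      withinSd = withinSd, nEmbryos = as.integer(nEmbryos),
      ablationsPerEmbryo = as.integer(ablationsPerEmbryo),
      femaleProb = femaleProb, somiteRange = as.integer(somiteRange),
      regionWeights = regionWeights, orientationWeights = orientationWeights,
      kinetics = kinetics, artifact = artifact, noise = noise,
      fieldSize = fieldSize, pixelSize = pixelSize,
      renderImages = renderImages, unknownSexProb = unknownSexProb,
      unknownStageProb = unknownStageProb, bubblesProb = bubblesProb,
      outsideRegionProb = outsideRegionProb, seed = as.integer(seed))
}
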