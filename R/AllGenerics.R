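#' @name accessors
#' @title Accessors for RecoilQuant objects
#' @description Slot accessors; user code should use these rather than `@`.
#' @param object a RecoilQuant S4 object.
#' @return the corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("recordingId", function(object) standardGeneric("recordingId"))
#' @rdname accessors
#' @export
setGeneric("truthV0", function(object) standardGeneric("truthV0"))
#' @rdname accessors
#' @export
setGeneric("truthTracks", function(object) standardGeneric("truthTracks"))
#' @rdname accessors
#' @export
setGeneric("imageStack", function(object) standardGeneric("imageStack"))
#' @rdname accessors
#' @export
setGeneric("irv", function(object) standardGeneric("irv"))
#' @rdname accessors
#' @export
setGeneric("controlIrvs", function(object) standardGeneric("controlIrvs"))

#' @rdname accessors
setMethod("recordingId", "SyntheticRecording", function(object) object@recordingId)
#' @rdname accessors
setMethod("recordingId", "RecoilMeasurement", function(object) object@recordingId)
#' @rdname accessors
setMethod("truthV0", "SyntheticRecording", function(object) object@truthV0)
#' @rdname accessors
setMethod("truthTracks", "SyntheticRecording", function(object) object@truthTracks)
#' @rdname accessors
setMethod("imageStack", "SyntheticRecording", function(object) object@stack)
#' @rdname accessors
setMethod("irv", "RecoilMeasurement", function(object) object@irv)
#' @rdname accessors
setMethod("controlIrvs", "RecoilMeasurement", function(object)
  c(orthogonal = object@orthogonalIrv, parallel = object@parallelIrv))

setMethod("show", "AblationSpec", function(object) {
  cat(sprintf(
    "AblationSpec: %.0f um cut at (%.1f, %.1f), axis (%.2f, %.2f)\n",
    object@length, object@center[1L], object@center[2L],
    object@axis[1L], object@axis[2L]))
  cat(sprintf("  %d frames every %.3f s; ablation between frames %d and %d\n",
              object@nFrames, object@frameInterval,
              object@ablationBetween[1L], object@ablationBetween[2L]))
})

setMethod("show", "SyntheticRecording", function(object) {
  cat(sprintf("SyntheticRecording %s (embryo %s): %s / %s recoil\n",
              object@recordingId, object@embryoId, object@region,
              object@orientation))
  cat(sprintf("  truth v0 = %.3f um/s; %s; %d landmarks x %d frames\n",
              object@truthV0,
              if (is.null(object@stack)) "tracks-only"
              else paste(dim(object@stack)[1:2], collapse = "x"),
              length(unique(object@truthTracks$landmark_id)),
              object@spec@nFrames))
})

setMethod("show", "RecoilMeasurement", function(object) {
  cat(sprintf(
    "RecoilMeasurement %s: IRV = %.3f um/s (orth %.3f, par %.3f)\n",
    object@recordingId, object@irv, object@orthogonalIrv,
    object@parallelIrv))
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf(
    "RigidTransform: %.4f deg about (%.1f, %.1f), shift (%.3f, %.3f) px\n",
    object@rotation, object@center[1L], object@center[2L],
    object@translation[1L], object@translation[2L]))
})

setMethod("show", "TissueMesh", function(object) {
  cat(sprintf(
    "TissueMesh: %d vertices, %d edges, %d cells (~%.1f um) in %.0fx%.0f um\n",
    nrow(object@vertices), nrow(object@edges), length(object@cells),
    object@meanCellDiameter, object@fieldSize[1L], object@fieldSize[2L]))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d embryos x %d ablations, embryoSd %.2f, withinSd %.2f, seed %d\n",
    object@nEmbryos, object@ablationsPerEmbryo, object@embryoSd,
    object@withinSd, object@seed))
  cat(sprintf("  images: %s (%.0f um field, %.2f um/px)\n",
              if (object@renderImages) "rendered" else "tracks-only",
              object@fieldSize, object@pixelSize))
})
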