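# Shared fixtures, built in code at test time.

# small mesh reused across tests (deterministic)
testMesh <- function(field = 64, seed = 101L) {
  buildCellMesh(field, 6, seed = seed)
}

# one tracks-only recording with given kinetics/artifact
testRecording <- function(v0 = 3, artifact = artifactModel(), seed = 7L,
                          axis = "RC", field = 64, render = FALSE,
                          noise = noiseModel(), tau = 1.5) {
  mesh <- testMesh(field, seed = seed + 1000L)
  simulateAblationRecording(
    mesh, ablationSpec(center = c(field / 2, field / 2), axis = axis),
    recoilKinetics(v0 = v0, tau = tau), artifact = artifact, noise = noise,
    seed = seed, renderFrames = if (render) 2:3 else integer(0))
}

# clean membrane frame (no cut, no artifact/noise) for registration tests
testMembraneFrame <- function(field = 48, seed = 55L) {
  rec <- simulateAblationRecording(
    testMesh(field, seed = seed), ablationSpec(c(field / 2, field / 2), "ML"),
    recoilKinetics(v0 = 0),
    noise = noiseModel(photonGain = 0, readNoiseSd = 0),
    seed = seed, renderFrames = 1L)
  rec@stack[, , 1L]
}

# margin-to-margin separation of the innermost recoil pair at a frame,
# computed directly from truth tracks (independent of the measurement code)
marginSeparation <- function(rec, frame) {
  tt <- rec@truthTracks
  tt <- tt[tt$frame == frame & tt$role == "recoil", ]
  n <- normalVector(c(rec@spec@axis))
  qs <- (cbind(tt$x_um, tt$y_um) -
           matrix(rec@spec@center, nrow(tt), 2, byrow = TRUE)) %*% n
  a <- tt[qs >= 0, ][1L, ]
  b <- tt[qs < 0, ][1L, ]
  abs(sum((c(a$x_um, a$y_um) - c(b$x_um, b$y_um)) * n))
}

normalVector <- RecoilQuant:::normalVector
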