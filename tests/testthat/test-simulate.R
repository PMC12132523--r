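# Generator contracts: recoil law, controls, artifact, cohort structure.

test_that("zero tension gives constant inter-landmark distances", {
  rec <- testRecording(v0 = 0)
  tt <- truthTracks(rec)
  first <- tt[tt$frame == 1, ]
  dist12 <- function(df) {
    p <- cbind(df$x_um, df$y_um)
    sqrt(sum((p[1, ] - p[nrow(p), ])^2))
  }
  d0 <- dist12(first)
  for (f in c(2, 3, 10, 20))
    expect_equal(dist12(tt[tt$frame == f, ]), d0, tolerance = 1e-12)
})

test_that("margin separation over the first post-ablation interval is v0 * dt", {
  rec <- testRecording(v0 = 3)
  gain <- marginSeparation(rec, 3) - marginSeparation(rec, 2)
  expect_equal(gain, 3 * 0.416, tolerance = 1e-12)
})

test_that("doubling v0 doubles the frame-2 to frame-3 separation increase", {
  r1 <- testRecording(v0 = 1.7, seed = 9)
  r2 <- testRecording(v0 = 3.4, seed = 9)
  g1 <- marginSeparation(r1, 3) - marginSeparation(r1, 2)
  g2 <- marginSeparation(r2, 3) - marginSeparation(r2, 2)
  expect_equal(g2 / g1, 2, tolerance = 1e-10)
})

test_that("per-margin displacement increments are non-increasing (dampening)", {
  rec <- testRecording(v0 = 4, tau = 1.2)
  seps <- vapply(2:20, function(f) marginSeparation(rec, f), numeric(1))
  incr <- diff(seps)
  expect_true(all(diff(incr) <= 1e-12))
  expect_true(all(incr >= -1e-12))
})

test_that("no recoil before the ablation; controls carry only artifact", {
  art <- artifactModel(heartbeatAmplitude = 1.5, rotationAmplitude = 0.3,
                       heartbeatPhase = 0.7)
  rec <- testRecording(v0 = 3, artifact = art)
  tt <- truthTracks(rec)
  dists <- function(role, frame, side = NULL) {
    sub <- tt[tt$role == role & tt$frame == frame, ]
    if (!is.null(side)) sub <- sub[sub$side == side, ]
    as.numeric(dist(as.matrix(sub[, c("x_um", "y_um")])))
  }
  # frames 1 and 2 differ only by the rigid artifact: inter-landmark
  # distances are preserved for every role
  for (role in c("recoil", "orthogonal_control", "parallel_control"))
    expect_equal(dists(role, 1), dists(role, 2), tolerance = 1e-9)
  # across the ablation, same-side orthogonal-control separations and all
  # parallel-control separations are unchanged (controls carry no recoil)
  for (side in c("A", "B"))
    expect_equal(dists("orthogonal_control", 2, side),
                 dists("orthogonal_control", 3, side), tolerance = 1e-9)
  expect_equal(dists("parallel_control", 2), dists("parallel_control", 3),
               tolerance = 1e-9)
  # recoil landmarks on opposite sides do separate
  expect_gt(max(abs(dists("recoil", 3) - dists("recoil", 2))), 1)
})

test_that("zero-amplitude artifact leaves frames differing only by recoil", {
  rec <- testRecording(v0 = 2, artifact = artifactModel())
  tt <- truthTracks(rec)
  par <- tt[tt$role == "parallel_control", ]
  p1 <- par[par$frame == 1, c("x_um", "y_um")]
  p20 <- par[par$frame == 20, c("x_um", "y_um")]
  expect_equal(as.matrix(p1), as.matrix(p20), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("recordings are deterministic given (config, seed)", {
  r1 <- testRecording(v0 = 2.5, seed = 42, render = TRUE,
                      artifact = artifactModel(heartbeatAmplitude = 1))
  r2 <- testRecording(v0 = 2.5, seed = 42, render = TRUE,
                      artifact = artifactModel(heartbeatAmplitude = 1))
  expect_identical(r1@truthTracks, r2@truthTracks)
  expect_identical(r1@stack, r2@stack)
})

test_that("ablation line exiting the field raises a geometry error", {
  mesh <- testMesh(64)
  expect_error(
    simulateAblationRecording(mesh, ablationSpec(c(5, 32), "ML"),
                              recoilKinetics(v0 = 1)),
    class = "rq_geometry_error")
})

test_that("cohort bookkeeping: sizes, ids, determinism, degenerate variance", {
  cfg <- simulationConfig(nEmbryos = 10, ablationsPerEmbryo = 5, seed = 21)
  sim <- simulateCohort(cfg)
  expect_length(sim$recordings, 50)
  ids <- vapply(sim$recordings, function(r) r@embryoId, character(1))
  expect_true(all(table(ids) <= 5))
  expect_equal(nrow(sim$metadata), 10)
  expect_false(anyDuplicated(sim$metadata$embryo_id) > 0)

  sim2 <- simulateCohort(cfg)
  expect_identical(sim$metadata, sim2$metadata)
  expect_identical(lapply(sim$recordings, truthTracks),
                   lapply(sim2$recordings, truthTracks))

  # zero variance components: every truth v0 equals its group mean
  cfg0 <- simulationConfig(nEmbryos = 4, ablationsPerEmbryo = 2,
                           embryoSd = 0, withinSd = 0, seed = 3)
  sim0 <- simulateCohort(cfg0)
  gm <- cfg0@groupMeans
  for (r in sim0$recordings) {
    sex <- sim0$metadata$sex[sim0$metadata$embryo_id == r@embryoId]
    expected <- gm$v0[gm$region == r@region & gm$orientation == r@orientation &
                        gm$sex == sex]
    expect_equal(truthV0(r), expected)
  }
})

test_that("an empty cohort is rejected", {
  expect_error(simulateCohort(simulationConfig(nEmbryos = 0)),
               class = "rq_invalid_configuration")
})

test_that("orientation label is orthogonal to the cut axis", {
  recRC <- testRecording(axis = "RC")  # cut along image y
  expect_equal(recRC@orientation, "ML")
  recML <- testRecording(axis = "ML")
  expect_equal(recML@orientation, "RC")
})
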