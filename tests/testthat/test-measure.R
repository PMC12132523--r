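# Point-pair selection, perpendicular distances, IRV computation.

test_that("perpendicular distance is the normal component of the separation", {
  expect_equal(perpendicularDistance(c(5, -4), c(5, 6), c(1, 0)), 10)
  expect_equal(perpendicularDistance(c(0, 0), c(7, 0), c(1, 0)), 0)
  expect_equal(perpendicularDistance(c(0, 0), c(3, 4), c(1, 0)), 4)
  expect_error(perpendicularDistance(c(0, 0), c(1, 1), c(0, 0)),
               class = "rq_validation_error")
})

test_that("IRV is the mean triplicate distance change over the frame interval", {
  expect_equal(computeIRV(c(10, 10, 10), c(11.248, 11.248, 11.248), 0.416), 3)
  expect_equal(computeIRV(c(4, 5, 6), c(4, 5, 6), 0.416), 0)
  expect_equal(computeIRV(c(10.0, 10.2, 9.8), c(11.0, 11.4, 10.6), 0.416),
               1 / 0.416, tolerance = 1e-9)  # 2.40385 um/s
  expect_error(computeIRV(c(1, 2), c(1, 2, 3), 0.416),
               class = "rq_validation_error")
  expect_error(computeIRV(c(1, 2, 3), c(1, 2, 3), 0),
               class = "rq_validation_error")
  expect_error(computeIRV(c(1, 2, 3), c(1, 2, 3), -1),
               class = "rq_validation_error")
})

test_that("selected recoil pairs straddle the cut near its centre", {
  rec <- testRecording(v0 = 3)
  m <- measureRecording(rec)
  pairs <- m@provenance$pairs
  rc <- pairs[pairs$role == "recoil", ]
  expect_equal(nrow(rc), 3)
  axis <- rec@measuredAxis
  n <- normalVector(axis)
  for (k in seq_len(3)) {
    q1 <- sum((c(rc$p1x_pre[k], rc$p1y_pre[k]) - rec@measuredCenter) * n)
    q2 <- sum((c(rc$p2x_pre[k], rc$p2y_pre[k]) - rec@measuredCenter) * n)
    expect_lt(q1 * q2, 0)  # opposite sides
    mid <- (c(rc$p1x_pre[k], rc$p1y_pre[k]) +
              c(rc$p2x_pre[k], rc$p2y_pre[k])) / 2
    s_mid <- sum((mid - rec@measuredCenter) * axis)
    expect_lte(abs(s_mid), rec@spec@length / 6 + 1e-9)
  }
  oc <- pairs[pairs$role == "orthogonal_control", ]
  for (k in seq_len(nrow(oc))) {
    q1 <- sum((c(oc$p1x_pre[k], oc$p1y_pre[k]) - rec@measuredCenter) * n)
    q2 <- sum((c(oc$p2x_pre[k], oc$p2y_pre[k]) - rec@measuredCenter) * n)
    expect_gt(q1 * q2, 0)  # same side
  }
})

test_that("a blank field raises an insufficient-landmarks error", {
  blank <- matrix(10, 200, 200)
  expect_error(
    selectPointPairs(blank, blank, center = c(21, 21), axis = c(1, 0),
                     pixelSize = 0.21),
    class = "rq_insufficient_landmarks")
})

test_that("too few recoil landmarks raise an insufficient-landmarks error", {
  rec <- testRecording(v0 = 3)
  tt <- rec@truthTracks
  rc_ids <- unique(tt$landmark_id[tt$role == "recoil"])
  keep <- !(tt$landmark_id %in% rc_ids[-seq_len(3)])  # <= 2 pairable recoil
  rec@truthTracks <- tt[keep, ]
  expect_error(measureRecording(rec, mode = "tracks"),
               class = "rq_insufficient_landmarks")
})

test_that("noise-free artifact-free measurement recovers truth exactly", {
  rec <- testRecording(v0 = 3)
  m <- measureRecording(rec)
  expect_equal(m@irv, 3, tolerance = 0.01)
  expect_equal(m@orthogonalIrv, 0, tolerance = 0.01)
  expect_equal(m@parallelIrv, 0, tolerance = 0.01)
})

test_that("measured IRV equals truth within 1% across the working range", {
  for (v0 in c(0.5, 1, 2, 3.5, 6)) {
    rec <- testRecording(v0 = v0, seed = 11)
    m <- measureRecording(rec)
    expect_equal(m@irv, v0, tolerance = 0.01 * max(v0, 1e-6))
  }
})

test_that("rigid artifact is removed exactly in tracks mode", {
  art <- artifactModel(heartbeatAmplitude = 2, rotationAmplitude = 0.4,
                       heartbeatPhase = 2.1)
  rec <- testRecording(v0 = 2.2, artifact = art)
  m <- measureRecording(rec)
  expect_equal(m@irv, 2.2, tolerance = 1e-6)
  expect_equal(m@orthogonalIrv, 0, tolerance = 1e-6)
  expect_equal(m@parallelIrv, 0, tolerance = 1e-6)
})

test_that("stored IRV reproduces mean(post - pre)/dt exactly", {
  for (v0 in c(0, 1.3, 4)) {
    rec <- testRecording(v0 = v0, seed = 17,
                         artifact = artifactModel(heartbeatAmplitude = 0.5))
    m <- measureRecording(rec)
    expect_identical(m@irv,
                     mean(m@postDistances[1, ] - m@preDistances[1, ]) /
                       m@deltaT)
    expect_equal(m@orthogonalIrv,
                 mean(m@postDistances[2, ] - m@preDistances[2, ]) / m@deltaT)
  }
})

test_that("image-mode tracking is quiet on a zero-recoil, zero-artifact recording", {
  rec <- testRecording(v0 = 0, render = TRUE, seed = 23)
  m <- measureRecording(rec, mode = "image")
  expect_lt(abs(m@irv), 0.25)        # < 0.5 px over dt
  expect_lt(abs(m@orthogonalIrv), 0.25)
  pairs <- m@provenance$pairs
  disp <- sqrt((pairs$p1x_post - pairs$p1x_pre)^2 +
                 (pairs$p1y_post - pairs$p1y_pre)^2)
  expect_lt(max(disp), 0.5 * rec@pixelSize)  # every displacement < 0.5 px
})

test_that("axis bookkeeping preserves simulated ML:RC anisotropy", {
  # simulate lateral tissue with ML recoil twice the RC recoil; the
  # measured anisotropy must match within 10%
  gm <- defaultGroupMeans()
  gm$v0 <- ifelse(gm$orientation == "ML", 4, 2)
  cfg <- simulationConfig(groupMeans = gm, embryoSd = 0, withinSd = 0.2,
                          nEmbryos = 12, ablationsPerEmbryo = 4,
                          regionWeights = c(lateral = 1), seed = 31)
  sim <- simulateCohort(cfg)
  mm <- measureCohort(sim$recordings, blinded = FALSE)
  ratio <- mean(mm$irv[mm$orientation == "ML"]) /
    mean(mm$irv[mm$orientation == "RC"])
  expect_equal(ratio, 2, tolerance = 0.1)
})

test_that("estimator bias across v0 grid is under 5% with controls near 0 (tracks mode)", {
  gm <- defaultGroupMeans()
  for (v0 in c(1, 3, 5)) {
    gm$v0 <- v0
    cfg <- simulationConfig(groupMeans = gm, embryoSd = 0, withinSd = 0,
                            nEmbryos = 5, ablationsPerEmbryo = 2,
                            artifact = artifactModel(heartbeatAmplitude = 1,
                                                     rotationAmplitude = 0.2),
                            seed = 40 + v0)
    sim <- simulateCohort(cfg)
    mm <- measureCohort(sim$recordings, blinded = FALSE)
    expect_equal(mean(mm$irv), v0, tolerance = 0.05 * v0)
    expect_lt(abs(mean(mm$orth_irv)), 0.15)
    expect_lt(abs(mean(mm$par_irv)), 0.15)
  }
})

test_that("blinded measurement reproduces unblinded values with labels intact", {
  cfg <- simulationConfig(nEmbryos = 3, ablationsPerEmbryo = 2, seed = 61)
  sim <- simulateCohort(cfg)
  a <- measureCohort(sim$recordings, blinded = TRUE, seed = 5)
  b <- measureCohort(sim$recordings, blinded = FALSE)
  expect_equal(a$irv, b$irv)
  expect_identical(a$region, b$region)
  expect_identical(a$recording_id, b$recording_id)
})

test_that("missing frames raise a validation error in image mode", {
  rec <- testRecording(v0 = 1)   # tracks-only
  expect_error(measureRecording(rec, mode = "image"),
               class = "rq_validation_error")
})
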