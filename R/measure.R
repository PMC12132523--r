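## IRV measurement: point-pair selection, perpendicular distances,
## triplicate averaging.

px2um <- function(p, pixelSize) (p - 0.5) * pixelSize
um2px <- function(p, pixelSize) p / pixelSize + 0.5

#' Perpendicular point-pair distance
#'
#' Straight-line distance between two points measured perpendicular to the
#' ablation path: the magnitude of the normal component of `p2 - p1`.
#'
#' @param p1,p2 numeric(2) positions, \eqn{\mu m}.
#' @param ablationAxis unit vector along the cut.
#' @return non-negative distance, \eqn{\mu m}.
#' @examples
#' perpendicularDistance(c(0, 0), c(3, 4), c(1, 0))  # 4
#' @export
perpendicularDistance <- function(p1, p2, ablationAxis) {
  n <- normalVector(unitVector(ablationAxis))
  abs(sum((p2 - p1) * n))
}

#' Initial recoil velocity from triplicate distances
#'
#' The three post-ablation distances minus the three pre-ablation distances
#' are averaged into one change in distance, which is divided by the time
#' between frames. Sign is preserved (control IRVs may be negative).
#'
#' @param preDistances,postDistances numeric(3), \eqn{\mu m}.
#' @param deltaT time between the pre and post frames, seconds.
#' @return IRV, \eqn{\mu m/s}.
#' @examples
#' computeIRV(c(10, 10, 10), c(11.248, 11.248, 11.248), 0.416)  # 3
#' @export
computeIRV <- function(preDistances, postDistances, deltaT) {
  if (length(preDistances) != 3L || length(postDistances) != 3L)
    stopValidation("exactly 3 pre and 3 post distances are required")
  if (!all(is.finite(c(preDistances, postDistances))))
    stopValidation("distances must be finite")
  if (!is.numeric(deltaT) || length(deltaT) != 1L || deltaT <= 0)
    stopValidation("deltaT must be a positive scalar")
  mean(postDistances - preDistances) / deltaT
}

# Candidate roles by position relative to the cut (mirrors the generator's
# role bands so image mode and truth-track mode agree).
classifyCandidates <- function(s, q, L, gapWidth, plateauHalfWidth = 6) {
  role <- rep(NA_character_, length(s))
  role[abs(s) <= L / 6 + 3 & abs(q) >= gapWidth / 2 + 0.2 &
         abs(q) <= plateauHalfWidth - 0.5] <- "recoil"
  role[is.na(role) & abs(s) <= L / 2 & abs(q) >= 2 & abs(q) <= 6] <-
    "orthogonal_control"
  role[is.na(role) & abs(s) >= L / 2 + 2 & abs(s) <= L / 2 + 14 &
         abs(q) <= 8] <- "parallel_control"
  role
}

# Detect candidate cell vertices: local maxima of the (already denoised)
# membrane image, with quadratic subpixel refinement. Returns pixel
# coordinates (x, y) and peak intensity.
detectVertices <- function(img, minSeparation = 4L) {
  sm <- denoiseFrame(img, 1)
  H <- nrow(sm); W <- ncol(sm)
  h <- minSeparation %/% 2L
  isMax <- matrix(TRUE, H, W)
  for (dx in -h:h) for (dy in -h:h) {
    if (dx == 0L && dy == 0L) next
    shifted <- matrix(-Inf, H, W)
    ys <- max(1L, 1L + dy):min(H, H + dy)
    xs <- max(1L, 1L + dx):min(W, W + dx)
    shifted[ys, xs] <- sm[ys - dy, xs - dx]
    isMax <- isMax & (sm >= shifted)
  }
  bg <- median(sm)
  thr <- bg + 0.4 * (quantile(sm, 0.999) - bg)
  isMax[sm < thr] <- FALSE
  isMax[c(1L, H), ] <- FALSE; isMax[, c(1L, W)] <- FALSE
  idx <- which(isMax)
  if (!length(idx))
    return(data.frame(x = numeric(0), y = numeric(0), peak = numeric(0)))
  ys <- (idx - 1L) %% H + 1L
  xs <- (idx - 1L) %/% H + 1L
  subpix <- function(m, p, z) {
    den <- m - 2 * p + z
    d <- ifelse(abs(den) > 1e-9, (m - z) / (2 * den), 0)
    pmin(pmax(d, -0.5), 0.5)
  }
  dx <- subpix(sm[cbind(ys, xs - 1L)], sm[idx], sm[cbind(ys, xs + 1L)])
  dy <- subpix(sm[cbind(ys - 1L, xs)], sm[idx], sm[cbind(ys + 1L, xs)])
  data.frame(x = xs + dx, y = ys + dy, peak = sm[idx])
}

# Track one point from pre to (registered) post by normalized
# cross-correlation template matching with quadratic subpixel refinement.
# Returns the displacement in pixels and the NCC confidence.
trackPoint <- function(pre, post, p, halfWin = 7L, searchRadius = 12L) {
  H <- nrow(pre); W <- ncol(pre)
  cx <- round(p[1L]); cy <- round(p[2L])
  h <- halfWin; r <- searchRadius
  if (cx - h < 1L || cx + h > W || cy - h < 1L || cy + h > H)
    return(NULL)
  tpl <- pre[(cy - h):(cy + h), (cx - h):(cx + h)]
  tpl <- tpl - mean(tpl)
  tss <- sqrt(sum(tpl^2))
  if (tss < 1e-9) return(NULL)
  lo <- c(cx - r - h, cy - r - h); hi <- c(cx + r + h, cy + r + h)
  if (lo[1L] < 1L || lo[2L] < 1L || hi[1L] > W || hi[2L] > H) {
    r <- min(r, cx - h - 1L, cy - h - 1L, W - cx - h, H - cy - h)
    if (r < 1L) return(NULL)
  }
  # FFT cross-correlation for the numerator; integral images for the
  # per-patch normalisation. ncc[v + r + 1, u + r + 1] over offsets -r..r.
  region <- post[(cy - r - h):(cy + r + h), (cx - r - h):(cx + r + h)]
  m <- nrow(region); k <- 2L * h + 1L
  P <- stats::nextn(m + k, c(2L, 3L, 5L))
  Rp <- matrix(0, P, P); Rp[seq_len(m), seq_len(m)] <- region
  Tp <- matrix(0, P, P); Tp[seq_len(k), seq_len(k)] <- tpl
  num <- Re(stats::fft(stats::fft(Rp) * Conj(stats::fft(Tp)),
                       inverse = TRUE)) / (P * P)
  nv <- m - k + 1L
  num <- num[seq_len(nv), seq_len(nv)]
  sat <- function(x) {  # summed-area table, S[i+1, j+1] = sum(x[1:i, 1:j])
    cs <- apply(x, 2L, cumsum)
    cs <- t(apply(cs, 1L, cumsum))
    rbind(0, cbind(0, cs))[, , drop = FALSE]
  }
  S1 <- sat(region); S2 <- sat(region^2)
  idx <- seq_len(nv)
  patchSum <- S1[idx + k, idx + k] - S1[idx, idx + k] -
    S1[idx + k, idx] + S1[idx, idx]
  patchSS <- S2[idx + k, idx + k] - S2[idx, idx + k] -
    S2[idx + k, idx] + S2[idx, idx]
  pvar <- pmax(patchSS - patchSum^2 / (k * k), 0)
  ncc <- matrix(-1, nv, nv)
  okv <- pvar > 1e-12
  ncc[okv] <- num[okv] / (sqrt(pvar[okv]) * tss)
  pk <- which(ncc == max(ncc), arr.ind = TRUE)[1L, ]
  v0 <- pk[1L] - r - 1L; u0 <- pk[2L] - r - 1L
  du <- dv <- 0
  if (abs(u0) < r && abs(v0) < r) {
    fit1d <- function(m, p0, z) {
      den <- m - 2 * p0 + z
      if (abs(den) > 1e-12) max(-0.5, min(0.5, (m - z) / (2 * den))) else 0
    }
    du <- fit1d(ncc[pk[1L], pk[2L] - 1L], ncc[pk[1L], pk[2L]],
                ncc[pk[1L], pk[2L] + 1L])
    dv <- fit1d(ncc[pk[1L] - 1L, pk[2L]], ncc[pk[1L], pk[2L]],
                ncc[pk[1L] + 1L, pk[2L]])
  }
  list(displacement = c(u0 + du, v0 + dv), confidence = max(ncc))
}

# Greedy pair formation from a candidate table (columns x, y [um], s, q,
# side, role, conf, post_x, post_y). Deterministic ranking: confidence,
# then proximity to the path centre, then lexicographic position. Works on
# index pairs; one data.frame is assembled per role.
buildPointPairs <- function(cand, L, nReplicates = 3L) {
  assemble <- function(i1, i2, role) {
    data.frame(role = role, replicate = 0L,
               p1x_pre = cand$x[i1], p1y_pre = cand$y[i1],
               p2x_pre = cand$x[i2], p2y_pre = cand$y[i2],
               p1x_post = cand$post_x[i1], p1y_post = cand$post_y[i1],
               p2x_post = cand$post_x[i2], p2y_post = cand$post_y[i2],
               confidence = (cand$conf[i1] + cand$conf[i2]) / 2,
               mid_s = (cand$s[i1] + cand$s[i2]) / 2,
               stringsAsFactors = FALSE)
  }
  rankOrder <- function(i1, i2) {
    conf <- (cand$conf[i1] + cand$conf[i2]) / 2
    mids <- abs(cand$s[i1] + cand$s[i2]) / 2
    order(-conf, mids, cand$x[i1], cand$y[i1])
  }

  # recoil: opposite sides, pair midpoint within the central third
  A <- which(cand$role == "recoil" & cand$side == "A")
  B <- which(cand$role == "recoil" & cand$side == "B")
  p1 <- integer(0); p2 <- integer(0)
  if (length(A) && length(B)) {
    gi <- rep(A, times = length(B))
    gj <- rep(B, each = length(A))
    okm <- abs(cand$s[gi] + cand$s[gj]) / 2 <= L / 6
    gi <- gi[okm]; gj <- gj[okm]
    if (length(gi)) {
      ds <- abs(cand$s[gi] - cand$s[gj])
      cf <- (cand$conf[gi] + cand$conf[gj]) / 2
      o <- order(ds, -cf)
      usedA <- usedB <- integer(0)
      for (k in o) {
        if (gi[k] %in% usedA || gj[k] %in% usedB) next
        p1 <- c(p1, gi[k]); p2 <- c(p2, gj[k])
        usedA <- c(usedA, gi[k]); usedB <- c(usedB, gj[k])
      }
      o2 <- rankOrder(p1, p2)
      p1 <- p1[o2]; p2 <- p2[o2]
    }
  }
  if (length(p1) < nReplicates)
    stopInsufficientLandmarks(sprintf(
      "only %d valid recoil pairs found (need %d)", length(p1), nReplicates))
  recoil <- assemble(p1[seq_len(nReplicates)], p2[seq_len(nReplicates)],
                     "recoil")

  # orthogonal controls: same side, adjacent and parallel to the cut
  o1 <- integer(0); o2i <- integer(0)
  for (sd in c("A", "B")) {
    S <- which(cand$role == "orthogonal_control" & cand$side == sd)
    if (length(S) < 2L) next
    S <- S[order(cand$s[S])]
    i1 <- S[-length(S)]; i2 <- S[-1L]
    ds <- cand$s[i2] - cand$s[i1]
    ok <- ds >= 1.5 & ds <= 12 & abs(cand$q[i2] - cand$q[i1]) <= 2.5
    o1 <- c(o1, i1[ok]); o2i <- c(o2i, i2[ok])
  }
  # parallel controls: outside the ablation path
  q1 <- integer(0); q2 <- integer(0)
  for (endSign in c(-1, 1)) {
    S <- which(cand$role == "parallel_control" & sign(cand$s) == endSign)
    if (length(S) < 2L) next
    cmb <- utils::combn(S, 2L)
    i1 <- cmb[1L, ]; i2 <- cmb[2L, ]
    ok <- abs(cand$q[i1] - cand$q[i2]) >= 2 & abs(cand$s[i1] - cand$s[i2]) <= 12
    q1 <- c(q1, i1[ok]); q2 <- c(q2, i2[ok])
  }
  if (!length(o1) || !length(q1))
    stopInsufficientLandmarks("no valid orthogonal or parallel control pair")
  oo <- rankOrder(o1, o2i)
  o1 <- o1[oo]; o2i <- o2i[oo]
  qo <- rankOrder(q1, q2)
  q1 <- q1[qo]; q2 <- q2[qo]
  sel <- function(v) v[rep(seq_along(v), length.out = nReplicates)]
  out <- rbind(recoil,
               assemble(sel(o1), sel(o2i), "orthogonal_control"),
               assemble(sel(q1), sel(q2), "parallel_control"))
  out$replicate <- rep(seq_len(nReplicates), 3L)
  rownames(out) <- NULL
  out
}

#' Select and track measurement point pairs
#'
#' Implements the three selection criteria for recoil pairs: points clearly
#' visible in both frames (cell vertices), abutting opposite edges of the
#' ablation, near the centre of the ablation path (pair midpoint within the
#' central third). Orthogonal control pairs are adjacent but parallel to the
#' ablation (same side, 2-6 \eqn{\mu m} offset); parallel control pairs lie
#' outside the ablation path (beyond the cut ends).
#'
#' In image mode, candidate vertices are detected as local intensity maxima
#' of the membrane image and tracked pre to post by template matching
#' (window half-width 1.5 \eqn{\mu m}, search radius 2.5 \eqn{\mu m}), each
#' with an NCC match-confidence score. In truth-track mode, candidates are
#' the supplied landmarks (already registered).
#'
#' @param preFrame,postFrame denoised, registered frames (post aligned onto
#'   pre); ignored in truth-track mode.
#' @param center,axis,cutLength,gapWidth ablation geometry in frame
#'   coordinates, \eqn{\mu m}.
#' @param pixelSize \eqn{\mu m}/px (image mode).
#' @param nReplicates recoil replicates (default 3).
#' @param truthTracks optional data.frame (landmark_id, role, side, x_pre,
#'   y_pre, x_post, y_post in \eqn{\mu m}) switching to truth-track mode.
#' @return data.frame of point pairs (one row per role x replicate).
#' @export
selectPointPairs <- function(preFrame = NULL, postFrame = NULL, center, axis,
                             cutLength = 36, gapWidth = 2, pixelSize = 0.21,
                             nReplicates = 3L, truthTracks = NULL) {
  axis <- unitVector(axis)
  n <- normalVector(axis)
  if (!is.null(truthTracks)) {
    rel <- cbind(truthTracks$x_pre - center[1L],
                 truthTracks$y_pre - center[2L])
    cand <- data.frame(x = truthTracks$x_pre, y = truthTracks$y_pre,
                       s = rel %*% axis, q = rel %*% n,
                       side = truthTracks$side, role = truthTracks$role,
                       conf = 1, post_x = truthTracks$x_post,
                       post_y = truthTracks$y_post,
                       stringsAsFactors = FALSE)
    return(buildPointPairs(cand, cutLength, nReplicates))
  }
  if (is.null(preFrame) || is.null(postFrame))
    stopValidation("image mode requires pre and post frames")
  vt <- detectVertices(preFrame)
  if (!nrow(vt)) stopInsufficientLandmarks("no detectable vertices")
  halfWin <- max(3L, round(1.5 / pixelSize))
  searchR <- max(3L, round(2.5 / pixelSize))
  xy <- cbind(px2um(vt$x, pixelSize), px2um(vt$y, pixelSize))
  rel <- sweep(xy, 2L, center)
  s <- as.numeric(rel %*% axis); q <- as.numeric(rel %*% n)
  role <- classifyCandidates(s, q, cutLength, gapWidth)
  keep <- !is.na(role)
  if (!any(keep)) stopInsufficientLandmarks("no vertices near the ablation")
  rows <- which(keep)
  tracked <- lapply(rows, function(i)
    trackPoint(preFrame, postFrame, c(vt$x[i], vt$y[i]), halfWin, searchR))
  okTrack <- !vapply(tracked, is.null, logical(1L))
  conf <- vapply(tracked[okTrack], `[[`, numeric(1L), "confidence")
  goodConf <- conf >= 0.4
  rows <- rows[okTrack][goodConf]
  tracked <- tracked[okTrack][goodConf]
  if (!length(rows)) stopInsufficientLandmarks("no trackable vertices")
  disp <- t(vapply(tracked, `[[`, numeric(2L), "displacement")) * pixelSize
  cand <- data.frame(x = xy[rows, 1L], y = xy[rows, 2L],
                     s = s[rows], q = q[rows],
                     side = ifelse(q[rows] >= 0, "A", "B"),
                     role = role[rows],
                     conf = vapply(tracked, `[[`, numeric(1L), "confidence"),
                     post_x = xy[rows, 1L] + disp[, 1L],
                     post_y = xy[rows, 2L] + disp[, 2L],
                     stringsAsFactors = FALSE)
  buildPointPairs(cand, cutLength, nReplicates)
}

#' Measure one ablation recording
#'
#' The full measurement pipeline: extract the pre/post frame pair, denoise,
#' bring into rigid-body register (registration driven by regions away from
#' the ablation band), select and track point pairs, measure perpendicular
#' distances in triplicate, and compute the initial recoil velocity plus
#' both control IRVs. \eqn{\Delta t} is the frame interval.
#'
#' @param recording a [SyntheticRecording-class] (image stacks or truth
#'   tracks).
#' @param mode `"auto"` (image mode when frames 2 and 3 are rendered, else
#'   tracks), `"image"` or `"tracks"`.
#' @param register logical; estimate and undo the inter-frame rigid motion.
#' @param registerMask `"auto"` (exclude the ablation band dilated by 5
#'   \eqn{\mu m}) or `"none"`.
#' @param denoiseStrength Gaussian sigma in pixels for [denoiseFrame()].
#' @param nReplicates replicate point pairs per role (default 3).
#' @return a [RecoilMeasurement-class].
#' @examples
#' mesh <- buildCellMesh(64, 6, seed = 3)
#' rec <- simulateAblationRecording(mesh, ablationSpec(c(32, 32), "RC"),
#'                                  recoilKinetics(v0 = 3), seed = 3)
#' measureRecording(rec)
#' @export
measureRecording <- function(recording, mode = c("auto", "image", "tracks"),
                             register = TRUE,
                             registerMask = c("auto", "none"),
                             denoiseStrength = 1, nReplicates = 3L) {
  mode <- match.arg(mode)
  registerMask <- match.arg(registerMask)
  spec <- recording@spec
  f <- spec@ablationBetween
  hasFrames <- !is.null(recording@stack) &&
    all(is.finite(recording@stack[, , f[1L]])) &&
    all(is.finite(recording@stack[, , f[2L]]))
  if (mode == "auto") mode <- if (hasFrames) "image" else "tracks"
  center <- recording@measuredCenter
  axis <- recording@measuredAxis
  transform <- NULL

  if (mode == "image") {
    if (!hasFrames)
      stopValidation("frames 2 and 3 are required for image-mode measurement")
    px <- recording@pixelSize
    pre <- denoiseFrame(recording@stack[, , f[1L]], denoiseStrength)
    post <- denoiseFrame(recording@stack[, , f[2L]], denoiseStrength)
    if (register) {
      mask <- NULL
      if (registerMask == "auto") {
        dims <- dim(pre)
        gx <- px2um(rep(seq_len(dims[2L]), each = dims[1L]), px)
        gy <- px2um(rep(seq_len(dims[1L]), dims[2L]), px)
        sA <- (gx - center[1L]) * axis[1L] + (gy - center[2L]) * axis[2L]
        qA <- (gx - center[1L]) * -axis[2L] + (gy - center[2L]) * axis[1L]
        mask <- matrix(!(abs(qA) < spec@gapWidth / 2 + 5 &
                           abs(sA) < spec@length / 2 + 5),
                       dims[1L], dims[2L])
      }
      transform <- estimateRigidTransform(pre, post, mask = mask)
      post <- transformImage(post, invertRigidTransform(transform))
    }
    pairs <- selectPointPairs(pre, post, center = center, axis = axis,
                              cutLength = spec@length,
                              gapWidth = spec@gapWidth, pixelSize = px,
                              nReplicates = nReplicates)
  } else {
    tt <- recording@truthTracks
    if (!nrow(tt)) stopValidation("recording has no truth tracks")
    t2 <- tt[tt$frame == f[1L], ]
    t3 <- tt[tt$frame == f[2L], ]
    p3 <- cbind(t3$x_um, t3$y_um)
    if (register) {
      parIdx <- t2$role == "parallel_control"
      if (sum(parIdx) >= 2L) {
        transform <- fitRigidPoints(cbind(t2$x_um, t2$y_um)[parIdx, ,
                                                            drop = FALSE],
                                    p3[parIdx, , drop = FALSE])
        p3 <- transformPoints(p3, invertRigidTransform(transform))
      }
    }
    tracks <- data.frame(landmark_id = t2$landmark_id, role = t2$role,
                         side = t2$side, x_pre = t2$x_um, y_pre = t2$y_um,
                         x_post = p3[, 1L], y_post = p3[, 2L],
                         stringsAsFactors = FALSE)
    pairs <- selectPointPairs(center = center, axis = axis,
                              cutLength = spec@length,
                              gapWidth = spec@gapWidth,
                              nReplicates = nReplicates,
                              truthTracks = tracks)
  }

  roles <- c("recoil", "orthogonal_control", "parallel_control")
  pre_d <- post_d <- matrix(NA_real_, 3L, nReplicates,
                            dimnames = list(c("recoil", "orthogonal",
                                              "parallel"), NULL))
  for (ri in seq_along(roles)) {
    pr <- pairs[pairs$role == roles[ri], , drop = FALSE]
    for (k in seq_len(nReplicates)) {
      pre_d[ri, k] <- perpendicularDistance(
        c(pr$p1x_pre[k], pr$p1y_pre[k]), c(pr$p2x_pre[k], pr$p2y_pre[k]),
        axis)
      post_d[ri, k] <- perpendicularDistance(
        c(pr$p1x_post[k], pr$p1y_post[k]), c(pr$p2x_post[k], pr$p2y_post[k]),
        axis)
    }
  }
  dt <- spec@frameInterval
  new("RecoilMeasurement", recordingId = recording@recordingId,
      irv = mean(post_d[1L, ] - pre_d[1L, ]) / dt,
      orthogonalIrv = mean(post_d[2L, ] - pre_d[2L, ]) / dt,
      parallelIrv = mean(post_d[3L, ] - pre_d[3L, ]) / dt,
      preDistances = pre_d, postDistances = post_d, deltaT = dt,
      region = recording@region, orientation = recording@orientation,
      provenance = list(mode = mode, pairs = pairs, transform = transform,
                        register = register, registerMask = registerMask,
                        denoiseStrength = denoiseStrength))
}

#' Measure a cohort of recordings
#'
#' Runs [measureRecording()] over a list of recordings. Recordings where
#' point-pair selection fails are flagged (`insufficient_landmarks`), not
#' silently dropped. With `blinded = TRUE` the recordings are processed in a
#' shuffled order with their group labels stripped; labels are re-joined
#' onto the results afterwards, so the measurement itself never sees them.
#'
#' @param recordings list of [SyntheticRecording-class].
#' @param blinded logical (default TRUE).
#' @param seed integer, shuffle seed for blinded mode.
#' @param ... passed to [measureRecording()].
#' @return data.frame, one row per recording: recording_id, embryo_id, irv,
#'   control IRVs, triplicate distances per role, delta_t, region,
#'   orientation, insufficient_landmarks flag.
#' @export
measureCohort <- function(recordings, blinded = TRUE, seed = 1L, ...) {
  ord <- seq_along(recordings)
  if (blinded)
    ord <- withr::with_seed(as.integer(seed), sample(ord))
  rows <- vector("list", length(recordings))
  for (i in ord) {
    rec <- recordings[[i]]
    work <- rec
    if (blinded) {
      work@region <- "blinded"
      work@orientation <- "blinded"
    }
    m <- tryCatch(measureRecording(work, ...), rq_insufficient_landmarks =
                    function(e) e)
    if (inherits(m, "condition")) {
      row <- data.frame(recording_id = rec@recordingId,
                        embryo_id = rec@embryoId, irv = NA_real_,
                        orth_irv = NA_real_, par_irv = NA_real_,
                        insufficient_landmarks = TRUE,
                        stringsAsFactors = FALSE)
      d <- as.data.frame(matrix(NA_real_, 1L, 18L))
    } else {
      row <- data.frame(recording_id = rec@recordingId,
                        embryo_id = rec@embryoId, irv = m@irv,
                        orth_irv = m@orthogonalIrv, par_irv = m@parallelIrv,
                        insufficient_landmarks = FALSE,
                        stringsAsFactors = FALSE)
      d <- as.data.frame(matrix(c(t(m@preDistances), t(m@postDistances)),
                                1L))
    }
    names(d) <- c(outer(1:3, c("recoil_pre", "orth_pre", "par_pre"),
                        function(k, nm) paste0(nm, k)),
                  outer(1:3, c("recoil_post", "orth_post", "par_post"),
                        function(k, nm) paste0(nm, k)))
    row <- cbind(row, d)
    row$delta_t_s <- rec@spec@frameInterval
    row$region <- rec@region
    row$orientation <- rec@orientation
    row$bubbles <- isTRUE(rec@flags$bubbles)
    row$outside_region <- isTRUE(rec@flags$outside_region)
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
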