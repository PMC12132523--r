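## Frame-pair preparation: denoising and rigid-body registration.

#' Denoise a frame
#'
#' Gaussian smoothing (via [EBImage::gblur]) meeting the pipeline's
#' denoising contract: dimensions preserved, intensity order of large-scale
#' structures preserved, exact shift-equivariance (linear filter), symmetric
#' kernel (no edge displacement).
#'
#' @param frame numeric matrix with finite values.
#' @param strength Gaussian sigma in pixels (default 1).
#' @return denoised matrix of the same dimensions.
#' @export
denoiseFrame <- function(frame, strength = 1) {
  if (!all(is.finite(frame))) stopValidation("frame contains non-finite pixels")
  if (strength <= 0) return(frame)
  out <- EBImage::gblur(frame, sigma = strength, boundary = "replicate")
  matrix(as.numeric(out), nrow(frame), ncol(frame))
}

# -- rigid transform algebra ------------------------------------------------
# A RigidTransform maps p -> R(p - center) + center + translation. Points
# are (x, y) pairs in pixel units; images are [row = y, col = x] matrices
# with pixel (i, j) centred at (x = j, y = i).

#' Apply a rigid transform to points or an image
#'
#' Points are transformed in closed form; images are resampled with bilinear
#' interpolation so that image content moves by the transform (a feature at
#' p appears at `W(p)` in the output).
#'
#' @param x an n x 2 matrix of points, or an image matrix. Two-column
#'   matrices are treated as points; pass `type = "image"` to override.
#' @param transform a [RigidTransform-class].
#' @param type `"points"` or `"image"` (default guessed from shape).
#' @return transformed points or resampled image.
#' @export
applyRigidTransform <- function(x, transform,
                                type = if (is.matrix(x) && ncol(x) == 2L)
                                  "points" else "image") {
  type <- match.arg(type, c("points", "image"))
  if (type == "points") transformPoints(x, transform)
  else transformImage(x, transform)
}

transformPoints <- function(points, tf) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L, byrow = TRUE)
  R <- rotationMatrix2(tf@rotation)
  sweep(sweep(points, 2L, tf@center) %*% t(R), 2L,
        tf@center + tf@translation, "+")
}

#' Invert a rigid transform
#' @param transform a [RigidTransform-class].
#' @return the inverse [RigidTransform-class] (same centre).
#' @export
invertRigidTransform <- function(transform) {
  Rinv <- rotationMatrix2(-transform@rotation)
  rigidTransform(-transform@rotation,
                 as.numeric(-Rinv %*% transform@translation),
                 transform@center)
}

# Bilinear sampling of img at pixel coordinates (x, y); outside -> fill.
bilinearSample <- function(img, x, y, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 1 & x0 <= W - 1 & y0 >= 1 & y0 <= H - 1
  out <- rep(fill, length(x))
  if (any(ok)) {
    xi <- x0[ok]; yi <- y0[ok]; fxi <- fx[ok]; fyi <- fy[ok]
    i00 <- yi + (xi - 1) * H
    v <- img[i00] * (1 - fxi) * (1 - fyi) + img[i00 + H] * fxi * (1 - fyi) +
      img[i00 + 1] * (1 - fxi) * fyi + img[i00 + H + 1] * fxi * fyi
    out[ok] <- v
  }
  out
}

transformImage <- function(img, tf, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  inv <- invertRigidTransform(tf)
  grid <- cbind(rep(seq_len(W), each = H), rep(seq_len(H), W))
  src <- transformPoints(grid, inv)
  matrix(bilinearSample(img, src[, 1L], src[, 2L], fill), H, W)
}

# 2x block-mean downsample (crops odd trailing row/col).
downsample2 <- function(img) {
  H <- 2L * (nrow(img) %/% 2L); W <- 2L * (ncol(img) %/% 2L)
  img <- img[seq_len(H), seq_len(W), drop = FALSE]
  (img[seq(1L, H, 2L), seq(1L, W, 2L)] + img[seq(2L, H, 2L), seq(1L, W, 2L)] +
     img[seq(1L, H, 2L), seq(2L, W, 2L)] +
     img[seq(2L, H, 2L), seq(2L, W, 2L)]) / 4
}

hannWindow <- function(H, W) {
  wy <- 0.5 - 0.5 * cos(2 * pi * (seq_len(H) - 1) / (H - 1))
  wx <- 0.5 - 0.5 * cos(2 * pi * (seq_len(W) - 1) / (W - 1))
  outer(wy, wx)
}

# Translation by phase correlation: returns s = (sx, sy) such that
# mov(p) ~ ref(p - s) (content of ref moved by +s gives mov), plus the
# normalized correlation peak as a score.
phaseCorrelate <- function(ref, mov) {
  w <- hannWindow(nrow(ref), ncol(ref))
  Fr <- stats::fft((ref - mean(ref)) * w)
  Fm <- stats::fft((mov - mean(mov)) * w)
  Rs <- Fm * Conj(Fr)
  mag <- Mod(Rs); mag[mag < 1e-12] <- 1e-12
  r <- Re(stats::fft(Rs / mag, inverse = TRUE)) / length(Rs)
  pk <- which.max(r)
  iy <- (pk - 1L) %% nrow(r) + 1L
  ix <- (pk - 1L) %/% nrow(r) + 1L
  sy <- iy - 1L; sx <- ix - 1L
  if (sy > nrow(r) / 2) sy <- sy - nrow(r)
  if (sx > ncol(r) / 2) sx <- sx - ncol(r)
  list(shift = c(sx, sy), score = max(r))
}

#' Estimate the rigid-body transform between two frames
#'
#' Intensity-based rigid registration: a coarse rotation search with phase
#' correlation for translation on a downsampled pyramid, followed by masked
#' Gauss-Newton least-squares refinement of (rotation, translation) over
#' pyramid levels. Returns the transform that, applied to `reference`
#' content, produces `moving` (so registering `moving` back onto
#' `reference` uses the inverse).
#'
#' When `mask` is supplied (TRUE = usable pixel), refinement is driven only
#' by masked-in pixels, so e.g. the ablation band can be excluded and the
#' recoil itself is not corrected away.
#'
#' @param reference,moving numeric matrices of identical dimensions.
#' @param mask optional logical matrix, TRUE where registration may look.
#' @param maxRotation bound of the coarse rotation search, degrees.
#' @param pyramidLevels number of pyramid levels (default 3).
#' @return a [RigidTransform-class] (rotation about the image centre).
#' @export
estimateRigidTransform <- function(reference, moving, mask = NULL,
                                   maxRotation = 6, pyramidLevels = 3L) {
  if (!all(dim(reference) == dim(moving)))
    stopValidation("frames must have identical dimensions")
  if (var(as.numeric(reference)) == 0 || var(as.numeric(moving)) == 0)
    stopDegenerateInput("featureless image: zero intensity variance")
  center <- c(ncol(reference), nrow(reference)) / 2 + 0.5

  refs <- list(reference); movs <- list(moving)
  masks <- list(if (is.null(mask)) NULL else mask * 1)
  for (l in seq_len(pyramidLevels - 1L)) {
    refs[[l + 1L]] <- downsample2(refs[[l]])
    movs[[l + 1L]] <- downsample2(movs[[l]])
    masks[[l + 1L]] <- if (is.null(mask)) NULL else downsample2(masks[[l]])
  }

  # coarse: rotation grid + phase correlation at the top pyramid level
  L <- pyramidLevels
  scale <- 2^(L - 1L)
  cL <- center / scale
  best <- list(theta = 0, shift = c(0, 0), score = -Inf)
  thetas <- if (maxRotation > 0) seq(-maxRotation, maxRotation, by = 1) else 0
  for (th in thetas) {
    undone <- transformImage(movs[[L]], rigidTransform(-th, c(0, 0), cL))
    pc <- phaseCorrelate(refs[[L]], undone)
    if (pc$score > best$score)
      best <- list(theta = th, shift = pc$shift, score = pc$score)
  }
  # compose: content shifted by s then rotated by theta equals
  # W(x) = R(x - c) + c + R s
  theta <- best$theta
  trans <- as.numeric(rotationMatrix2(theta) %*% best$shift) * scale

  for (l in seq(L, 1L)) {
    sc <- 2^(l - 1L)
    fit <- refineRigidGN(refs[[l]], movs[[l]],
                         if (is.null(mask)) NULL else masks[[l]] > 0.5,
                         theta, trans / sc, center / sc)
    theta <- fit$theta
    trans <- fit$trans * sc
  }
  rigidTransform(theta, trans, center)
}

# Gauss-Newton refinement of W(x) = R(x - c) + c + t minimizing
# sum_mask (mov(W(x)) - ref(x))^2.
refineRigidGN <- function(ref, mov, mask, theta, trans, center,
                          maxIter = 15L, maxPixels = 20000L) {
  H <- nrow(ref); W <- ncol(ref)
  use <- matrix(TRUE, H, W)
  if (!is.null(mask)) use <- use & mask
  # interior only (gradient validity)
  use[c(1L, H), ] <- FALSE; use[, c(1L, W)] <- FALSE
  idx <- which(use)
  if (length(idx) > maxPixels)
    idx <- idx[round(seq(1L, length(idx), length.out = maxPixels))]
  ys <- (idx - 1L) %% H + 1L
  xs <- (idx - 1L) %/% H + 1L
  refv <- ref[idx]
  # gradient images of mov (central differences)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  gx[, 2:(W - 1L)] <- (mov[, 3:W] - mov[, 1:(W - 2L)]) / 2
  gy[2:(H - 1L), ] <- (mov[3:H, ] - mov[1:(H - 2L), ]) / 2

  for (it in seq_len(maxIter)) {
    R <- rotationMatrix2(theta)
    dx <- xs - center[1L]; dy <- ys - center[2L]
    wx <- R[1L, 1L] * dx + R[1L, 2L] * dy + center[1L] + trans[1L]
    wy <- R[2L, 1L] * dx + R[2L, 2L] * dy + center[2L] + trans[2L]
    inb <- wx >= 2 & wx <= W - 1 & wy >= 2 & wy <= H - 1
    if (sum(inb) < 50L) break
    mv <- bilinearSample(mov, wx[inb], wy[inb])
    r <- mv - refv[inb]
    gxv <- bilinearSample(gx, wx[inb], wy[inb])
    gyv <- bilinearSample(gy, wx[inb], wy[inb])
    thr <- theta * pi / 180
    # d(W)/dtheta in radians
    dwx <- -sin(thr) * dx[inb] - cos(thr) * dy[inb]
    dwy <- cos(thr) * dx[inb] - sin(thr) * dy[inb]
    J <- cbind(gxv * dwx + gyv * dwy, gxv, gyv)
    JtJ <- crossprod(J)
    diag(JtJ) <- diag(JtJ) * (1 + 1e-8) + 1e-12
    delta <- tryCatch(solve(JtJ, -crossprod(J, r)),
                      error = function(e) rep(0, 3L))
    theta <- theta + delta[1L] * 180 / pi
    trans <- trans + delta[2:3]
    if (abs(delta[1L]) * 180 / pi < 1e-4 && max(abs(delta[2:3])) < 1e-3)
      break
  }
  list(theta = theta, trans = trans)
}

# Least-squares 2D rigid fit (Kabsch) mapping `from` points onto `to`:
# to ~ R from + t. Used for tracks-mode registration from control
# landmarks.
fitRigidPoints <- function(from, to) {
  if (nrow(from) < 2L)
    stopDegenerateInput("need at least 2 points for a rigid fit")
  cf <- colMeans(from); ct <- colMeans(to)
  Hm <- crossprod(sweep(from, 2L, cf), sweep(to, 2L, ct))
  sv <- svd(Hm)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
  theta <- atan2(R[2L, 1L], R[1L, 1L]) * 180 / pi
  tvec <- ct - as.numeric(R %*% cf)
  rigidTransform(theta, tvec, c(0, 0))
}
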