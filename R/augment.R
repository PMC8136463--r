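#' Augmentation configuration
#'
#' Ranges for the three training-time augmentations: a random affine
#' transform (rotation, uniform scale, translation about the image
#' centre), a random gamma change (`I^gamma` on \[0,1\] intensities) and
#' random erasure of a rectangle (filled with 0).  Ranges are sampled
#' uniformly.  Defaults — rotation +/-15 degrees, scale 0.9–1.1,
#' translation +/-5% of the image size, erased area up to 10% — are
#' package choices of typical magnitudes for ultrasound keypoint
#' training.
#'
#' @param rotation_deg,scale,translate_frac,gamma,erase_area_frac numeric
#'   `c(lo, hi)` sampling intervals.
#' @return list of class `aug_config`.
#' @export
aug_config <- function(rotation_deg = c(-15, 15), scale = c(0.9, 1.1),
                       translate_frac = c(-0.05, 0.05),
                       gamma = c(0.8, 1.25),
                       erase_area_frac = c(0, 0.10)) {
  rng <- list(rotation_deg = rotation_deg, scale = scale,
              translate_frac = translate_frac, gamma = gamma,
              erase_area_frac = erase_area_frac)
  for (nm in names(rng)) {
    r <- rng[[nm]]
    if (length(r) != 2L || diff(r) < 0)
      .stopf("%s must be an interval c(lo, hi)", nm)
  }
  if (any(rng$gamma <= 0)) .stopf("gamma range must be positive")
  if (any(rng$scale <= 0)) .stopf("scale range must be positive")
  if (any(rng$erase_area_frac < 0) || any(rng$erase_area_frac > 1))
    .stopf("erase_area_frac must lie in [0, 1]")
  structure(rng, class = "aug_config")
}

#' @describeIn aug_config degenerate ranges that leave the input
#'   unchanged.
#' @export
identity_aug_config <- function() {
  aug_config(rotation_deg = c(0, 0), scale = c(1, 1),
             translate_frac = c(0, 0), gamma = c(1, 1),
             erase_area_frac = c(0, 0))
}

# bilinear sample of `img` at fractional (x, y); outside -> 0
.bilinear <- function(img, px, py) {
  H <- nrow(img); W <- ncol(img)
  x0 <- floor(px); y0 <- floor(py)
  fx <- px - x0; fy <- py - y0
  at <- function(xx, yy) {
    ok <- xx >= 0 & xx <= W - 1 & yy >= 0 & yy <= H - 1
    v <- numeric(length(xx))
    v[ok] <- img[cbind(yy[ok] + 1, xx[ok] + 1)]
    v
  }
  at(x0, y0) * (1 - fx) * (1 - fy) + at(x0 + 1, y0) * fx * (1 - fy) +
    at(x0, y0 + 1) * (1 - fx) * fy + at(x0 + 1, y0 + 1) * fx * fy
}

#' Randomly augment an image and its keypoints consistently
#'
#' Samples one affine transform, gamma and erasure rectangle from
#' `config` and applies them: the affine is applied identically to image
#' (bilinear resampling, zero outside) and keypoint coordinates; gamma
#' and erasure affect only the image.  Keypoints mapped outside the
#' raster are flagged invalid so downstream loss weighting can zero
#' them; an erased rectangle does not invalidate a keypoint.
#'
#' @param image numeric matrix with intensities in \[0, 1\].
#' @param keypoints data frame with columns `x`, `y` (0-based pixels).
#' @param config an [aug_config()].
#' @param seed integer seed; the same seed reproduces the augmentation.
#' @return list with `image`, `keypoints` (input plus logical `valid`),
#'   and `params` (the sampled transform).
#' @export
augment_frame <- function(image, keypoints, config = aug_config(),
                          seed = 1L) {
  if (any(image < 0 | image > 1)) .stopf("image intensities must be in [0, 1]")
  .check_cols(keypoints, c("x", "y"), "keypoints")
  set.seed(seed)
  H <- nrow(image); W <- ncol(image)
  runif1 <- function(r) stats::runif(1, r[1], r[2])
  theta <- runif1(config$rotation_deg) * pi / 180
  sc <- runif1(config$scale)
  tx <- runif1(config$translate_frac) * W
  ty <- runif1(config$translate_frac) * H
  gam <- runif1(config$gamma)
  efrac <- runif1(config$erase_area_frac)
  ctr <- c((W - 1) / 2, (H - 1) / 2)
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  fwd <- function(x, y) {
    p <- sc * R %*% rbind(x - ctr[1], y - ctr[2])
    list(x = p[1, ] + ctr[1] + tx, y = p[2, ] + ctr[2] + ty)
  }
  inv <- function(x, y) {
    p <- t(R) %*% rbind(x - ctr[1] - tx, y - ctr[2] - ty) / sc
    list(x = p[1, ] + ctr[1], y = p[2, ] + ctr[2])
  }
  identity_affine <- theta == 0 && sc == 1 && tx == 0 && ty == 0
  if (identity_affine) {
    out <- image
  } else {
    qx <- rep(0:(W - 1), each = H)
    qy <- rep(0:(H - 1), times = W)
    src <- inv(qx, qy)
    out <- matrix(.bilinear(image, src$x, src$y), H, W)
  }
  if (gam != 1) out <- out^gam
  if (efrac > 0) {
    area <- efrac * H * W
    ar <- stats::runif(1, 0.5, 2)
    ew <- max(1L, min(W, round(sqrt(area * ar))))
    eh <- max(1L, min(H, round(area / ew)))
    ex <- sample.int(W - ew + 1L, 1L)
    ey <- sample.int(H - eh + 1L, 1L)
    out[ey:(ey + eh - 1L), ex:(ex + ew - 1L)] <- 0
  }
  kp <- fwd(keypoints$x, keypoints$y)
  keypoints$x <- kp$x
  keypoints$y <- kp$y
  keypoints$valid <- kp$x >= 0 & kp$x <= W - 1 & kp$y >= 0 & kp$y <= H - 1
  list(image = out, keypoints = keypoints,
       params = list(rotation_deg = theta * 180 / pi, scale = sc,
                     translate_px = c(tx, ty), gamma = gam,
                     erase_area_frac = efrac))
}
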