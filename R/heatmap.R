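#' Encode a keypoint as a Gaussian heatmap regression target
#'
#' The target is an image with intensity 1 at the point of interest,
#' decaying to 0 in all directions as a Gaussian with SD `sigma_px`
#' (default 4 pixels): the value at pixel `q` is
#' `exp(-||q - p||^2 / (2 sigma^2))`.  A missing point encodes to the
#' all-zero map.  No renormalisation is applied after boundary
#' truncation, so the peak stays exactly 1 for in-raster integer points.
#'
#' @param point numeric `c(x, y)` (0-based pixel coordinates) or `NULL` /
#'   `NA` for a missing keypoint.
#' @param shape integer `c(rows, cols)`.
#' @param sigma_px Gaussian SD in pixels.
#' @return `rows x cols` numeric matrix in \[0, 1\].
#' @export
encode_heatmap <- function(point, shape, sigma_px = 4) {
  if (length(shape) != 2L || any(shape < 1L))
    .stopf("shape must be positive c(rows, cols)")
  if (sigma_px <= 0) .stopf("sigma_px must be positive")
  H <- shape[1]; W <- shape[2]
  if (is.null(point) || anyNA(point)) return(matrix(0, H, W))
  x <- point[1]; y <- point[2]
  if (x < 0 || x > W - 1 || y < 0 || y > H - 1)
    .stopf("point (%.3g, %.3g) outside a %dx%d raster", x, y, H, W)
  dx2 <- ((0:(W - 1)) - x)^2
  dy2 <- ((0:(H - 1)) - y)^2
  exp(-outer(dy2, dx2, `+`) / (2 * sigma_px^2))
}

#' Decode a heatmap to its peak coordinate
#'
#' Returns the 0-based `c(x, y)` position of the maximum value.  Ties are
#' broken at the smallest row-major index (scanning rows top to bottom,
#' left to right).  An all-zero map decodes to `NULL` (missing keypoint).
#'
#' @param h numeric matrix.
#' @return numeric `c(x, y)` or `NULL`.
#' @export
decode_heatmap <- function(h) {
  if (!length(h)) .stopf("empty heatmap")
  if (all(h == 0)) return(NULL)
  idx <- which(h == max(h), arr.ind = TRUE)
  rm_index <- (idx[, 1] - 1) * ncol(h) + (idx[, 2] - 1)
  i <- which.min(rm_index)
  c(x = unname(idx[i, 2]) - 1, y = unname(idx[i, 1]) - 1)
}

#' Centre crop (or zero-pad) an image to a square target
#'
#' Crops/pads each axis symmetrically to `target` pixels, assigning the
#' odd leftover pixel to the trailing side; padding value is 0.  The
#' returned spec maps coordinates between the original and cropped
#' rasters (`cropped = original + offset`).
#'
#' @param image numeric matrix.
#' @param target side length of the output, pixels.
#' @return list with `image` (`target x target`) and `spec`, a
#'   `crop_spec` carrying `row_offset` and `col_offset` (y and x
#'   additive offsets) plus the per-side crop/pad amounts.
#' @export
center_crop <- function(image, target = 640L) {
  if (!length(image)) .stopf("empty image")
  axis_plan <- function(n) {
    if (n >= target) {
      lead <- (n - target) %/% 2
      list(crop_lead = lead, crop_trail = n - target - lead,
           pad_lead = 0L, pad_trail = 0L, offset = -lead)
    } else {
      lead <- (target - n) %/% 2
      list(crop_lead = 0L, crop_trail = 0L,
           pad_lead = lead, pad_trail = target - n - lead, offset = lead)
    }
  }
  rp <- axis_plan(nrow(image))
  cp <- axis_plan(ncol(image))
  out <- matrix(0, target, target)
  src_r <- (1 + rp$crop_lead):(nrow(image) - rp$crop_trail)
  src_c <- (1 + cp$crop_lead):(ncol(image) - cp$crop_trail)
  out[(1 + rp$pad_lead):(rp$pad_lead + length(src_r)),
      (1 + cp$pad_lead):(cp$pad_lead + length(src_c))] <-
    image[src_r, src_c]
  spec <- structure(list(target = target,
                         row_offset = rp$offset, col_offset = cp$offset,
                         rows = rp, cols = cp), class = "crop_spec")
  list(image = out, spec = spec)
}

#' Map keypoint coordinates through a crop
#'
#' Applies (or inverts) a [center_crop()] coordinate map to `c(x, y)`
#' points; applying then inverting is the identity.
#'
#' @param points numeric `c(x, y)` or a matrix / data frame with columns
#'   `x`, `y` (or two unnamed columns).
#' @param spec a `crop_spec`.
#' @param inverse map cropped coordinates back to the original raster.
#' @return same shape as `points`.
#' @export
apply_crop_spec <- function(points, spec, inverse = FALSE) {
  s <- if (inverse) -1 else 1
  shift <- function(x, y) list(x = x + s * spec$col_offset,
                               y = y + s * spec$row_offset)
  if (is.null(dim(points))) {
    z <- shift(points[1], points[2])
    out <- points
    out[1] <- z$x; out[2] <- z$y
    return(out)
  }
  cx <- if ("x" %in% colnames(points)) "x" else 1L
  cy <- if ("y" %in% colnames(points)) "y" else 2L
  z <- shift(points[, cx], points[, cy])
  points[, cx] <- z$x
  points[, cy] <- z$y
  points
}

#' Per-keypoint loss weights from an annotation
#'
#' Missing keypoints get weight 0 so the corresponding heatmap
#' contributes nothing to a training loss; present keypoints get 1.
#'
#' @param annotation data frame with columns `keypoint_name` and
#'   `missing` (one reading of one frame).
#' @return named numeric vector over [keypoint_names()].
#' @export
loss_weights <- function(annotation) {
  .check_cols(annotation, c("keypoint_name", "missing"), "annotation")
  w <- stats::setNames(rep(0, 4), keypoint_names())
  i <- match(annotation$keypoint_name, names(w))
  w[i[!is.na(i)]] <- as.numeric(!annotation$missing[!is.na(i)])
  w
}

#' Convert pixel coordinates to physical millimetres (and back)
#'
#' `x_mm = x_px * col_spacing`, `y_mm = y_px * row_spacing` — the
#' conversion applied with DICOM PixelSpacing metadata (row spacing
#' first, then column).
#'
#' @param point numeric `c(x, y)`.
#' @param pixel_spacing_row_mm,pixel_spacing_col_mm mm per pixel, > 0.
#' @return numeric `c(x, y)` in the other unit.
#' @export
pixels_to_mm <- function(point, pixel_spacing_row_mm,
                         pixel_spacing_col_mm) {
  if (pixel_spacing_row_mm <= 0 || pixel_spacing_col_mm <= 0)
    .stopf("pixel spacings must be positive")
  c(point[1] * pixel_spacing_col_mm, point[2] * pixel_spacing_row_mm)
}

#' @rdname pixels_to_mm
#' @export
mm_to_pixels <- function(point, pixel_spacing_row_mm,
                         pixel_spacing_col_mm) {
  if (pixel_spacing_row_mm <= 0 || pixel_spacing_col_mm <= 0)
    .stopf("pixel spacings must be positive")
  c(point[1] / pixel_spacing_col_mm, point[2] / pixel_spacing_row_mm)
}
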