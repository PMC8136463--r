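#' Compute the three LV dimensions from one keypoint set
#'
#' Each dimension is the Euclidean distance, in mm space, between its two
#' keypoints: IVS from `sept_ant` to `sept_post`, LVID from `sept_post`
#' to `pw_endo`, PW from `pw_endo` to `pw_epi`.  Distances are computed
#' after per-axis pixel-spacing conversion so anisotropic rasters are
#' honoured.  A dimension is missing (`NA`) exactly when either of its
#' keypoints is missing; no plausibility clamping is applied.
#'
#' @param keypoints data frame with columns `keypoint_name`, `x_px`,
#'   `y_px`, `missing` (one reading of one frame).
#' @param pixel_spacing_row_mm,pixel_spacing_col_mm mm per pixel, > 0.
#' @return named numeric `c(ivs_mm, lvid_mm, pw_mm)` (with `NA` for
#'   missing dimensions).
#' @export
compute_dimensions <- function(keypoints, pixel_spacing_row_mm,
                               pixel_spacing_col_mm) {
  if (pixel_spacing_row_mm <= 0 || pixel_spacing_col_mm <= 0)
    .stopf("pixel spacings must be positive")
  .check_cols(keypoints, c("keypoint_name", "x_px", "y_px", "missing"),
              "keypoints")
  get_mm <- function(name) {
    i <- match(name, keypoints$keypoint_name)
    if (is.na(i) || keypoints$missing[i] || is.na(keypoints$x_px[i]))
      return(NULL)
    c(keypoints$x_px[i] * pixel_spacing_col_mm,
      keypoints$y_px[i] * pixel_spacing_row_mm)
  }
  dl <- dimension_lines()
  out <- vapply(seq_len(nrow(dl)), function(i) {
    a <- get_mm(dl$start[i]); b <- get_mm(dl$end[i])
    if (is.null(a) || is.null(b)) NA_real_ else sqrt(sum((a - b)^2))
  }, numeric(1))
  stats::setNames(out, paste0(dl$dimension, "_mm"))
}

#' Euclidean localization error of one keypoint, in mm
#'
#' @param point,reference_point numeric `c(x, y)` in pixels, or `NULL` /
#'   `NA` when missing.
#' @param pixel_spacing_row_mm,pixel_spacing_col_mm mm per pixel, > 0.
#' @return distance in mm, or `NA` if either point is missing.
#' @export
keypoint_localization_error <- function(point, reference_point,
                                        pixel_spacing_row_mm,
                                        pixel_spacing_col_mm) {
  if (is.null(point) || is.null(reference_point) || anyNA(point) ||
      anyNA(reference_point)) return(NA_real_)
  a <- pixels_to_mm(point, pixel_spacing_row_mm, pixel_spacing_col_mm)
  b <- pixels_to_mm(reference_point, pixel_spacing_row_mm,
                    pixel_spacing_col_mm)
  sqrt(sum((a - b)^2))
}

#' Measurement table from an annotation table
#'
#' Applies [compute_dimensions()] to every (frame, rater, reading)
#' group, joining per-frame pixel spacing and cardiac phase from the
#' frame metadata.
#'
#' @param annotations annotation table (`frame_id`, `rater_id`,
#'   `reading_index`, `keypoint_name`, `x_px`, `y_px`, `missing`).
#' @param frames_meta frame metadata (`frame_id`, `phase`,
#'   `pixel_spacing_row_mm`, `pixel_spacing_col_mm`).
#' @return data frame `frame_id`, `rater_id`, `reading_index`, `phase`,
#'   `ivs_mm`, `lvid_mm`, `pw_mm`.
#' @export
measurements_from_annotations <- function(annotations, frames_meta) {
  .check_cols(annotations, c("frame_id", "rater_id", "reading_index",
                             "keypoint_name", "x_px", "y_px", "missing"),
              "annotations")
  .check_cols(frames_meta, c("frame_id", "phase", "pixel_spacing_row_mm",
                             "pixel_spacing_col_mm"), "frames_meta")
  orphans <- setdiff(unique(annotations$frame_id), frames_meta$frame_id)
  if (length(orphans))
    .stopf("annotations reference frame id(s) absent from frames: %s",
           paste(utils::head(orphans, 10), collapse = ", "))
  fm <- frames_meta[match(annotations$frame_id, frames_meta$frame_id), ]
  key <- paste(annotations$frame_id, annotations$rater_id,
               annotations$reading_index, sep = "\r")
  groups <- split(seq_len(nrow(annotations)), key)
  rows <- lapply(groups, function(ix) {
    a <- annotations[ix, , drop = FALSE]
    d <- compute_dimensions(a, fm$pixel_spacing_row_mm[ix[1]],
                            fm$pixel_spacing_col_mm[ix[1]])
    data.frame(frame_id = a$frame_id[1], rater_id = a$rater_id[1],
               reading_index = a$reading_index[1], phase = fm$phase[ix[1]],
               ivs_mm = d[["ivs_mm"]], lvid_mm = d[["lvid_mm"]],
               pw_mm = d[["pw_mm"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$frame_id, out$rater_id, out$reading_index), ]
}
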