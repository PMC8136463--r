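#' Phantom generator configuration
#'
#' Describes the synthetic PLAX-like study: image raster, pixel spacing,
#' and the population distributions of the three LV dimensions.  Dimension
#' defaults are the validation-population values: LVIDd 47.0 (SD 6.4) mm,
#' LVIDs 37.7 (SD 7.3) mm, diastolic septum 11.7 (SD 2.4) mm and diastolic
#' posterior wall 11.0 (SD 1.6) mm.  Systolic wall thicknesses are not
#' separately specified for the population, so the diastolic draws are
#' scaled by `systolic_wall_scale` (default 1.3, ordinary systolic wall
#' thickening).
#'
#' @param image_height_px,image_width_px raster size in pixels.
#' @param pixel_spacing_row_mm,pixel_spacing_col_mm physical size of one
#'   pixel along rows (y) and columns (x), mm.
#' @param lvid_d_mean_mm,lvid_d_sd_mm,lvid_s_mean_mm,lvid_s_sd_mm,ivsd_mean_mm,ivsd_sd_mm,pwd_mean_mm,pwd_sd_mm
#'   population mean/SD of each dimension, mm.
#' @param systolic_wall_scale multiplicative systolic thickening applied to
#'   the diastolic wall draws.
#' @param axis_angle_deg_range interval (degrees) from which the
#'   measurement-axis tilt away from the image vertical is drawn.
#' @param band_halfwidth_mm lateral half-width of the rendered wall/cavity
#'   bands, mm.
#' @param speckle_noise_sd SD of the additive intensity noise (image is
#'   clipped back to \[0, 1\]).
#' @param n_studies number of studies; each contributes one end-diastolic
#'   and one end-systolic frame.
#' @return a list of class `phantom_config`.
#' @export
phantom_config <- function(image_height_px = 320L,
                           image_width_px = 320L,
                           pixel_spacing_row_mm = 0.5,
                           pixel_spacing_col_mm = 0.5,
                           lvid_d_mean_mm = 47.0, lvid_d_sd_mm = 6.4,
                           lvid_s_mean_mm = 37.7, lvid_s_sd_mm = 7.3,
                           ivsd_mean_mm = 11.7, ivsd_sd_mm = 2.4,
                           pwd_mean_mm = 11.0, pwd_sd_mm = 1.6,
                           systolic_wall_scale = 1.3,
                           axis_angle_deg_range = c(-20, 20),
                           band_halfwidth_mm = 25,
                           speckle_noise_sd = 0.05,
                           n_studies = 100L) {
  cfg <- list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    pixel_spacing_row_mm = pixel_spacing_row_mm,
    pixel_spacing_col_mm = pixel_spacing_col_mm,
    lvid_d_mean_mm = lvid_d_mean_mm, lvid_d_sd_mm = lvid_d_sd_mm,
    lvid_s_mean_mm = lvid_s_mean_mm, lvid_s_sd_mm = lvid_s_sd_mm,
    ivsd_mean_mm = ivsd_mean_mm, ivsd_sd_mm = ivsd_sd_mm,
    pwd_mean_mm = pwd_mean_mm, pwd_sd_mm = pwd_sd_mm,
    systolic_wall_scale = systolic_wall_scale,
    axis_angle_deg_range = as.numeric(axis_angle_deg_range),
    band_halfwidth_mm = band_halfwidth_mm,
    speckle_noise_sd = speckle_noise_sd,
    n_studies = as.integer(n_studies)
  )
  with(cfg, {
    if (image_height_px < 1L || image_width_px < 1L)
      .stopf("image dimensions must be positive")
    if (pixel_spacing_row_mm <= 0 || pixel_spacing_col_mm <= 0)
      .stopf("pixel spacings must be positive")
    sds <- c(lvid_d_sd_mm, lvid_s_sd_mm, ivsd_sd_mm, pwd_sd_mm,
             speckle_noise_sd)
    if (any(sds < 0)) .stopf("all SDs must be nonnegative")
    if (n_studies < 1L) .stopf("n_studies must be >= 1")
    if (length(axis_angle_deg_range) != 2L ||
        diff(axis_angle_deg_range) < 0)
      .stopf("axis_angle_deg_range must be an interval c(lo, hi)")
  })
  structure(cfg, class = "phantom_config")
}

# normal draw truncated at > 0 (resample)
.rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Sample per-study true dimensions
#'
#' Draws each study's true dimensions from the configured population
#' distributions, truncated at positive values; the systolic internal
#' diameter is resampled until it is smaller than the diastolic one.
#'
#' @param config a [phantom_config()].
#' @param n_studies number of studies (defaults to `config$n_studies`).
#' @param seed integer seed.
#' @return data frame with one row per study and columns `study_id`,
#'   `ivs_ED`, `lvid_ED`, `pw_ED`, `ivs_ES`, `lvid_ES`, `pw_ES` (mm).
#' @export
sample_study_dimensions <- function(config, n_studies = config$n_studies,
                                    seed = 1L) {
  set.seed(seed)
  n <- n_studies
  lvid_d <- .rnorm_pos(n, config$lvid_d_mean_mm, config$lvid_d_sd_mm)
  lvid_s <- .rnorm_pos(n, config$lvid_s_mean_mm, config$lvid_s_sd_mm)
  while (any(bad <- lvid_s >= lvid_d)) {
    lvid_s[bad] <- .rnorm_pos(sum(bad), config$lvid_s_mean_mm,
                              config$lvid_s_sd_mm)
  }
  ivs_d <- .rnorm_pos(n, config$ivsd_mean_mm, config$ivsd_sd_mm)
  pw_d <- .rnorm_pos(n, config$pwd_mean_mm, config$pwd_sd_mm)
  data.frame(
    study_id = sprintf("study%03d", seq_len(n)),
    ivs_ED = ivs_d, lvid_ED = lvid_d, pw_ED = pw_d,
    ivs_ES = ivs_d * config$systolic_wall_scale,
    lvid_ES = lvid_s,
    pw_ES = pw_d * config$systolic_wall_scale,
    stringsAsFactors = FALSE
  )
}

#' Render one synthetic PLAX-like frame with known keypoints
#'
#' Renders a deliberately simple phantom: two bright myocardial bands
#' (septum and posterior wall) separated by a dark cavity, oriented along
#' a measurement axis tilted by an angle drawn from
#' `config$axis_angle_deg_range`, plus additive speckle-like noise.  The
#' four ground-truth keypoints sit at the band boundaries along the
#' measurement axis, centred in the image, so the rendered geometry
#' realises exactly the requested IVS/LVID/PW.
#'
#' @param config a [phantom_config()].
#' @param dims_mm named numeric vector `c(ivs=, lvid=, pw=)`, mm.
#' @param phase `"ED"` or `"ES"`.
#' @param seed integer seed (axis angle and speckle noise).
#' @param frame_id,study_id identifiers stored in the frame.
#' @return an object of class `echo_frame`: a list with `frame_id`,
#'   `study_id`, `video_id`, `phase`, `image` (rows x cols matrix in
#'   \[0,1\]), `pixel_spacing_row_mm`, `pixel_spacing_col_mm`, `truth`
#'   (data frame `keypoint_name`, `x_px`, `y_px`, `missing`), `dims_mm`
#'   and `axis_angle_deg`.
#' @export
generate_phantom_frame <- function(config, dims_mm, phase = c("ED", "ES"),
                                   seed = 1L, frame_id = "frame001",
                                   study_id = "study001") {
  phase <- match.arg(phase)
  stopifnot(all(c("ivs", "lvid", "pw") %in% names(dims_mm)))
  dims_mm <- dims_mm[c("ivs", "lvid", "pw")]
  if (any(dims_mm <= 0)) .stopf("all requested dimensions must be positive")
  set.seed(seed)
  theta <- stats::runif(1, config$axis_angle_deg_range[1],
                        config$axis_angle_deg_range[2]) * pi / 180
  u <- c(sin(theta), cos(theta))          # (x, y), y increases downwards
  H <- config$image_height_px
  W <- config$image_width_px
  rsp <- config$pixel_spacing_row_mm
  csp <- config$pixel_spacing_col_mm
  ctr <- c((W - 1) / 2 * csp, (H - 1) / 2 * rsp)
  total <- sum(dims_mm)
  anchor <- ctr - u * total / 2            # sept_ant, mm
  offsets <- cumsum(c(0, dims_mm))
  pts_mm <- t(vapply(offsets, function(s) anchor + u * s, numeric(2)))
  truth <- data.frame(
    keypoint_name = keypoint_names(),
    x_px = pts_mm[, 1] / csp,
    y_px = pts_mm[, 2] / rsp,
    missing = FALSE,
    stringsAsFactors = FALSE
  )
  margin <- 2
  out_x <- truth$x_px < margin | truth$x_px > W - 1 - margin
  out_y <- truth$y_px < margin | truth$y_px > H - 1 - margin
  if (any(out_x | out_y)) {
    worst <- names(dims_mm)[which.max(dims_mm)]
    .stopf(paste0("rendered ventricle exceeds image bounds: total axis ",
                  "extent %.1f mm does not fit a %dx%d px image at ",
                  "(%.3g, %.3g) mm/px; largest offending dimension is ",
                  "'%s' = %.1f mm"),
           total, H, W, rsp, csp, worst, dims_mm[[worst]])
  }

  xs <- (0:(W - 1)) * csp
  ys <- (0:(H - 1)) * rsp
  X <- matrix(xs, H, W, byrow = TRUE)
  Y <- matrix(ys, H, W)
  S <- (X - anchor[1]) * u[1] + (Y - anchor[2]) * u[2]   # along axis
  Tc <- (X - anchor[1]) * u[2] - (Y - anchor[2]) * u[1]  # lateral
  inband <- abs(Tc) <= config$band_halfwidth_mm
  img <- matrix(0.25, H, W)
  wall <- inband & ((S >= 0 & S <= dims_mm["ivs"]) |
                    (S >= dims_mm["ivs"] + dims_mm["lvid"] & S <= total))
  cavity <- inband & S > dims_mm["ivs"] &
    S < dims_mm["ivs"] + dims_mm["lvid"]
  img[wall] <- 0.85
  img[cavity] <- 0.05
  if (config$speckle_noise_sd > 0) {
    img <- img + matrix(stats::rnorm(H * W, 0, config$speckle_noise_sd),
                        H, W)
  }
  img[img < 0] <- 0
  img[img > 1] <- 1

  structure(list(
    frame_id = frame_id, study_id = study_id, video_id = study_id,
    phase = phase, image = img,
    pixel_spacing_row_mm = rsp, pixel_spacing_col_mm = csp,
    truth = truth, dims_mm = dims_mm,
    axis_angle_deg = theta * 180 / pi
  ), class = "echo_frame")
}

#' @export
print.echo_frame <- function(x, ...) {
  cat(sprintf("<echo_frame %s (%s, %s): %dx%d px, %.3g/%.3g mm/px>\n",
              x$frame_id, x$study_id, x$phase,
              nrow(x$image), ncol(x$image),
              x$pixel_spacing_row_mm, x$pixel_spacing_col_mm))
  invisible(x)
}
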