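# Shared fixtures, all generated in code.

# a small, fast study configuration (noise presets unchanged)
small_study_config <- function(n_studies = 3L, n_experts = 5L, ...) {
  study_config(
    phantom = phantom_config(n_studies = n_studies,
                             speckle_noise_sd = 0.02),
    n_experts = n_experts, write_images = FALSE, ...)
}

noiseless_study_config <- function(n_studies = 3L, n_experts = 5L) {
  study_config(
    phantom = phantom_config(n_studies = n_studies, speckle_noise_sd = 0),
    n_experts = n_experts,
    expert_template = rater_model("expert"),
    ai_model = rater_model("ai"),
    write_images = FALSE)
}

simple_frame <- function(lvid = 47, ivs = 11.7, pw = 11, angle = c(0, 0),
                         seed = 1L, spacing = 0.5) {
  cfg <- phantom_config(axis_angle_deg_range = angle,
                        speckle_noise_sd = 0,
                        pixel_spacing_row_mm = spacing,
                        pixel_spacing_col_mm = spacing)
  generate_phantom_frame(cfg, c(ivs = ivs, lvid = lvid, pw = pw), "ED",
                         seed = seed)
}

keypoint_df <- function(xs, ys, missing = rep(FALSE, 4)) {
  data.frame(keypoint_name = keypoint_names(), x_px = xs, y_px = ys,
             missing = missing, stringsAsFactors = FALSE)
}

# minimal explicit-VR little-endian DICOM writer, built directly from the
# encoding rules so it is independent of the reader under test
write_minimal_dicom <- function(path, pixel_spacing = c(0.5, 0.25),
                                include_spacing = TRUE) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  put_short <- function(group, elem, vr, value) {
    writeBin(as.raw(c(bitwAnd(group, 255), bitwShiftR(group, 8),
                      bitwAnd(elem, 255), bitwShiftR(elem, 8))), con)
    writeBin(charToRaw(vr), con)
    v <- charToRaw(value)
    if (length(v) %% 2 == 1) v <- c(v, charToRaw(" "))
    writeBin(as.raw(c(length(v) %% 256, length(v) %/% 256)), con)
    writeBin(v, con)
  }
  put_short(0x0008, 0x0060, "CS", "US")
  put_short(0x0010, 0x0010, "PN", "PHANTOM^SYNTHETIC")
  if (include_spacing) {
    put_short(0x0028, 0x0030, "DS",
              paste(format(pixel_spacing), collapse = "\\"))
  }
  put_short(0x0028, 0x0100, "US", "")
  invisible(path)
}
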