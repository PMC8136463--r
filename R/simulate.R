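#' Simulated rater (expert or AI) noise model
#'
#' Keypoint placement error is modelled in physical (mm) space, in the
#' frame of each keypoint's own measurement line: a component along the
#' measurement direction ("transverse", it changes the measured dimension)
#' and a component perpendicular to it ("longitudinal", sliding along the
#' myocardium).  Both SDs are expressed as fractions of the true line
#' length, matching how multi-reader keypoint scatter is reported, and
#' longitudinal scatter is typically much larger than transverse.
#' `bias_mm` is a systematic measurement-lengthening offset: each keypoint
#' is shifted outward along its own line by `bias_mm / 2` (line starts
#' move backwards, line ends forwards), so a positive bias lengthens the
#' measurement by `bias_mm`.
#'
#' @param rater_id identifier.
#' @param longitudinal_sd_frac SD of the error along the myocardium
#'   (perpendicular to the measurement line), as a fraction of line length.
#' @param transverse_sd_frac SD of the error along the measurement
#'   direction, as a fraction of line length.
#' @param bias_mm systematic offset, mm (see above).
#' @param miss_prob probability that any one keypoint of any one reading
#'   is left unannotated, independently.
#' @return a list of class `rater_model`.
#' @export
rater_model <- function(rater_id, longitudinal_sd_frac = 0,
                        transverse_sd_frac = 0, bias_mm = 0,
                        miss_prob = 0) {
  if (longitudinal_sd_frac < 0 || transverse_sd_frac < 0)
    .stopf("noise SD fractions must be nonnegative")
  if (miss_prob < 0 || miss_prob > 1)
    .stopf("miss_prob must lie in [0, 1]")
  structure(list(rater_id = as.character(rater_id),
                 longitudinal_sd_frac = longitudinal_sd_frac,
                 transverse_sd_frac = transverse_sd_frac,
                 bias_mm = bias_mm, miss_prob = miss_prob),
            class = "rater_model")
}

# true measurement lines of a frame, in mm space: named list of line_frame
.truth_lines_mm <- function(frame) {
  tr <- frame$truth
  p_mm <- function(name) {
    i <- match(name, tr$keypoint_name)
    c(tr$x_px[i] * frame$pixel_spacing_col_mm,
      tr$y_px[i] * frame$pixel_spacing_row_mm)
  }
  dl <- dimension_lines()
  out <- lapply(seq_len(nrow(dl)), function(i) {
    line_frame(p_mm(dl$start[i]), p_mm(dl$end[i]))
  })
  names(out) <- dl$dimension
  out
}

#' Simulate one rater's blinded readings of a frame
#'
#' Each reading displaces every ground-truth keypoint independently:
#' Gaussian noise with SD `transverse_sd_frac * L` along the keypoint's
#' measurement line and `longitudinal_sd_frac * L` perpendicular to it
#' (`L` = true length of that keypoint's line, mm), plus the systematic
#' `bias_mm` half-shift, all in mm space and converted back to pixels.
#' Each keypoint is independently flagged missing with probability
#' `miss_prob`.  Readings are mutually independent, emulating raters
#' blinded to any previous labelling.
#'
#' @param frame an `echo_frame` with ground truth.
#' @param rater a [rater_model()].
#' @param n_readings number of independent readings.
#' @param seed integer seed.
#' @return data frame in annotation-table form: `frame_id`, `rater_id`,
#'   `reading_index`, `keypoint_name`, `x_px`, `y_px`, `missing`.
#' @export
simulate_rater_annotations <- function(frame, rater, n_readings = 2L,
                                       seed = 1L) {
  if (is.null(frame$truth)) .stopf("frame has no ground truth")
  if (n_readings < 1L) .stopf("n_readings must be >= 1")
  set.seed(seed)
  lines <- .truth_lines_mm(frame)
  kp <- keypoint_names()
  tr <- frame$truth
  csp <- frame$pixel_spacing_col_mm
  rsp <- frame$pixel_spacing_row_mm
  rows <- vector("list", n_readings * length(kp))
  n <- 0L
  for (r in seq_len(n_readings)) {
    for (k in kp) {
      lf <- lines[[.kp_noise_line[[k]]]]
      L <- lf$length_mm
      t_err <- .kp_noise_role[[k]] * rater$bias_mm / 2 +
        stats::rnorm(1, 0, rater$transverse_sd_frac * L)
      l_err <- stats::rnorm(1, 0, rater$longitudinal_sd_frac * L)
      miss <- stats::runif(1) < rater$miss_prob
      i <- match(k, tr$keypoint_name)
      p_mm <- c(tr$x_px[i] * csp, tr$y_px[i] * rsp) +
        t_err * lf$unit_along + l_err * lf$unit_perp
      n <- n + 1L
      rows[[n]] <- data.frame(
        frame_id = frame$frame_id, rater_id = rater$rater_id,
        reading_index = r, keypoint_name = k,
        x_px = if (miss) NA_real_ else p_mm[1] / csp,
        y_px = if (miss) NA_real_ else p_mm[2] / rsp,
        missing = miss, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' @describeIn simulate_rater_annotations single-reading convenience for an
#'   automated (AI) rater.
#' @param ai_model a [rater_model()] for the automated rater.
#' @export
simulate_ai_annotations <- function(frame, ai_model, seed = 1L) {
  simulate_rater_annotations(frame, ai_model, n_readings = 1L, seed = seed)
}

#' Validation-study configuration
#'
#' Bundles the phantom configuration with the reader panel: by default 13
#' experts reading every frame twice, blinded, plus one AI rater reading
#' once — i.e. 26 expert evaluations and one AI evaluation per frame, and
#' 100 studies contributing one end-diastolic and one end-systolic frame
#' each (200 frames).  Default noise presets: experts 20% longitudinal /
#' 10% transverse of line length with 2% missingness; AI 15% / 7% with
#' none.
#'
#' @param phantom a [phantom_config()].
#' @param n_experts number of experts.
#' @param n_readings blinded readings per expert per frame.
#' @param expert_template a [rater_model()] whose noise parameters are
#'   given to every expert (ids are assigned `expert01`, ...).
#' @param ai_model a [rater_model()] for the AI rater.
#' @param write_images whether [generate_validation_study()] writes PNGs.
#' @return a list of class `study_config`.
#' @export
study_config <- function(phantom = phantom_config(),
                         n_experts = 13L, n_readings = 2L,
                         expert_template = rater_model(
                           "expert", longitudinal_sd_frac = 0.20,
                           transverse_sd_frac = 0.10, miss_prob = 0.02),
                         ai_model = rater_model(
                           "ai", longitudinal_sd_frac = 0.15,
                           transverse_sd_frac = 0.07),
                         write_images = TRUE) {
  if (n_experts < 1L) .stopf("n_experts must be >= 1")
  structure(list(phantom = phantom, n_experts = as.integer(n_experts),
                 n_readings = as.integer(n_readings),
                 expert_template = expert_template, ai_model = ai_model,
                 write_images = isTRUE(write_images)),
            class = "study_config")
}

# in-memory synthesis of the whole study; returns frames list + tables
.synthesize_study <- function(config, seed) {
  ph <- config$phantom
  dims <- sample_study_dimensions(ph, seed = .derive_seed(seed, 0))
  experts <- lapply(seq_len(config$n_experts), function(e) {
    m <- config$expert_template
    m$rater_id <- sprintf("expert%02d", e)
    m
  })
  frames <- list()
  ann <- list()
  truth <- list()
  fi <- 0L
  for (s in seq_len(nrow(dims))) {
    for (phase in c("ED", "ES")) {
      fi <- fi + 1L
      d <- c(ivs = dims[[paste0("ivs_", phase)]][s],
             lvid = dims[[paste0("lvid_", phase)]][s],
             pw = dims[[paste0("pw_", phase)]][s])
      fid <- sprintf("frame%03d_%s", s, phase)
      fr <- generate_phantom_frame(ph, d, phase,
                                   seed = .derive_seed(seed, fi),
                                   frame_id = fid,
                                   study_id = dims$study_id[s])
      frames[[fi]] <- fr
      truth[[fi]] <- cbind(frame_id = fid, fr$truth,
                           stringsAsFactors = FALSE)
      a <- lapply(seq_along(experts), function(e) {
        simulate_rater_annotations(fr, experts[[e]], config$n_readings,
                                   seed = .derive_seed(seed, fi, e))
      })
      a[[length(a) + 1L]] <- simulate_ai_annotations(
        fr, config$ai_model, seed = .derive_seed(seed, fi, 9999))
      ann[[fi]] <- do.call(rbind, a)
    }
  }
  frames_meta <- do.call(rbind, lapply(frames, function(f) data.frame(
    frame_id = f$frame_id, study_id = f$study_id, video_id = f$video_id,
    phase = f$phase,
    pixel_spacing_row_mm = f$pixel_spacing_row_mm,
    pixel_spacing_col_mm = f$pixel_spacing_col_mm,
    stringsAsFactors = FALSE
  )))
  list(frames = frames, frames_meta = frames_meta,
       truth = do.call(rbind, truth),
       annotations = do.call(rbind, ann),
       expert_ids = vapply(experts, `[[`, "", "rater_id"),
       ai_id = config$ai_model$rater_id)
}

#' Generate a complete synthetic validation study on disk
#'
#' Writes, under `out_dir`: `frames/<frame_id>.png` (8-bit grayscale,
#' unless `write_images` is off), `frames.csv`, `truth.csv`,
#' `annotations.csv` and `manifest.json` (configuration, seed, row
#' counts).  The default configuration yields 100 studies, 200 frames,
#' and per frame 26 expert evaluations (13 experts x 2 blinded readings)
#' plus one AI reading.
#'
#' @param config a [study_config()].
#' @param seed integer seed; recorded in the manifest.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the in-memory tables (`frames_meta`, `truth`,
#'   `annotations`, `expert_ids`, `ai_id`).
#' @export
generate_validation_study <- function(config = study_config(), seed = 1L,
                                      out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    .stopf("cannot create output directory '%s'", out_dir)
  syn <- .synthesize_study(config, seed)
  if (config$write_images) {
    fdir <- file.path(out_dir, "frames")
    dir.create(fdir, showWarnings = FALSE)
    for (f in syn$frames) {
      png::writePNG(f$image, file.path(fdir, paste0(f$frame_id, ".png")))
    }
  }
  utils::write.csv(syn$frames_meta, file.path(out_dir, "frames.csv"),
                   row.names = FALSE)
  utils::write.csv(syn$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  utils::write.csv(syn$annotations, file.path(out_dir, "annotations.csv"),
                   row.names = FALSE)
  manifest <- list(
    seed = seed,
    n_studies = config$phantom$n_studies,
    n_experts = config$n_experts,
    n_readings = config$n_readings,
    expert_model = unclass(config$expert_template),
    ai_model = unclass(config$ai_model),
    phantom = unclass(config$phantom),
    n_frames = nrow(syn$frames_meta),
    n_annotation_rows = nrow(syn$annotations)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(syn[c("frames_meta", "truth", "annotations", "expert_ids",
                  "ai_id")])
}

#' Split frames into training and progress-monitoring sets by video
#'
#' Frames from one video must never appear in both partitions.  Whole
#' (shuffled) videos are assigned greedily to the training partition while
#' it stays within `floor(train_frac * N)` frames; every other video goes
#' to progress monitoring.  With one frame per video and `train_frac`
#' 0.8, 1894 frames split into exactly 1515 training and 379
#' progress-monitoring frames.
#'
#' @param frames data frame with columns `frame_id` and `video_id`.
#' @param train_frac target training fraction of frames.
#' @param seed integer seed for the video shuffle.
#' @return list with `train_frames`, `progress_frames` (frame ids) and
#'   `train_videos`, `progress_videos`.
#' @export
grouped_train_split <- function(frames, train_frac = 0.8, seed = 1L) {
  .check_cols(frames, c("frame_id", "video_id"), "frames")
  vids <- unique(frames$video_id)
  if (length(vids) < 2L)
    .stopf("need at least 2 videos to split; got %d", length(vids))
  set.seed(seed)
  vids <- sample(vids)
  sizes <- table(frames$video_id)[vids]
  budget <- floor(train_frac * nrow(frames))
  train_v <- character(0)
  used <- 0L
  for (v in vids) {
    if (used + sizes[[v]] <= budget) {
      train_v <- c(train_v, v)
      used <- used + sizes[[v]]
    }
  }
  prog_v <- setdiff(vids, train_v)
  list(train_frames = frames$frame_id[frames$video_id %in% train_v],
       progress_frames = frames$frame_id[frames$video_id %in% prog_v],
       train_videos = train_v, progress_videos = prog_v)
}
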