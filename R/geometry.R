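#' Orthonormal frame of a measurement line
#'
#' The frame in which keypoint deviations are decomposed: `unit_along`
#' points from the line start to its end (for the LVID, from the
#' posterior septum towards the posterior wall), and `unit_perp` is
#' `unit_along` rotated by +90 degrees in image orientation (y axis
#' pointing down), i.e. `unit_perp = (u_y, -u_x)`.
#'
#' @param start,end numeric `c(x, y)` endpoints in mm space.
#' @return list of class `line_frame` with `start_mm`, `end_mm`,
#'   `length_mm`, `unit_along`, `unit_perp`.
#' @export
line_frame <- function(start, end) {
  d <- end - start
  len <- sqrt(sum(d^2))
  if (len == 0) .stopf("line endpoints coincide")
  ua <- d / len
  structure(list(start_mm = start, end_mm = end, length_mm = len,
                 unit_along = ua, unit_perp = c(ua[2], -ua[1])),
            class = "line_frame")
}

#' Decompose a keypoint deviation against a consensus line
#'
#' Expresses the deviation of an observed keypoint from its consensus
#' location in the consensus measurement line's frame, normalised by line
#' length — equivalent to rotating and rescaling the image so the
#' consensus line is vertical with length 1.  `transverse_frac` is the
#' component along the measurement direction (it perturbs the measured
#' dimension); `longitudinal_frac` is the perpendicular component (a slide
#' along the myocardium that barely affects the dimension).
#'
#' @param observed,consensus numeric `c(x, y)` in mm space.
#' @param frame a [line_frame()].
#' @return named numeric `c(transverse_frac, longitudinal_frac)`.
#' @export
decompose_deviation <- function(observed, consensus, frame) {
  d <- observed - consensus
  c(transverse_frac = sum(d * frame$unit_along) / frame$length_mm,
    longitudinal_frac = sum(d * frame$unit_perp) / frame$length_mm)
}

# per-rater coordinate-wise median position of each keypoint, mm space
.per_rater_keypoints_mm <- function(ann, rsp, csp) {
  ok <- !ann$missing & !is.na(ann$x_px)
  a <- ann[ok, , drop = FALSE]
  if (!nrow(a)) return(a[0, c("rater_id", "keypoint_name")])
  key <- interaction(a$rater_id, a$keypoint_name, drop = TRUE)
  xs <- tapply(a$x_px * csp, key, stats::median)
  ys <- tapply(a$y_px * rsp, key, stats::median)
  ids <- do.call(rbind, strsplit(names(xs), ".", fixed = TRUE))
  data.frame(rater_id = ids[, 1], keypoint_name = ids[, 2],
             x_mm = as.numeric(xs), y_mm = as.numeric(ys),
             stringsAsFactors = FALSE)
}

#' Consensus keypoint locations for one frame
#'
#' For each keypoint, takes the coordinate-wise median (x and y
#' separately, in mm space) of each expert's per-expert median position,
#' then the coordinate-wise median across experts.  A keypoint is missing
#' when fewer than `min_experts` experts contribute.
#'
#' @param annotations annotation rows for one frame (columns `rater_id`,
#'   `reading_index`, `keypoint_name`, `x_px`, `y_px`, `missing`),
#'   restricted to the raters that define the consensus.
#' @param pixel_spacing_row_mm,pixel_spacing_col_mm mm per pixel.
#' @param min_experts minimum contributing experts per keypoint.
#' @return data frame `keypoint_name`, `x_mm`, `y_mm`, `n_experts`,
#'   `missing`.
#' @export
consensus_keypoints <- function(annotations, pixel_spacing_row_mm,
                                pixel_spacing_col_mm, min_experts = 3L) {
  per <- .per_rater_keypoints_mm(annotations, pixel_spacing_row_mm,
                                 pixel_spacing_col_mm)
  out <- data.frame(keypoint_name = keypoint_names(), x_mm = NA_real_,
                    y_mm = NA_real_, n_experts = 0L, missing = TRUE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    p <- per[per$keypoint_name == out$keypoint_name[i], , drop = FALSE]
    out$n_experts[i] <- nrow(p)
    if (nrow(p) >= min_experts) {
      out$x_mm[i] <- stats::median(p$x_mm)
      out$y_mm[i] <- stats::median(p$y_mm)
      out$missing[i] <- FALSE
    }
  }
  out
}

#' Decompose every annotated keypoint of a study against consensus lines
#'
#' For each frame, builds the expert-consensus keypoints (optionally
#' leave-one-out for the rater being evaluated), forms the consensus line
#' of each measurement, and decomposes every reading's keypoints against
#' the line(s) of the measurement(s) they define — LVID endpoints against
#' the LVID line, septal points against the IVS line, posterior-wall
#' points against the PW line.  A keypoint shared by two measurements
#' (e.g. the posterior septum) yields one row per measurement.
#'
#' @param annotations full annotation table.
#' @param frames_meta frame metadata (`frame_id`, `phase`, pixel
#'   spacings).
#' @param expert_ids rater ids defining the consensus.
#' @param min_experts minimum experts per consensus keypoint.
#' @param leave_one_out when `TRUE`, an expert's deviations are taken
#'   against a consensus excluding that expert.
#' @return data frame `frame_id`, `method_id`, `reading_index`,
#'   `keypoint_name`, `dimension`, `point_end` (`"anterior"` for the line
#'   start, `"posterior"` for its end), `phase`, `transverse_frac`,
#'   `longitudinal_frac`.
#' @export
decompose_annotations <- function(annotations, frames_meta, expert_ids,
                                  min_experts = 3L,
                                  leave_one_out = FALSE) {
  .check_cols(annotations, c("frame_id", "rater_id", "reading_index",
                             "keypoint_name", "x_px", "y_px", "missing"),
              "annotations")
  .check_cols(frames_meta, c("frame_id", "phase", "pixel_spacing_row_mm",
                             "pixel_spacing_col_mm"), "frames_meta")
  dl <- dimension_lines()
  res <- vector("list", nrow(frames_meta))
  for (fi in seq_len(nrow(frames_meta))) {
    fid <- frames_meta$frame_id[fi]
    rsp <- frames_meta$pixel_spacing_row_mm[fi]
    csp <- frames_meta$pixel_spacing_col_mm[fi]
    phase <- frames_meta$phase[fi]
    fann <- annotations[annotations$frame_id == fid, , drop = FALSE]
    eann <- fann[fann$rater_id %in% expert_ids, , drop = FALSE]
    cons_all <- consensus_keypoints(eann, rsp, csp, min_experts)
    cons_for <- function(method) {
      if (leave_one_out && method %in% expert_ids) {
        consensus_keypoints(eann[eann$rater_id != method, , drop = FALSE],
                            rsp, csp, min_experts)
      } else cons_all
    }
    cpt <- function(cons, k) {
      i <- match(k, cons$keypoint_name)
      if (cons$missing[i]) NULL else c(cons$x_mm[i], cons$y_mm[i])
    }
    rows <- list()
    for (method in unique(fann$rater_id)) {
      cons <- cons_for(method)
      mann <- fann[fann$rater_id == method, , drop = FALSE]
      for (li in seq_len(nrow(dl))) {
        p0 <- cpt(cons, dl$start[li])
        p1 <- cpt(cons, dl$end[li])
        if (is.null(p0) || is.null(p1) || all(p0 == p1)) next
        lf <- line_frame(p0, p1)
        for (pe in c("anterior", "posterior")) {
          k <- if (pe == "anterior") dl$start[li] else dl$end[li]
          ck <- cpt(cons, k)
          obs <- mann[mann$keypoint_name == k & !mann$missing, ,
                      drop = FALSE]
          if (!nrow(obs)) next
          for (oi in seq_len(nrow(obs))) {
            dec <- decompose_deviation(
              c(obs$x_px[oi] * csp, obs$y_px[oi] * rsp), ck, lf)
            rows[[length(rows) + 1L]] <- data.frame(
              frame_id = fid, method_id = method,
              reading_index = obs$reading_index[oi],
              keypoint_name = k, dimension = dl$dimension[li],
              point_end = pe, phase = phase,
              transverse_frac = dec[["transverse_frac"]],
              longitudinal_frac = dec[["longitudinal_frac"]],
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    res[[fi]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summarise decomposed keypoint scatter
#'
#' Per stratum — method, measurement, phase (ED, ES and pooled) and point
#' end (anterior, posterior and pooled) — reports the SD of the
#' transverse and longitudinal fractions in percent of line length, with
#' a variance-ratio F test of longitudinal against transverse scatter.
#' A second table compares posterior- against anterior-point scatter per
#' component.  Strata with fewer than 2 rows are marked unavailable
#' (`NA` statistics).
#'
#' @param decomp output of [decompose_annotations()] (optionally with
#'   `method_id` recoded, e.g. experts pooled).
#' @param alpha significance threshold recorded alongside the tests.
#' @return list with data frames `summary` and `tests`.
#' @export
decomposition_summary <- function(decomp, alpha = 0.05) {
  .check_cols(decomp, c("method_id", "dimension", "phase", "point_end",
                        "transverse_frac", "longitudinal_frac"), "decomp")
  phases <- c("ED", "ES", "pooled")
  ends <- c("anterior", "posterior", "pooled")
  combos <- expand.grid(method_id = unique(decomp$method_id),
                        dimension = unique(decomp$dimension),
                        phase = phases, point_end = ends,
                        stringsAsFactors = FALSE)
  pick <- function(m, d, ph, pe) {
    s <- decomp[decomp$method_id == m & decomp$dimension == d, ,
                drop = FALSE]
    if (ph != "pooled") s <- s[s$phase == ph, , drop = FALSE]
    if (pe != "pooled") s <- s[s$point_end == pe, , drop = FALSE]
    s
  }
  summ <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    s <- pick(combos$method_id[i], combos$dimension[i], combos$phase[i],
              combos$point_end[i])
    n <- nrow(s)
    if (n < 2L) {
      return(cbind(combos[i, ], n = n, sd_transverse_pct = NA_real_,
                   sd_longitudinal_pct = NA_real_,
                   f_long_vs_trans = NA_real_, p_long_vs_trans = NA_real_,
                   available = FALSE))
    }
    ft <- tryCatch(f_test_sd(s$longitudinal_frac, s$transverse_frac),
                   error = function(e) list(statistic = NA_real_,
                                            p_value = NA_real_))
    cbind(combos[i, ], n = n,
          sd_transverse_pct = 100 * stats::sd(s$transverse_frac),
          sd_longitudinal_pct = 100 * stats::sd(s$longitudinal_frac),
          f_long_vs_trans = ft$statistic, p_long_vs_trans = ft$p_value,
          available = TRUE)
  }))
  rownames(summ) <- NULL

  tcomb <- expand.grid(method_id = unique(decomp$method_id),
                       dimension = unique(decomp$dimension),
                       component = c("longitudinal", "transverse"),
                       stringsAsFactors = FALSE)
  tests <- do.call(rbind, lapply(seq_len(nrow(tcomb)), function(i) {
    col <- paste0(tcomb$component[i], "_frac")
    a <- pick(tcomb$method_id[i], tcomb$dimension[i], "pooled",
              "posterior")[[col]]
    b <- pick(tcomb$method_id[i], tcomb$dimension[i], "pooled",
              "anterior")[[col]]
    ft <- if (length(a) >= 2 && length(b) >= 2) {
      tryCatch(f_test_sd(a, b),
               error = function(e) list(statistic = NA_real_,
                                        p_value = NA_real_))
    } else list(statistic = NA_real_, p_value = NA_real_)
    data.frame(comparison = "posterior_vs_anterior",
               method_id = tcomb$method_id[i],
               dimension = tcomb$dimension[i],
               component = tcomb$component[i],
               statistic = ft$statistic, p_value = ft$p_value,
               alpha = alpha, stringsAsFactors = FALSE)
  }))
  list(summary = summ, tests = tests)
}
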