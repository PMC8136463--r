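#' One expert's measurement of one dimension on one frame
#'
#' The median of that expert's non-missing readings — with two blinded
#' readings this is their mean; with one reading available, that reading;
#' with none, missing.
#'
#' @param values numeric vector of the expert's readings (may contain
#'   `NA`).
#' @return a single mm value, or `NA` if no reading is available.
#' @export
per_expert_measurement <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) return(NA_real_)
  stats::median(v)
}

#' Per-expert measurement table
#'
#' Collapses a measurement table to one value per (frame, rater,
#' dimension) via [per_expert_measurement()].
#'
#' @param measurements output of [measurements_from_annotations()].
#' @return long data frame `frame_id`, `rater_id`, `phase`, `dimension`,
#'   `value_mm`.
#' @export
per_expert_measurements <- function(measurements) {
  .check_cols(measurements, c("frame_id", "rater_id", "phase", "ivs_mm",
                              "lvid_mm", "pw_mm"), "measurements")
  long <- do.call(rbind, lapply(c("ivs", "lvid", "pw"), function(d) {
    data.frame(frame_id = measurements$frame_id,
               rater_id = measurements$rater_id,
               phase = measurements$phase, dimension = d,
               value_mm = measurements[[paste0(d, "_mm")]],
               stringsAsFactors = FALSE)
  }))
  key <- interaction(long$frame_id, long$rater_id, long$dimension,
                     drop = TRUE)
  first <- !duplicated(key)
  out <- long[first, c("frame_id", "rater_id", "phase", "dimension")]
  out$value_mm <- as.numeric(
    tapply(long$value_mm, key, per_expert_measurement)[as.character(key[first])])
  rownames(out) <- NULL
  out
}

#' Consensus-of-experts reference measurements
#'
#' The reference standard for each dimension on each frame is the median
#' across experts of their per-expert measurements (even counts take the
#' mean of the middle two).  A reference is missing when fewer than
#' `min_experts` experts contribute.  `consensus = "pooled"` instead
#' takes the median of all expert readings pooled, the alternative
#' reading of a median-of-experts rule.  `exclude_rater` supports
#' leave-one-out sensitivity analysis.
#'
#' @param measurements measurement table
#'   ([measurements_from_annotations()]).
#' @param expert_ids rater ids that define the consensus.
#' @param min_experts minimum contributing experts per reference value.
#' @param consensus `"per_expert_median"` (default) or `"pooled"`.
#' @param exclude_rater optional rater id excluded from the consensus.
#' @return data frame `frame_id`, `phase`, `dimension`, `reference_mm`,
#'   `n_experts`.
#' @export
consensus_reference <- function(measurements, expert_ids,
                                min_experts = 3L,
                                consensus = c("per_expert_median",
                                              "pooled"),
                                exclude_rater = NULL) {
  consensus <- match.arg(consensus)
  ids <- setdiff(expert_ids, exclude_rater)
  em <- measurements[measurements$rater_id %in% ids, , drop = FALSE]
  per <- per_expert_measurements(em)
  key <- interaction(per$frame_id, per$dimension, drop = TRUE)
  first <- !duplicated(key)
  out <- per[first, c("frame_id", "phase", "dimension")]
  if (consensus == "per_expert_median") {
    agg_n <- tapply(!is.na(per$value_mm), key, sum)
    agg_v <- tapply(per$value_mm, key, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) stats::median(v) else NA_real_
    })
  } else {
    long <- do.call(rbind, lapply(c("ivs", "lvid", "pw"), function(d) {
      data.frame(frame_id = em$frame_id, rater_id = em$rater_id,
                 dimension = d, value_mm = em[[paste0(d, "_mm")]],
                 stringsAsFactors = FALSE)
    }))
    lkey <- interaction(long$frame_id, long$dimension, drop = TRUE)
    n_by_expert <- tapply(seq_len(nrow(long)), lkey, function(ix) {
      length(unique(long$rater_id[ix][!is.na(long$value_mm[ix])]))
    })
    v_pooled <- tapply(long$value_mm, lkey, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) stats::median(v) else NA_real_
    })
    k <- as.character(key[first])
    out$reference_mm <- as.numeric(v_pooled[k])
    out$n_experts <- as.integer(n_by_expert[k])
    out$reference_mm[out$n_experts < min_experts] <- NA_real_
    rownames(out) <- NULL
    return(out)
  }
  k <- as.character(key[first])
  out$reference_mm <- as.numeric(agg_v[k])
  out$n_experts <- as.integer(agg_n[k])
  out$reference_mm[out$n_experts < min_experts] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Signed deviations of a method's measurements from the reference
#'
#' One row per matched (frame, dimension): `signed_deviation_mm =
#' measurement_mm - reference_mm` (e.g. +2 mm when the method measures an
#' LVID of 41 mm against a 39 mm consensus).  Pairs with a missing
#' measurement or reference are excluded and counted in the
#' `"n_excluded"` attribute.
#'
#' @param method_measurements data frame `frame_id`, `phase`,
#'   `dimension`, `value_mm` — e.g. one rater's slice of
#'   [per_expert_measurements()].
#' @param references output of [consensus_reference()].
#' @param method_id label stored in the result.
#' @return a deviation table: `frame_id`, `method_id`, `phase`,
#'   `dimension`, `measurement_mm`, `reference_mm`,
#'   `signed_deviation_mm`; attribute `n_excluded`.
#' @export
signed_deviations <- function(method_measurements, references,
                              method_id = "method") {
  .check_cols(method_measurements, c("frame_id", "dimension", "value_mm"),
              "method_measurements")
  .check_cols(references, c("frame_id", "dimension", "reference_mm"),
              "references")
  m <- merge(method_measurements, references,
             by = c("frame_id", "dimension"),
             suffixes = c("", ".ref"))
  keep <- !is.na(m$value_mm) & !is.na(m$reference_mm)
  phase <- if ("phase" %in% names(m)) m$phase else
    if ("phase.ref" %in% names(m)) m$phase.ref else NA_character_
  out <- data.frame(frame_id = m$frame_id[keep], method_id = method_id,
                    phase = phase[keep], dimension = m$dimension[keep],
                    measurement_mm = m$value_mm[keep],
                    reference_mm = m$reference_mm[keep],
                    signed_deviation_mm = m$value_mm[keep] -
                      m$reference_mm[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$dimension, out$frame_id), ]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!keep)
  out
}
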