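#' Validation-run configuration
#'
#' Everything one analysis run needs: either `mode = "generate"` with a
#' [study_config()], or `mode = "load"` with paths to `frames.csv`,
#' `annotations.csv` (and optionally `truth.csv`) in the interchange
#' schema; plus the analysis flags and the seed, which is recorded in
#' every output.
#'
#' @param mode `"generate"` or `"load"`.
#' @param study a [study_config()] (generate mode).
#' @param frames_csv,annotations_csv input paths (load mode).
#' @param expert_ids expert rater ids (load mode; in generate mode they
#'   are known from the generator).  Every other rater is treated as a
#'   method under evaluation.
#' @param ai_id the AI rater id.
#' @param min_experts minimum experts behind any consensus value.
#' @param consensus `"per_expert_median"` or `"pooled"`.
#' @param leave_one_out evaluate each expert against a consensus that
#'   excludes them.
#' @param alpha significance threshold for the report's tests.
#' @param seed integer seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("generate", "load"),
                       study = study_config(),
                       frames_csv = NULL, annotations_csv = NULL,
                       expert_ids = NULL, ai_id = "ai",
                       min_experts = 3L,
                       consensus = c("per_expert_median", "pooled"),
                       leave_one_out = FALSE, alpha = 0.05, seed = 1L) {
  mode <- match.arg(mode)
  consensus <- match.arg(consensus)
  if (mode == "load" &&
      (is.null(frames_csv) || is.null(annotations_csv)))
    .stopf("load mode requires frames_csv and annotations_csv")
  structure(list(mode = mode, study = study, frames_csv = frames_csv,
                 annotations_csv = annotations_csv,
                 expert_ids = expert_ids, ai_id = ai_id,
                 min_experts = as.integer(min_experts),
                 consensus = consensus,
                 leave_one_out = isTRUE(leave_one_out), alpha = alpha,
                 seed = as.integer(seed)),
            class = "run_config")
}

.read_table_checked <- function(path, cols, what) {
  if (!file.exists(path)) .stopf("%s file '%s' not found", what, path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_cols(df, cols, what)
  df
}

#' Run the full validation analysis and write the report bundle
#'
#' Generates (or loads) a study, derives measurements, builds the
#' consensus reference, computes agreement statistics for the AI and for
#' every expert treated as an individual, decomposes keypoint errors
#' against the consensus measurement lines, and writes to `out_dir`:
#' `measurements.csv`, `agreement_summary.csv`, `tests.csv`,
#' `decomposition.csv`, `decomposition_summary.csv` and `manifest.json`
#' (configuration, seed, row/exclusion counts).  Reports in `tests.csv`:
#' per dimension, the AI's ED-vs-ES precision F test, the AI-vs-pooled
#' experts precision F test, the paired Wilcoxon of AI vs mean-expert
#' absolute error, and the decomposition comparisons.  Degenerate strata
#' (e.g. zero variance) yield `NA` statistics rather than failures.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return invisibly, a list with all tables.
#' @export
run_validation <- function(config, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    .stopf("cannot create output directory '%s'", out_dir)
  if (config$mode == "generate") {
    syn <- .synthesize_study(config$study, config$seed)
    frames_meta <- syn$frames_meta
    annotations <- syn$annotations
    expert_ids <- syn$expert_ids
    ai_id <- syn$ai_id
  } else {
    frames_meta <- .read_table_checked(
      config$frames_csv,
      c("frame_id", "phase", "pixel_spacing_row_mm",
        "pixel_spacing_col_mm"), "frames")
    annotations <- .read_table_checked(
      config$annotations_csv,
      c("frame_id", "rater_id", "reading_index", "keypoint_name",
        "x_px", "y_px", "missing"), "annotations")
    annotations$missing <- as.logical(annotations$missing) |
      is.na(annotations$x_px)
    orphans <- setdiff(unique(annotations$frame_id),
                       frames_meta$frame_id)
    if (length(orphans))
      .stopf("annotation frame id(s) missing from frames.csv: %s",
             paste(orphans, collapse = ", "))
    expert_ids <- config$expert_ids
    if (is.null(expert_ids))
      expert_ids <- setdiff(unique(annotations$rater_id), config$ai_id)
    ai_id <- config$ai_id
  }

  measurements <- measurements_from_annotations(annotations, frames_meta)
  per <- per_expert_measurements(measurements)
  refs <- consensus_reference(measurements, expert_ids,
                              min_experts = config$min_experts,
                              consensus = config$consensus)

  methods <- c(ai_id, expert_ids)
  dev_list <- lapply(methods, function(m) {
    r <- if (config$leave_one_out && m %in% expert_ids) {
      consensus_reference(measurements, expert_ids,
                          min_experts = config$min_experts,
                          consensus = config$consensus,
                          exclude_rater = m)
    } else refs
    mm <- per[per$rater_id == m,
              c("frame_id", "phase", "dimension", "value_mm")]
    signed_deviations(mm, r[, c("frame_id", "dimension", "reference_mm")],
                      method_id = m)
  })
  n_excluded <- sum(vapply(dev_list, attr, 0, "n_excluded"))
  deviations <- do.call(rbind, dev_list)
  summary_tbl <- stratified_summaries(deviations)

  safe <- function(expr) tryCatch(expr, error = function(e)
    list(statistic = NA_real_, p_value = NA_real_))
  test_rows <- list()
  add_test <- function(comparison, dimension, res) {
    test_rows[[length(test_rows) + 1L]] <<- data.frame(
      comparison = comparison, dimension = dimension,
      statistic = res$statistic, p_value = res$p_value,
      alpha = config$alpha, stringsAsFactors = FALSE)
  }
  ai_dev <- deviations[deviations$method_id == ai_id, , drop = FALSE]
  ex_dev <- deviations[deviations$method_id != ai_id, , drop = FALSE]
  for (d in unique(deviations$dimension)) {
    a <- ai_dev[ai_dev$dimension == d, , drop = FALSE]
    e <- ex_dev[ex_dev$dimension == d, , drop = FALSE]
    add_test("ai_precision_ED_vs_ES", d, safe(f_test_sd(
      a$signed_deviation_mm[a$phase == "ED"],
      a$signed_deviation_mm[a$phase == "ES"])))
    add_test("ai_vs_experts_precision", d, safe(f_test_sd(
      a$signed_deviation_mm, e$signed_deviation_mm)))
    expert_abs <- tapply(abs(e$signed_deviation_mm), e$frame_id, mean)
    ai_abs <- abs(a$signed_deviation_mm)[match(names(expert_abs),
                                               a$frame_id)]
    add_test("ai_vs_experts_abs_error_wilcoxon", d,
             safe(wilcoxon_abs_errors(ai_abs, as.numeric(expert_abs))))
  }

  decomp <- decompose_annotations(annotations, frames_meta, expert_ids,
                                  min_experts = config$min_experts,
                                  leave_one_out = config$leave_one_out)
  dpool <- decomp
  dpool$method_id <- ifelse(dpool$method_id %in% expert_ids, "experts",
                            dpool$method_id)
  dsum <- decomposition_summary(rbind(decomp, dpool[
    dpool$method_id == "experts", , drop = FALSE]), alpha = config$alpha)
  tests <- rbind(do.call(rbind, test_rows),
                 data.frame(comparison = paste0(
                   "decomposition_", dsum$tests$comparison, "_",
                   dsum$tests$method_id, "_", dsum$tests$component),
                   dimension = dsum$tests$dimension,
                   statistic = dsum$tests$statistic,
                   p_value = dsum$tests$p_value, alpha = config$alpha,
                   stringsAsFactors = FALSE))

  wr <- function(df, name) utils::write.csv(
    df, file.path(out_dir, name), row.names = FALSE)
  wr(measurements, "measurements.csv")
  wr(summary_tbl, "agreement_summary.csv")
  wr(tests, "tests.csv")
  wr(decomp, "decomposition.csv")
  wr(dsum$summary, "decomposition_summary.csv")
  manifest <- list(
    seed = config$seed, mode = config$mode,
    consensus = config$consensus,
    leave_one_out = config$leave_one_out,
    min_experts = config$min_experts, alpha = config$alpha,
    ai_id = ai_id, expert_ids = expert_ids,
    n_frames = nrow(frames_meta),
    n_annotation_rows = nrow(annotations),
    n_missing_keypoints = sum(annotations$missing),
    n_measurement_rows = nrow(measurements),
    n_deviation_rows = nrow(deviations),
    n_excluded_deviations = n_excluded)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(frames_meta = frames_meta, annotations = annotations,
                 measurements = measurements, references = refs,
                 deviations = deviations, agreement_summary = summary_tbl,
                 tests = tests, decomposition = decomp,
                 decomposition_summary = dsum$summary,
                 manifest = manifest))
}
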