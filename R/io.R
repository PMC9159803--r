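#' Write per-trial classification results as tidy CSV
#'
#' One row per trial: `participant_id`, `trial_id`, `condition`, `side`,
#' `category`, `srt_ms`.
#'
#' @param results classification data.frame (from [latent_to_results()] or
#'   [process_trial()] rows).
#' @param file output path.
#' @param participant_id recycled into the `participant_id` column when the
#'   results lack one.
#' @return The path, invisibly.
#' @export
write_trial_results <- function(results, file, participant_id = NA_character_) {
  out <- results
  if (is.null(out$participant_id)) out$participant_id <- participant_id
  if (is.null(out$trial_id)) out$trial_id <- seq_len(nrow(out))
  out <- out[, c("participant_id", "trial_id", "condition", "side",
                 "category", "srt_ms")]
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}

#' Write QC decisions and the exclusion summary
#'
#' Saves the per-participant decisions as `qc_decisions.csv` and the
#' [summarize_exclusions()] accounting as `qc_summary.json` in `dir`.
#'
#' @param decisions data.frame of [apply_qc()] rows.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_qc <- function(decisions, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(decisions, file.path(dir, "qc_decisions.csv"),
                   row.names = FALSE)
  s <- summarize_exclusions(decisions)
  jsonlite::write_json(s, file.path(dir, "qc_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
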