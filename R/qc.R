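#' Participant-level quality control decision
#'
#' Applies the outlier-rejection rules to one participant's tallies. Rules
#' are checked in a fixed order and every triggered rule is recorded, so the
#' decision is auditable; the participant is included iff no rule triggers.
#' Rule identifiers, in order: `validation_accuracy` (ingest screen),
#' `step1_viable` (PRO or ANTI viable count below the minimum),
#' `step2_bad_trials` (PRO or ANTI eye-loss count or non-compliance count
#' strictly above 20% of the expected per-condition trials; the two counts
#' are tested separately, either sufficing), `step3_moca` (MoCA present and
#' below cutoff), `anti_correct` (no ANTI viable correct response). Missing
#' MoCA or validation values never trigger exclusion.
#'
#' @param counts data.frame from [tally_counts()] with rows for conditions
#'   `"pro"` and `"anti"`.
#' @param moca MoCA score, or NA when not administered.
#' @param validation_error average eye-tracker validation error (degrees),
#'   or NA when unavailable.
#' @param anti_correct_count number of ANTI viable correct responses; taken
#'   from `counts` when omitted.
#' @param params a [qc_params()].
#' @param participant_id optional identifier carried into the decision.
#' @return A single-row data.frame: `participant_id`, `included`, `reasons`
#'   (comma-separated triggered rule ids, `""` when included), `first_reason`.
#' @export
apply_qc <- function(counts, moca = NA, validation_error = NA,
                     anti_correct_count = NULL, params = qc_params(),
                     participant_id = NA_character_) {
  need <- c("pro", "anti")
  if (!all(need %in% counts$condition))
    stop("`counts` must contain rows for both pro and anti conditions")
  num_cols <- c("viable", "eye_loss", "noncompliance")
  if (any(unlist(counts[num_cols]) < 0)) stop("counts must be non-negative")
  row <- function(cond) counts[counts$condition == cond, , drop = FALSE]
  pro <- row("pro"); anti <- row("anti")
  if (is.null(anti_correct_count)) {
    cc <- intersect(c("viable_correct_express", "viable_correct_regular"),
                    names(anti))
    anti_correct_count <- sum(unlist(anti[cc]))
  }
  bad_limit <- params$max_badtrial_fraction * params$expected_trials

  reasons <- character(0)
  if (!is.na(validation_error) && validation_error >= params$max_validation_error)
    reasons <- c(reasons, "validation_accuracy")
  if (pro$viable < params$min_viable_count || anti$viable < params$min_viable_count)
    reasons <- c(reasons, "step1_viable")
  if (pro$eye_loss > bad_limit || anti$eye_loss > bad_limit ||
      pro$noncompliance > bad_limit || anti$noncompliance > bad_limit)
    reasons <- c(reasons, "step2_bad_trials")
  if (!is.na(moca) && moca < params$min_moca)
    reasons <- c(reasons, "step3_moca")
  if (params$require_any_anti_correct && anti_correct_count == 0)
    reasons <- c(reasons, "anti_correct")

  data.frame(participant_id = participant_id,
             included = length(reasons) == 0,
             reasons = paste(reasons, collapse = ","),
             first_reason = if (length(reasons)) reasons[1] else NA_character_,
             stringsAsFactors = FALSE)
}

#' Summarize cohort exclusions
#'
#' Attributes each excluded participant to the first rule that triggered
#' (mirroring sequential accounting: a participant failing several rules is
#' counted once, under the earliest), and reports per-reason counts, the
#' three-step total, and the final cohort size.
#'
#' @param decisions data.frame of rows from [apply_qc()].
#' @return A list: `recruited`, `excluded`, `per_reason` (named counts in
#'   rule order), `three_step_total` (sum over the three outlier-rejection
#'   steps) and `final_cohort_size`.
#' @export
summarize_exclusions <- function(decisions) {
  order_ids <- c("validation_accuracy", "step1_viable", "step2_bad_trials",
                 "step3_moca", "anti_correct")
  first <- decisions$first_reason[!decisions$included]
  per_reason <- vapply(order_ids, function(id) sum(first == id, na.rm = TRUE),
                       integer(1))
  excluded <- sum(!decisions$included)
  list(recruited = nrow(decisions),
       excluded = excluded,
       per_reason = per_reason,
       three_step_total = sum(per_reason[c("step1_viable", "step2_bad_trials",
                                           "step3_moca")]),
       final_cohort_size = nrow(decisions) - excluded)
}
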