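#' First stimulus-directed saccade of a trial
#'
#' Among the detected saccades (time-ordered), returns the earliest one
#' whose onset is at or after the start of the anticipatory window (-110 ms)
#' and whose horizontal displacement toward one of the two potential
#' stimulus locations (at +/-10 degrees on the horizontal axis) is at least
#' the direction criterion. Returns `NULL` when no saccade qualifies.
#'
#' @param events a `saccade_events` data.frame from [detect_saccades()].
#' @param windows a [classification_windows()].
#' @param params a [classification_params()].
#' @return A single-row data.frame (one saccade) or `NULL`.
#' @export
first_stimulus_directed_saccade <- function(events,
                                            windows = classification_windows(),
                                            params = classification_params()) {
  if (is.null(events) || nrow(events) == 0) return(NULL)
  dx <- events$end_x - events$start_x
  ok <- events$onset_ms >= windows$anticipatory[1] &
    abs(dx) >= params$direction_criterion
  if (!any(ok)) return(NULL)
  events[which(ok)[which.min(events$onset_ms[ok])], , drop = FALSE]
}

#' Classify one trial into the IPAST taxonomy
#'
#' Applies the classification cascade: eye-tracking loss, then failure to
#' acquire fixation, then the saccade-based categories. The first
#' substantive saccade (amplitude >= `min_saccade_amplitude`, onset within
#' -110..800 ms) decides between a random (off-axis) saccade and a
#' stimulus-axis-directed response; absent any such saccade the trial is a
#' no-saccade non-compliance. Stimulus-directed responses are anticipatory
#' when launched in -110..89 ms, otherwise viable, scored correct or as a
#' direction error from (condition, direction) and express or regular from
#' the latency window. Direction errors are defined for ANTI trials;
#' a PRO-trial saccade away from the stimulus is non-compliant
#' (random saccade), since PRO errors are not among the behavioral measures.
#'
#' @param events a `saccade_events` data.frame for the trial.
#' @param condition `"pro"` or `"anti"`.
#' @param side stimulus side, `"left"` or `"right"`.
#' @param eye_loss logical: was tracking lost beyond tolerance?
#' @param fixated logical: was the fixation point acquired?
#' @param windows a [classification_windows()].
#' @param params a [classification_params()].
#' @return A single-row data.frame: `condition`, `side`, `category`,
#'   `srt_ms` (NA unless anticipatory or viable).
#' @export
classify_trial <- function(events, condition, side,
                           eye_loss = FALSE, fixated = TRUE,
                           windows = classification_windows(),
                           params = classification_params()) {
  res <- function(category, srt = NA_real_) {
    data.frame(condition = condition, side = side, category = category,
               srt_ms = srt, stringsAsFactors = FALSE)
  }
  if (isTRUE(eye_loss)) return(res("eye_loss"))
  if (!isTRUE(fixated)) return(res("noncompliant_no_fixation"))

  # first substantive saccade in the response window decides the branch
  if (!is.null(events) && nrow(events) > 0) {
    sub <- events[events$onset_ms >= windows$anticipatory[1] &
                    events$onset_ms <= windows$viable[2] &
                    events$amplitude >= params$min_saccade_amplitude, ,
                  drop = FALSE]
  } else sub <- NULL
  if (is.null(sub) || nrow(sub) == 0) return(res("noncompliant_no_saccade"))
  first <- sub[which.min(sub$onset_ms), , drop = FALSE]
  dx <- first$end_x - first$start_x
  if (abs(dx) < params$direction_criterion)
    return(res("noncompliant_random_saccade"))

  srt <- first$onset_ms
  toward <- (dx > 0) == (side == "right")
  if (srt < windows$viable[1]) return(res("anticipatory", srt))
  correct <- if (condition == "pro") toward else !toward
  if (condition == "pro" && !correct)
    return(res("noncompliant_random_saccade"))
  epoch <- if (srt < windows$regular[1]) "express" else "regular"
  cat <- paste0("viable_", if (correct) "correct_" else "error_", epoch)
  res(cat, srt)
}

#' Trace-level quality flags for classification
#'
#' Computes the two pre-classification flags from a raw trace: `eye_loss`
#' (more than `max_invalid_fraction` invalid samples between FP onset and
#' 800 ms after STIM onset) and `fixated` (some run of valid samples within
#' `fixation_radius` degrees of the fixation point lasting at least
#' `min_fixation_ms` during the FP epoch).
#'
#' @param trace a [gaze_trace()].
#' @param params a [classification_params()].
#' @return Named list with logical elements `eye_loss` and `fixated`.
#' @export
trace_qc_flags <- function(trace, params = classification_params()) {
  ev <- attr(trace, "events")
  win <- trace$time_ms >= ev$fp_on & trace$time_ms <= ev$stim_on + 800
  eye_loss <- mean(!trace$valid[win]) > params$max_invalid_fraction

  fp <- trace$time_ms >= ev$fp_on & trace$time_ms <= ev$fp_off
  d <- sqrt(trace$x_deg[fp]^2 + trace$y_deg[fp]^2)
  near <- !is.na(d) & d <= params$fixation_radius
  dt <- stats::median(diff(trace$time_ms))
  need <- ceiling(params$min_fixation_ms / dt)
  r <- rle(near)
  fixated <- any(r$values & r$lengths >= need)
  list(eye_loss = eye_loss, fixated = fixated)
}

#' Detect and classify one trial from its raw trace
#'
#' Convenience wrapper chaining [trace_qc_flags()], [detect_saccades()] and
#' [classify_trial()].
#'
#' @param trace a [gaze_trace()].
#' @param det a [detection_params()].
#' @param windows a [classification_windows()].
#' @param params a [classification_params()].
#' @return A single-row classification data.frame (see [classify_trial()]).
#' @export
process_trial <- function(trace, det = detection_params(),
                          windows = classification_windows(),
                          params = classification_params()) {
  flags <- trace_qc_flags(trace, params)
  events <- if (flags$eye_loss) NULL else detect_saccades(trace, det)
  classify_trial(events, attr(trace, "condition"), attr(trace, "side"),
                 eye_loss = flags$eye_loss, fixated = flags$fixated,
                 windows = windows, params = params)
}

#' Tally per-condition trial counts
#'
#' Behavioral counts are all trials for which eye tracking was not lost;
#' they split into non-compliance counts (never fixated, random saccade, no
#' saccade), an explicit anticipatory stratum, and viable counts (correct
#' response or direction error inside the 90-800 ms window).
#'
#' @param results data.frame of per-trial classifications with columns
#'   `condition` and `category`.
#' @return A data.frame with one row per condition: `condition`, `total`,
#'   `eye_loss`, `behavioral`, `noncompliance`, `anticipatory`, `viable`,
#'   plus one column per viable sub-category.
#' @export
tally_counts <- function(results) {
  conds <- unique(results$condition)
  tab <- table(factor(results$category, levels = TRIAL_CATEGORIES),
               factor(results$condition, levels = conds))
  col <- function(cat) as.integer(tab[cat, ])
  total <- as.integer(colSums(tab))
  eye_loss <- col("eye_loss")
  noncompliance <- col("noncompliant_no_fixation") +
    col("noncompliant_random_saccade") + col("noncompliant_no_saccade")
  vce <- col("viable_correct_express"); vcr <- col("viable_correct_regular")
  vee <- col("viable_error_express"); ver <- col("viable_error_regular")
  data.frame(condition = conds, total = total, eye_loss = eye_loss,
             behavioral = total - eye_loss, noncompliance = noncompliance,
             anticipatory = col("anticipatory"),
             viable = vce + vcr + vee + ver,
             viable_correct_express = vce, viable_correct_regular = vcr,
             viable_error_express = vee, viable_error_regular = ver,
             stringsAsFactors = FALSE)
}

#' Map latent simulated outcomes to trial classifications
#'
#' Converts the latent outcomes of [sample_trial_outcomes()] directly into
#' the taxonomy (bypassing trace rendering and detection), using the exact
#' latent latency against the classification windows. Latencies beyond the
#' viable window become no-saccade non-compliance; PRO responses away from
#' the stimulus become random-saccade non-compliance.
#'
#' @param outcomes data.frame from [sample_trial_outcomes()].
#' @param windows a [classification_windows()].
#' @return A data.frame with `condition`, `side`, `category`, `srt_ms`.
#' @export
latent_to_results <- function(outcomes, windows = classification_windows()) {
  fate <- outcomes$fate
  lat <- outcomes$latency_ms
  category <- rep(NA_character_, nrow(outcomes))
  category[fate == "eye_loss"] <- "eye_loss"
  category[fate == "no_fixation"] <- "noncompliant_no_fixation"
  category[fate == "random_saccade"] <- "noncompliant_random_saccade"
  category[fate == "no_saccade"] <- "noncompliant_no_saccade"

  resp <- fate %in% c("express", "regular", "anticipatory")
  late <- resp & lat > windows$viable[2]
  category[late] <- "noncompliant_no_saccade"
  ant <- resp & !late & lat < windows$viable[1]
  category[ant] <- "anticipatory"

  viable <- resp & !late & !ant
  correct <- ifelse(outcomes$condition == "pro",
                    outcomes$toward_stim, !outcomes$toward_stim)
  pro_wrong <- viable & outcomes$condition == "pro" & !correct
  category[pro_wrong] <- "noncompliant_random_saccade"
  viable <- viable & !pro_wrong
  epoch <- ifelse(lat < windows$regular[1], "express", "regular")
  category[viable] <- paste0("viable_",
                             ifelse(correct[viable], "correct_", "error_"),
                             epoch[viable])
  srt <- ifelse(ant | viable, lat, NA_real_)
  data.frame(condition = outcomes$condition, side = outcomes$side,
             category = category, srt_ms = srt, stringsAsFactors = FALSE)
}
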