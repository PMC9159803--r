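#' Task configuration for the interleaved pro/anti-saccade task
#'
#' Defines the timing and geometry of one IPAST session: a central fixation
#' point (FP) shown for 1000 ms, a 200 ms gap with a blank screen, a peripheral
#' stimulus (STIM) at 10 degrees left or right shown for 1000 ms, and a
#' 1000 ms inter-trial interval, over two blocks of 120 trials with condition
#' (PRO/ANTI) and side (left/right) counterbalanced within block.
#'
#' @param n_blocks number of blocks.
#' @param trials_per_block trials per block; must be divisible by 4 so that
#'   condition x side counterbalancing is exact.
#' @param fp_duration,gap_duration,stim_duration,iti_duration epoch durations
#'   in ms.
#' @param stim_eccentricity horizontal stimulus eccentricity in degrees.
#' @param sampling_rate eye tracker sampling rate in Hz.
#' @return An object of class `task_config`.
#' @export
task_config <- function(n_blocks = 2L, trials_per_block = 120L,
                        fp_duration = 1000, gap_duration = 200,
                        stim_duration = 1000, iti_duration = 1000,
                        stim_eccentricity = 10, sampling_rate = 500) {
  if (trials_per_block %% 4L != 0L)
    stop("`trials_per_block` must be divisible by 4 for condition x side counterbalancing")
  durs <- c(fp_duration, gap_duration, stim_duration, iti_duration)
  if (any(durs <= 0)) stop("all epoch durations must be positive")
  if (sampling_rate <= 0) stop("`sampling_rate` must be positive")
  structure(list(
    n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    fp_duration = fp_duration, gap_duration = gap_duration,
    stim_duration = stim_duration, iti_duration = iti_duration,
    stim_eccentricity = stim_eccentricity,
    sampling_rate = sampling_rate,
    dt = 1000 / sampling_rate
  ), class = "task_config")
}

#' Generative behavioral parameters for one participant
#'
#' Parameterizes the latent race model used to simulate trial outcomes.
#' On every behavioral trial an express pathway (a direct sensorimotor
#' transformation of the stimulus transient) fires with probability
#' `p_express[condition]`, producing a short-latency saccade toward the
#' stimulus with a truncated-normal latency on the 90-139 ms express epoch.
#' Otherwise two processes race: an automated stimulus-directed motor command
#' with a shifted-gamma finishing time, and a voluntary goal-directed command
#' with a (later-shifted) shifted-gamma finishing time. On ANTI trials the
#' location-specific voluntary suppression cancels the automated command
#' outright with probability `1 - p_automatic`; a surviving automated
#' command drives a regular-latency direction error if it finishes before
#' the voluntary command, which otherwise drives a correct anti-saccade. On
#' PRO trials both commands are stimulus-directed (the automated command
#' always runs), so the earlier finishing time gives a correct pro-saccade.
#' Trials may instead be diverted
#' to non-behavioral fates (eye-tracking loss, never fixating, a random
#' off-axis saccade, no saccade at all) or to an anticipatory guess.
#'
#' The race distributions are not taken from any empirical fit; defaults are
#' chosen so that the analytic adult ANTI regular-latency error rate is about
#' 0.2 and mean latencies fall in the ranges typical of gap-paradigm IPAST
#' data. All values are configuration, not estimates.
#'
#' @param p_express named probability of the express pathway per condition
#'   (`pro`, `anti`).
#' @param express_mean,express_sd truncated-normal express latency parameters
#'   (ms), truncated to the 90-139 ms epoch.
#' @param auto_shape,auto_scale,auto_shift shifted-gamma parameters (ms) of
#'   the automated process finishing time.
#' @param vol_shape,vol_scale,vol_shift shifted-gamma parameters (ms) of the
#'   voluntary process finishing time; `vol_shift` must be >= `auto_shift`.
#' @param p_automatic probability that the automated command survives the
#'   voluntary suppression and enters the race on ANTI trials.
#' @param p_anticipatory probability of an anticipatory guess (uniform latency
#'   on -110..89 ms, random direction).
#' @param p_noncompliance named probabilities of the three non-compliance
#'   subtypes (`no_fixation`, `random_saccade`, `no_saccade`).
#' @param p_eyeloss probability the trial is lost to tracking failure.
#' @param fixation_noise_sd Gaussian positional noise during fixation
#'   (degrees).
#' @return An object of class `behavior_params`.
#' @export
behavior_params <- function(p_express = c(pro = 0.20, anti = 0.06),
                            express_mean = 108, express_sd = 14,
                            auto_shape = 2, auto_scale = 55, auto_shift = 105,
                            vol_shape = 8, vol_scale = 12, vol_shift = 150,
                            p_automatic = 0.30,
                            p_anticipatory = 0.02,
                            p_noncompliance = c(no_fixation = 0.01,
                                                random_saccade = 0.01,
                                                no_saccade = 0.01),
                            p_eyeloss = 0.02,
                            fixation_noise_sd = 0.02) {
  probs <- c(p_express, p_automatic, p_anticipatory, p_noncompliance, p_eyeloss)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (p_anticipatory + sum(p_noncompliance) + p_eyeloss > 1)
    stop("trial-fate probabilities must sum to at most 1")
  if (vol_shift < auto_shift)
    stop("`vol_shift` must be >= `auto_shift` (voluntary command cannot start earlier)")
  if (any(c(auto_shape, auto_scale, vol_shape, vol_scale) <= 0))
    stop("gamma shape/scale parameters must be positive")
  if (fixation_noise_sd < 0) stop("`fixation_noise_sd` must be non-negative")
  if (!all(c("pro", "anti") %in% names(p_express)))
    stop("`p_express` needs elements named 'pro' and 'anti'")
  if (!all(c("no_fixation", "random_saccade", "no_saccade") %in% names(p_noncompliance)))
    stop("`p_noncompliance` needs no_fixation/random_saccade/no_saccade elements")
  structure(list(
    p_express = p_express,
    express_mean = express_mean, express_sd = express_sd,
    auto_shape = auto_shape, auto_scale = auto_scale, auto_shift = auto_shift,
    vol_shape = vol_shape, vol_scale = vol_scale, vol_shift = vol_shift,
    p_automatic = p_automatic,
    p_anticipatory = p_anticipatory,
    p_noncompliance = p_noncompliance,
    p_eyeloss = p_eyeloss,
    fixation_noise_sd = fixation_noise_sd
  ), class = "behavior_params")
}

#' Saccade detection parameters
#'
#' The per-trial speed threshold is the mean plus `noise_multiplier` standard
#' deviations of the background speed noise during fixation, floored at
#' `min_threshold` (20 degrees/s). Speed must stay above threshold for
#' `min_duration` ms (10 ms = 5 consecutive samples at 500 Hz, inclusive) for
#' a saccade to be detected.
#'
#' @param noise_multiplier multiplier on the fixation-noise standard
#'   deviation.
#' @param min_threshold floor of the dynamic threshold, degrees/s.
#' @param min_duration minimum supra-threshold duration, ms.
#' @param fixation_guard ms dropped from the start of the fixation epoch when
#'   estimating background noise (avoids contamination by the landing saccade
#'   from the previous trial).
#' @param min_fixation_samples minimum valid fixation speed samples required
#'   to estimate the dynamic threshold; below this the floor is used.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(noise_multiplier = 2.5, min_threshold = 20,
                             min_duration = 10, fixation_guard = 100,
                             min_fixation_samples = 10L) {
  if (min_threshold <= 0) stop("`min_threshold` must be positive")
  if (min_duration <= 0) stop("`min_duration` must be positive")
  structure(list(noise_multiplier = noise_multiplier,
                 min_threshold = min_threshold,
                 min_duration = min_duration,
                 fixation_guard = fixation_guard,
                 min_fixation_samples = as.integer(min_fixation_samples)),
            class = "detection_params")
}

#' Trial classification latency windows
#'
#' All bounds are in ms relative to STIM onset. Saccades launched in the
#' anticipatory window (-110 to 89 ms) reflect guessing and are excluded from
#' the behavioral measures; saccades in the viable window (90-800 ms) are
#' split into express (90-139 ms) and regular (140-800 ms) latencies.
#' Integer bounds are inclusive; for continuous latencies the boundaries at
#' 90 and 140 ms belong to the later epoch.
#'
#' @param anticipatory,viable,express,regular two-element numeric windows.
#' @return An object of class `classification_windows`.
#' @export
classification_windows <- function(anticipatory = c(-110, 89),
                                   viable = c(90, 800),
                                   express = c(90, 139),
                                   regular = c(140, 800)) {
  stopifnot(length(anticipatory) == 2, length(viable) == 2,
            length(express) == 2, length(regular) == 2)
  if (express[1] != viable[1] || regular[2] != viable[2] ||
      regular[1] != express[2] + 1)
    stop("express and regular epochs must partition the viable window")
  if (viable[1] != anticipatory[2] + 1)
    stop("anticipatory and viable windows must be contiguous")
  structure(list(anticipatory = anticipatory, viable = viable,
                 express = express, regular = regular),
            class = "classification_windows")
}

#' Trial classification parameters
#'
#' Spatial criteria used when mapping detected saccades onto the trial
#' taxonomy. Stimuli appear only at +/-10 degrees on the horizontal axis, so
#' a saccade counts as stimulus-axis-directed when its horizontal
#' displacement toward one of the two potential stimulus locations is at
#' least `direction_criterion` degrees.
#'
#' @param direction_criterion minimum horizontal displacement (degrees) for a
#'   saccade to count as directed at a potential stimulus location.
#' @param min_saccade_amplitude minimum amplitude (degrees) for a detected
#'   movement to count as a response saccade at all.
#' @param fixation_radius maximum distance (degrees) from the fixation point
#'   for gaze to count as fixating.
#' @param min_fixation_ms minimum continuous fixation (ms) during the FP
#'   epoch for fixation to count as acquired.
#' @param max_invalid_fraction fraction of invalid samples (between FP onset
#'   and 800 ms post-STIM) above which the trial is scored as eye-tracking
#'   loss.
#' @return An object of class `classification_params`.
#' @export
classification_params <- function(direction_criterion = 2,
                                  min_saccade_amplitude = 2,
                                  fixation_radius = 2,
                                  min_fixation_ms = 200,
                                  max_invalid_fraction = 0.25) {
  structure(list(direction_criterion = direction_criterion,
                 min_saccade_amplitude = min_saccade_amplitude,
                 fixation_radius = fixation_radius,
                 min_fixation_ms = min_fixation_ms,
                 max_invalid_fraction = max_invalid_fraction),
            class = "classification_params")
}

#' Voluntary override time parameters
#'
#' @param grid_step resolution (ms) of the cumulative-distribution grid.
#' @param kernel_points width of the box smoothing kernel (odd number of
#'   grid points; 7 points at 1 ms resolution).
#' @param search_window window (ms, relative to STIM onset) within which the
#'   minimum of the smoothed difference distribution is sought.
#' @return An object of class `vot_params`.
#' @export
vot_params <- function(grid_step = 1, kernel_points = 7L,
                       search_window = c(90, 400)) {
  if (kernel_points %% 2L != 1L) stop("`kernel_points` must be odd")
  if (search_window[1] < 90 || search_window[2] > 800)
    stop("`search_window` must lie within the viable window")
  structure(list(grid_step = grid_step,
                 kernel_points = as.integer(kernel_points),
                 search_window = search_window),
            class = "vot_params")
}

#' Participant-level quality control parameters
#'
#' Encodes the three-step outlier rejection procedure plus two auxiliary
#' screens: (1) exclude if the PRO or ANTI viable trial count is below
#' `min_viable_count`; (2) exclude if the PRO or ANTI eye-loss count or
#' non-compliance count exceeds `max_badtrial_fraction` of the expected
#' per-condition trial count (20% of 120 = 24, triggering strictly above 24);
#' (3) exclude if a MoCA score is present and below `min_moca`. Participants
#' whose eye-tracker validation accuracy is present and at or above
#' `max_validation_error` degrees are screened out at ingest, and
#' participants without a single ANTI viable correct response are excluded
#' (their VOT is undefined). Missing MoCA or validation values never trigger
#' exclusion.
#'
#' @param min_viable_count minimum per-condition viable trial count.
#' @param max_badtrial_fraction maximum tolerated fraction of
#'   `expected_trials` lost to eye loss or non-compliance, per condition.
#' @param expected_trials expected trials per condition.
#' @param min_moca minimum MoCA score (when available).
#' @param max_validation_error maximum average validation error in degrees
#'   (exclusion at values >= this bound).
#' @param require_any_anti_correct exclude participants with zero ANTI viable
#'   correct responses.
#' @return An object of class `qc_params`.
#' @export
qc_params <- function(min_viable_count = 30L, max_badtrial_fraction = 0.20,
                      expected_trials = 120L, min_moca = 20,
                      max_validation_error = 1.5,
                      require_any_anti_correct = TRUE) {
  if (max_badtrial_fraction <= 0 || max_badtrial_fraction >= 1)
    stop("`max_badtrial_fraction` must lie in (0, 1)")
  if (min_viable_count > expected_trials)
    stop("`min_viable_count` cannot exceed `expected_trials`")
  structure(list(min_viable_count = as.integer(min_viable_count),
                 max_badtrial_fraction = max_badtrial_fraction,
                 expected_trials = as.integer(expected_trials),
                 min_moca = min_moca,
                 max_validation_error = max_validation_error,
                 require_any_anti_correct = isTRUE(require_any_anti_correct)),
            class = "qc_params")
}

# canonical trial taxonomy, in classification precedence order
TRIAL_CATEGORIES <- c(
  "eye_loss",
  "noncompliant_no_fixation",
  "noncompliant_random_saccade",
  "noncompliant_no_saccade",
  "anticipatory",
  "viable_correct_express",
  "viable_correct_regular",
  "viable_error_express",
  "viable_error_regular"
)

#' Trial taxonomy
#'
#' @return Character vector of the nine trial categories.
#' @export
trial_categories <- function() TRIAL_CATEGORIES
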