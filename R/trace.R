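#' Construct a gaze trace
#'
#' A gaze trace holds the monocular eye-position samples of one trial
#' together with its event marks. Times are in ms relative to STIM onset
#' (so FP onset is negative), positions in degrees, and `valid` flags
#' tracker-valid samples; invalid samples carry NA positions.
#'
#' @param time_ms strictly increasing sample times (ms, relative to STIM
#'   onset) at the nominal sampling interval.
#' @param x_deg,y_deg gaze position in degrees.
#' @param valid logical validity flag per sample.
#' @param events named list with `fp_on`, `fp_off`, `stim_on`, `stim_off`
#'   (ms relative to STIM onset, so `stim_on` is 0).
#' @param condition,side trial metadata (`"pro"`/`"anti"`, `"left"`/`"right"`).
#' @return A data.frame of class `gaze_trace` with attributes `events`,
#'   `condition`, `side`.
#' @export
gaze_trace <- function(time_ms, x_deg, y_deg, valid = rep(TRUE, length(time_ms)),
                       events, condition = NA_character_, side = NA_character_) {
  n <- length(time_ms)
  stopifnot(length(x_deg) == n, length(y_deg) == n, length(valid) == n)
  if (n > 1 && any(diff(time_ms) <= 0))
    stop("`time_ms` must be strictly increasing")
  req <- c("fp_on", "fp_off", "stim_on", "stim_off")
  if (!all(req %in% names(events)))
    stop("`events` must contain fp_on, fp_off, stim_on, stim_off")
  ev <- events[req]
  if (!(ev$fp_on < ev$fp_off && ev$fp_off < ev$stim_on && ev$stim_on < ev$stim_off))
    stop("event marks must be ordered fp_on < fp_off < stim_on < stim_off")
  x_deg[!valid] <- NA_real_
  y_deg[!valid] <- NA_real_
  out <- data.frame(time_ms = time_ms, x_deg = x_deg, y_deg = y_deg,
                    valid = valid)
  structure(out, events = ev, condition = condition, side = side,
            class = c("gaze_trace", "data.frame"))
}

#' @export
print.gaze_trace <- function(x, ...) {
  ev <- attr(x, "events")
  cat(sprintf("<gaze_trace> %d samples, %s/%s, FP %g..%g ms, STIM %g..%g ms\n",
              nrow(x), attr(x, "condition"), attr(x, "side"),
              ev$fp_on, ev$fp_off, ev$stim_on, ev$stim_off))
  invisible(x)
}

# raised-cosine displacement profile: 0 at t=0 rising smoothly to 1 at t=D.
# Peak speed is amplitude * pi / (2 D), a symmetric single-peaked profile
# that satisfies the detector's speed and duration criteria for any
# task-scale amplitude.
raised_cosine <- function(frac) (1 - cos(pi * pmin(pmax(frac, 0), 1))) / 2

# main-sequence-flavored duration: ~30 ms for small saccades up to ~55 ms
# for 10 degree saccades
saccade_duration_ms <- function(amplitude) pmin(60, 30 + 2.5 * amplitude)

#' Render a synthetic gaze trace for a latent trial outcome
#'
#' Converts one latent outcome (a row as produced by
#' [sample_trial_outcomes()]) into a 500 Hz gaze trace covering FP onset
#' through STIM offset. Fixation epochs are white Gaussian positional noise;
#' saccades are raised-cosine position ramps with amplitude-scaled durations
#' (30-60 ms); eye-loss outcomes contain runs of invalid samples;
#' no-fixation outcomes hold gaze away from the fixation point for the whole
#' trial; random-saccade outcomes launch a vertical saccade off the stimulus
#' axis; no-saccade outcomes fixate throughout.
#'
#' @param outcome single-row data.frame (or list) with `condition`, `side`,
#'   `fate`, `latency_ms`, `toward_stim`.
#' @param config a [task_config()].
#' @param params a [behavior_params()] (only `fixation_noise_sd` is used).
#' @return A [gaze_trace()].
#' @export
render_gaze_trace <- function(outcome, config = task_config(),
                              params = behavior_params()) {
  dt <- config$dt
  t0 <- -(config$fp_duration + config$gap_duration)
  time <- seq(t0, config$stim_duration, by = dt)
  n <- length(time)
  events <- list(fp_on = t0, fp_off = -config$gap_duration,
                 stim_on = 0, stim_off = config$stim_duration)
  fate <- outcome$fate
  lat <- outcome$latency_ms
  if (fate %in% c("express", "regular", "anticipatory")) {
    if (is.na(lat) || lat < t0 || lat > config$stim_duration)
      stop("outcome latency lies outside the trial window")
  }
  stim_x <- ifelse(outcome$side == "left", -1, 1) * config$stim_eccentricity

  x <- stats::rnorm(n, 0, params$fixation_noise_sd)
  y <- stats::rnorm(n, 0, params$fixation_noise_sd)
  valid <- rep(TRUE, n)

  # The latent latency is defined as the operational saccade onset: the time
  # the eye speed reaches the 20 deg/s detection floor. The raised-cosine
  # ramp is therefore led in by the (analytic) time it spends below the
  # floor, so a detector sees onset at the nominal latency.
  add_saccade <- function(x, onset_ms, target, dur = saccade_duration_ms(abs(target))) {
    peak <- abs(target) * pi / (2 * dur)          # deg/ms
    lead <- dur / pi * asin(min(1, 0.020 / peak)) # 20 deg/s = 0.020 deg/ms
    ramp <- raised_cosine((time - (onset_ms - lead)) / dur)
    x + target * ramp
  }

  if (fate %in% c("express", "regular", "anticipatory")) {
    target_x <- if (isTRUE(outcome$toward_stim)) stim_x else -stim_x
    x <- add_saccade(x, lat, target_x)
  } else if (fate == "random_saccade") {
    # off-axis (vertical) saccade at a plausible latency
    y <- add_saccade(y, stats::runif(1, 120, 500), 5)
  } else if (fate == "no_fixation") {
    # gaze parked well away from the FP for the entire trial
    x <- x + 4
    y <- y + 3
  } else if (fate == "eye_loss") {
    # a long blink/track-loss run covering >25% of the scored window
    start <- sample.int(floor(n * 0.5), 1)
    len <- ceiling(n * 0.4)
    valid[seq(start, min(n, start + len - 1))] <- FALSE
  }
  # "no_saccade": fixation noise only

  gaze_trace(time, x, y, valid, events,
             condition = outcome$condition, side = outcome$side)
}

#' Write / read gaze traces as plain CSV
#'
#' Long-format trace table with columns `trial_id`, `time_ms`, `x_deg`,
#' `y_deg`, `valid`, plus a per-trial events table (`trial_id`, `fp_on_ms`,
#' `gap_on_ms`, `stim_on_ms`, `stim_off_ms`, `condition`, `side`). The
#' writer/reader pair round-trips traces exactly (full double precision).
#'
#' @param traces list of [gaze_trace()] objects.
#' @param samples_file,events_file output CSV paths.
#' @return `write_traces_csv` returns the file paths invisibly;
#'   `read_traces_csv` returns a list of [gaze_trace()] objects.
#' @export
write_traces_csv <- function(traces, samples_file, events_file) {
  ids <- seq_along(traces)
  samp <- do.call(rbind, lapply(ids, function(i) {
    tr <- traces[[i]]
    data.frame(trial_id = i, time_ms = tr$time_ms, x_deg = tr$x_deg,
               y_deg = tr$y_deg, valid = tr$valid)
  }))
  evs <- do.call(rbind, lapply(ids, function(i) {
    ev <- attr(traces[[i]], "events")
    data.frame(trial_id = i, fp_on_ms = ev$fp_on, gap_on_ms = ev$fp_off,
               stim_on_ms = ev$stim_on, stim_off_ms = ev$stim_off,
               condition = attr(traces[[i]], "condition"),
               side = attr(traces[[i]], "side"))
  }))
  utils::write.csv(format(samp, digits = 17, trim = TRUE, scientific = FALSE),
                   samples_file, row.names = FALSE, quote = FALSE)
  utils::write.csv(evs, events_file, row.names = FALSE, quote = FALSE)
  invisible(c(samples_file, events_file))
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(samples_file, events_file) {
  samp <- utils::read.csv(samples_file)
  evs <- utils::read.csv(events_file)
  lapply(evs$trial_id, function(id) {
    s <- samp[samp$trial_id == id, ]
    e <- evs[evs$trial_id == id, ]
    gaze_trace(s$time_ms, s$x_deg, s$y_deg, as.logical(s$valid),
               events = list(fp_on = e$fp_on_ms, fp_off = e$gap_on_ms,
                             stim_on = e$stim_on_ms, stim_off = e$stim_off_ms),
               condition = e$condition, side = e$side)
  })
}
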